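options(csfhydro.verbose = FALSE)

# constant-radius annulus phantom (cord r_c, dura r_d) for geometry oracles
const_annulus_cfg <- function(r_cord = 2, r_dura = 4, L = 20, px = 0.375,
                              ...) {
  phantom_config(L = L, pixel_spacing = px, slice_thickness = 1,
                 cord_radius = data.frame(z = c(0, L),
                                          value = rep(r_cord, 2)),
                 sas_area = data.frame(z = c(0, L),
                                       value = rep(pi * (r_dura^2 - r_cord^2), 2)),
                 ...)
}

# rasterised disk mask of radius r (mm) at pixel size px (mm)
disk_mask <- function(r, px, margin = 4) {
  n <- as.integer(ceiling((2 * r + margin) / px))
  if (n %% 2L == 0L) n <- n + 1L
  cc <- (n + 1) / 2
  xs <- (seq_len(n) - cc) * px
  outer(xs^2, xs^2, `+`) <= r^2
}

# sampled sinusoidal waveform -Q0 sin(2 pi (t/T + phase)) (caudal systole)
sine_wave <- function(Q0 = 0.5, period = 0.5, n = 24, phase = 0, z = NA) {
  tt <- (seq_len(n) - 1) / n * period
  flow_waveform(-Q0 * sin(2 * pi * (tt / period + phase)), period, z)
}

# flow-slice set with cervical coverage fine enough to localise the
# amplitude peak (see the SV-peak recovery tests)
dense_slices <- function() c(0, 10, 20, 30, 40, 55, 84, 120, 149, 190, 237)
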