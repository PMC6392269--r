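# Digital phantoms: annular spinal-canal geometry plus travelling-wave
# per-pixel velocity exports, with analytic ground truth, in the exact file
# formats the readers consume.

# Canonical CSF pulse shape constants (module constants, not a claim about
# any real cohort): sharp systolic (caudal, negative) lobe at 0.2 T, broad
# diastolic lobe at 0.6 T, systolic/diastolic amplitude ratio ~ 1.7.
.shape_k_sys <- 6
.shape_k_dia <- 2
.shape_u_sys <- 0.2
.shape_u_dia <- 0.6
.shape_a_dia <- 0.6

shape_raw <- function(u) {
  -exp(.shape_k_sys * (cos(2 * pi * (u - .shape_u_sys)) - 1)) +
    .shape_a_dia * exp(.shape_k_dia * (cos(2 * pi * (u - .shape_u_dia)) - 1))
}

shape_consts <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      uu <- seq(0, 1, length.out = 20001)[-20001]
      v <- shape_raw(uu)
      m <- mean(v)
      amp <- diff(range(v - m))
      cache <<- list(mean = m, amp = amp,
                     abs_integral = mean(abs((v - m) / amp)),
                     min = min((v - m) / amp), max = max((v - m) / amp))
    }
    cache
  }
})

#' Canonical CSF pulse shape
#'
#' Periodic two-lobe waveform used by the flow phantom: a sharp systolic
#' (negative, caudal) peak at phase fraction 0.2 and a broader diastolic
#' lobe at 0.6, zero mean over the cycle, normalised to unit peak-to-peak
#' amplitude, systolic/diastolic amplitude ratio about 1.7.
#'
#' @param u phase fraction(s); evaluated periodically (any real).
#' @return Shape value(s); `Q(z,t) = Q_a(z) * csf_pulse_shape(t/T - delay)`.
#' @export
csf_pulse_shape <- function(u) {
  sc <- shape_consts()
  (shape_raw(u %% 1) - sc$mean) / sc$amp
}

interp_cp <- function(cp, z) {
  if (is.function(cp)) cp(z) else approx(cp$z, cp$value, xout = z, rule = 2)$y
}

# Default flow-rate amplitude: smooth asymmetric bump peaking at 25 mm
# caudal of the FM (sharper cranial rise, long caudal decay), amplitude
# 0.9 ml/s at the peak decaying to ~0 in the lower lumbar spine.
default_q_amplitude <- function(z) {
  w <- ifelse(z < 25, 25, 110)
  0.9 * exp(-((z - 25) / w)^2)
}

#' Phantom configuration
#'
#' Defines an annular digital phantom of the spinal subarachnoid space:
#' axially varying cord radius and SAS area (dura radius derived as
#' `sqrt(r_cord^2 + A_sas/pi)`), an oscillatory zero-net-flow waveform
#' propagating caudally at a prescribed pulse wave velocity, plus optional
#' Gaussian pixel noise and constant per-slice velocity offsets.
#'
#' Defaults emulate the adult cynomolgus monkey: SAS length 300 mm, SAS
#' area spanning roughly 7--75 mm^2 with its minimum near 70 mm caudal of
#' the FM, cardiac period 0.55 s with flow-rate amplitude peaking
#' (~0.9 ml/s) about 25 mm caudal of the FM, anatomic pixels 0.375 mm and
#' flow pixels 0.45 mm.
#'
#' @param L phantom length, mm.
#' @param pixel_spacing anatomic in-plane pixel size, mm.
#' @param slice_thickness anatomic slice spacing, mm.
#' @param flow_pixel_spacing PC-MRI in-plane pixel size, mm.
#' @param period cardiac cycle period T, s.
#' @param n_phases cardiac phases per cycle.
#' @param pwv prescribed pulse wave velocity, m/s.
#' @param cord_radius control points (data frame `z`, `value` in mm) for the
#'   cord radius; linearly interpolated, 0 beyond the last point (conus /
#'   filum).
#' @param sas_area control points for the SAS cross-sectional area, mm^2.
#' @param q_amplitude flow-rate amplitude `Q_a(z)` in ml/s: either a
#'   function of z or a control-point data frame.  The default is a smooth
#'   asymmetric bump peaking at 0.9 ml/s about 25 mm caudal of the FM
#'   (markedly smaller at the FM itself) with a long caudal decay to
#'   near zero in the lower lumbar spine.
#' @param noise_sd per-pixel Gaussian velocity noise SD, cm/s.
#' @param offset constant per-slice flow offset(s) delta, ml/s (recycled
#'   over slices); emulates eddy-current bias.
#' @param seed integer seed for the noise generator (`NULL`: leave RNG
#'   state alone).
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(L = 300,
                           pixel_spacing = 0.375,
                           slice_thickness = 1,
                           flow_pixel_spacing = 0.45,
                           period = 0.55,
                           n_phases = 24L,
                           pwv = 1.2,
                           cord_radius = data.frame(
                             z = c(0, 30, 70, 120, 180, 220),
                             value = c(2.2, 2.6, 2.3, 1.8, 0.8, 0)),
                           sas_area = data.frame(
                             z = c(0, 25, 70, 150, 230, 300),
                             value = c(75, 55, 7, 22, 18, 7)),
                           q_amplitude = default_q_amplitude,
                           noise_sd = 0,
                           offset = 0,
                           seed = NULL) {
  if (L <= 0 || pixel_spacing <= 0 || slice_thickness <= 0 ||
      flow_pixel_spacing <= 0 || period <= 0 || pwv <= 0)
    stop_validation("all phantom scales must be positive")
  if (any(cord_radius$value < 0) || any(sas_area$value <= 0))
    stop_validation("cord radius must be >= 0 and SAS area > 0 everywhere")
  structure(list(L = L, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness,
                 flow_pixel_spacing = flow_pixel_spacing,
                 period = period, n_phases = as.integer(n_phases), pwv = pwv,
                 cord_radius = cord_radius, sas_area = sas_area,
                 q_amplitude = q_amplitude, noise_sd = noise_sd,
                 offset = offset, seed = seed),
            class = "phantom_config")
}

#' Analytic phantom radii and geometry at given levels
#'
#' @param cfg a [phantom_config()].
#' @param z axial positions, mm.
#' @return Data frame `z`, `r_cord`, `r_dura` (mm), `A_c`, `A_d`, `A_sas`
#'   (mm^2), `P_c`, `P_d`, `P_sas` (mm), `D_h` (mm), all from exact circle
#'   formulas.
#' @export
phantom_truth_profile <- function(cfg, z) {
  rc <- interp_cp(cfg$cord_radius, z)
  rc[z > max(cfg$cord_radius$z)] <- 0
  A_sas <- interp_cp(cfg$sas_area, z)
  rd <- sqrt(rc^2 + A_sas / pi)
  A_c <- pi * rc^2; A_d <- pi * rd^2
  P_c <- 2 * pi * rc; P_d <- 2 * pi * rd
  data.frame(z = z, r_cord = rc, r_dura = rd,
             A_c = A_c, A_d = A_d, A_sas = A_d - A_c,
             P_c = P_c, P_d = P_d, P_sas = P_c + P_d,
             D_h = 4 * (A_d - A_c) / (P_c + P_d))
}

#' Prescribed flow waveform of the phantom
#'
#' `Q(z, t) = Q_a(z) * csf_pulse_shape((t - z / PWV) / T)` — the amplitude
#' profile rides a waveform travelling caudally at the prescribed PWV.
#'
#' @param cfg a [phantom_config()].
#' @param z axial position(s), mm.
#' @param t time(s) within the cycle, s.
#' @return Flow in ml/s (matrix if both arguments have length > 1,
#'   z indexing rows).
#' @export
phantom_flow <- function(cfg, z, t) {
  qa <- interp_cp(cfg$q_amplitude, z)
  delay <- z / 1000 / cfg$pwv
  out <- outer(seq_along(z), seq_along(t),
               function(i, j) qa[i] * csf_pulse_shape((t[j] - delay[i]) / cfg$period))
  if (length(z) == 1L || length(t) == 1L) drop(out) else out
}

#' Ground-truth stroke volume profile of the phantom
#'
#' `SV(z) = Q_a(z) * T * integral |shape| du`, exact for the module's pulse
#' shape (the shape integral is a module constant).
#'
#' @inheritParams phantom_truth_profile
#' @return SV in ml at each `z`.
#' @export
phantom_truth_sv <- function(cfg, z) {
  interp_cp(cfg$q_amplitude, z) * cfg$period * shape_consts()$abs_integral
}

raster_slice <- function(rc, rd, n, dx) {
  cc <- (n + 1) / 2
  xs <- (seq_len(n) - cc) * dx
  r2 <- outer(xs^2, xs^2, `+`)
  list(cord = if (rc > 0) r2 <= rc^2 else r2 < 0,  # rc = 0: no cord
       dura = r2 <= rd^2)
}

#' Generate the phantom segmentation volume
#'
#' Rasterises concentric circles per axial slice into a label volume
#' (1 = cord, 2 = CSF between cord and dura) and returns it with the
#' analytic ground truth: per-slice circle areas/perimeters and totals by
#' the rectangle rule on the analytic profile.
#'
#' @param cfg a [phantom_config()].
#' @param fov in-plane field of view, mm; default fits the largest dura
#'   radius plus a 3 mm margin.
#' @return List: `seg` (a [segmentation_volume()]), `truth` (list with
#'   `profile` from [phantom_truth_profile()] on the slice grid and
#'   `totals`, a [global_geometry()]).
#' @export
generate_geometry <- function(cfg, fov = NULL) {
  stopifnot(inherits(cfg, "phantom_config"))
  z <- seq(0, cfg$L, by = cfg$slice_thickness)
  tr <- phantom_truth_profile(cfg, z)
  need <- 2 * max(tr$r_dura) + 3
  fov <- fov %||% need
  if (fov < 2 * max(tr$r_dura))
    stop_validation("dura radius exceeds the field of view")
  n <- as.integer(ceiling(fov / cfg$pixel_spacing))
  if (n %% 2L == 0L) n <- n + 1L
  cord <- array(FALSE, dim = c(n, n, length(z)))
  dura <- array(FALSE, dim = c(n, n, length(z)))
  for (i in seq_along(z)) {
    m <- raster_slice(tr$r_cord[i], tr$r_dura[i], n, cfg$pixel_spacing)
    cord[, , i] <- m$cord
    dura[, , i] <- m$dura
  }
  seg <- segmentation_volume(cord, dura,
                             spacing = c(cfg$pixel_spacing, cfg$pixel_spacing,
                                         cfg$slice_thickness),
                             axial_axis = 3L, fm_index = 1L)
  totals <- global_geometry(
    SA_c = sum(tr$P_c) * cfg$slice_thickness / 100,
    SA_d = sum(tr$P_d) * cfg$slice_thickness / 100,
    V_c = sum(tr$A_c) * cfg$slice_thickness / 1000,
    V_d = sum(tr$A_d) * cfg$slice_thickness / 1000,
    L_sas = cfg$L)
  list(seg = seg, truth = list(profile = tr, totals = totals))
}

#' Default phantom flow-slice locations
#'
#' Disc midpoints of the six acquisition levels (FM, C2-C3, C5-C6, T4-T5,
#' T10-T11, L3-L4) read off the cynomolgus [vertebral_table()].
#'
#' @return Numeric z positions in mm.
#' @export
default_flow_slices <- function() {
  vt <- vertebral_table()
  mid <- function(a, b) mean(vt$z_mean[match(c(a, b), vt$level)])
  c(FM = 0, `C2-C3` = mid("C2", "C3"), `C5-C6` = mid("C5", "C6"),
    `T4-T5` = mid("T4", "T5"), `T10-T11` = mid("T10", "T11"),
    `L3-L4` = mid("L3", "L4"))
}

#' Generate phantom per-pixel velocity exports
#'
#' For each requested slice, rasterises the local annulus at the PC-MRI
#' pixel size, distributes the prescribed flow `Q*(t)` as a plug profile
#' over the ROI pixels (velocity `= Q*/A_roi`), then adds i.i.d. Gaussian
#' pixel noise and the constant per-slice offset `delta/A_roi` (so the
#' recovered flow offset equals `delta`).  Identical config and seed give
#' identical output.
#'
#' @param cfg a [phantom_config()].
#' @param slice_zs slice positions, mm; default [default_flow_slices()].
#' @return List: `rois` (list of [velocity_roi()]), `truth` (list with
#'   `Q` matrix slices x phases of the noise-free prescribed flow, `sv`,
#'   `q_amplitude`, `offsets` (ml/s), `pwv`, `slice_zs`).
#' @export
generate_flow <- function(cfg, slice_zs = default_flow_slices()) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (any(slice_zs < 0 | slice_zs > cfg$L))
    stop_validation("slice positions must lie within [0, L]")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  offsets <- rep(cfg$offset, length.out = length(slice_zs))
  tt <- (seq_len(cfg$n_phases) - 1) / cfg$n_phases * cfg$period
  tr <- phantom_truth_profile(cfg, slice_zs)
  Qstar <- matrix(0, length(slice_zs), cfg$n_phases)
  rois <- vector("list", length(slice_zs))
  A_pix <- cfg$flow_pixel_spacing^2
  for (s in seq_along(slice_zs)) {
    fovn <- as.integer(ceiling((2 * tr$r_dura[s] + 3) / cfg$flow_pixel_spacing))
    if (fovn %% 2L == 0L) fovn <- fovn + 1L
    m <- raster_slice(tr$r_cord[s], tr$r_dura[s], fovn, cfg$flow_pixel_spacing)
    roi_mask <- m$dura & !m$cord
    npix <- sum(roi_mask)
    if (npix == 0L) stop_validation("empty annulus at slice z = ", slice_zs[s])
    A_roi <- npix * A_pix
    Q <- phantom_flow(cfg, slice_zs[s], tt)
    Qstar[s, ] <- Q
    # velocity [cm/s] = 100 * Q [ml/s] / A [mm^2]
    v_plug <- 100 * Q / A_roi
    v_off <- 100 * offsets[s] / A_roi
    V <- matrix(rep(v_plug, each = npix), npix, cfg$n_phases) + v_off
    if (cfg$noise_sd > 0)
      V <- V + matrix(rnorm(npix * cfg$n_phases, 0, cfg$noise_sd),
                      npix, cfg$n_phases)
    ij <- which(roi_mask, arr.ind = TRUE)
    rois[[s]] <- velocity_roi(V, ij, A_pix, cfg$period, slice_zs[s])
  }
  list(rois = rois,
       truth = list(Q = Qstar, sv = phantom_truth_sv(cfg, slice_zs),
                    q_amplitude = interp_cp(cfg$q_amplitude, slice_zs),
                    offsets = offsets, pwv = cfg$pwv, slice_zs = slice_zs))
}

#' Write a complete phantom study to disk
#'
#' Emits exactly what the readers consume: the NIfTI label volume, one
#' velocity CSV + JSON sidecar per flow slice, and a flat key--value
#' ground-truth manifest (JSON).
#'
#' @param cfg a [phantom_config()].
#' @param dir output directory (created if needed).
#' @param slice_zs flow-slice positions, mm.
#' @return Invisible list of written paths (`segmentation`, `velocity`,
#'   `manifest`).
#' @export
write_phantom <- function(cfg, dir, slice_zs = default_flow_slices()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geo <- generate_geometry(cfg)
  flw <- generate_flow(cfg, slice_zs)
  seg_path <- file.path(dir, "phantom_labels.nii.gz")
  write_segmentation(geo$seg, seg_path)
  vel_paths <- character(length(flw$rois))
  for (s in seq_along(flw$rois)) {
    vel_paths[s] <- file.path(dir, sprintf("velocity_slice%02d.csv", s))
    write_velocity_csv(flw$rois[[s]], vel_paths[s])
  }
  manifest <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(pwv_m_s = cfg$pwv, period_s = cfg$period,
         slice_z_mm = as.numeric(slice_zs),
         offsets_ml_s = as.numeric(flw$truth$offsets),
         sv_ml = as.numeric(flw$truth$sv),
         q_amplitude_ml_s = as.numeric(flw$truth$q_amplitude),
         V_sas_ml = geo$truth$totals$V_sas,
         SA_sas_cm2 = geo$truth$totals$SA_sas,
         L_sas_mm = geo$truth$totals$L_sas),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(segmentation = seg_path, velocity = vel_paths,
                 manifest = manifest))
}
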