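make_waves <- function(zs, fun, period = 0.5, n = 24) {
  tt <- (seq_len(n) - 1) / n * period
  lapply(zs, function(z) flow_waveform(fun(z, tt), period, z))
}

test_that("a field constant in z is reproduced at every level", {
  zs <- seq(0, 250, by = 50)
  waves <- make_waves(zs, function(z, tt) -sin(2 * pi * tt / 0.5))
  stf <- fit_spatiotemporal(waves)
  ref <- -sin(2 * pi * stf$t / 0.5)
  for (i in seq(1, length(stf$z), by = 25))
    expect_equal(stf$Q[i, ], ref, tolerance = 0.01, ignore_attr = TRUE)
})

test_that("surface validation rejects too few or duplicate slices", {
  zs <- c(0, 100)
  waves <- make_waves(zs, function(z, tt) sin(2 * pi * tt / 0.5))
  expect_error(fit_spatiotemporal(waves), "at least 3")
  waves3 <- make_waves(c(0, 100, 100), function(z, tt) sin(2 * pi * tt / 0.5))
  expect_error(fit_spatiotemporal(waves3), "duplicate")
  wavesT <- make_waves(c(0, 100, 200), function(z, tt) sin(2 * pi * tt / 0.5))
  wavesT[[2]] <- flow_waveform(wavesT[[2]]$Q, 0.6, 100)
  expect_error(fit_spatiotemporal(wavesT), "one cycle period")
})

test_that("a travelling wave is interpolated faithfully between slices", {
  cfg <- phantom_config(noise_sd = 0)
  fl <- generate_flow(cfg)
  waves <- lapply(fl$rois, function(r) offset_correct(waveform_from_pixels(r))$waveform)
  stf <- fit_spatiotemporal(waves)
  peak_amp <- max(abs(fl$truth$Q))
  for (zm in c(27, 60, 117, 192)) {
    i <- which.min(abs(stf$z - zm))
    analytic <- phantom_flow(cfg, stf$z[i], stf$t)
    rms <- sqrt(mean((stf$Q[i, ] - analytic)^2))
    expect_lt(rms, 0.05 * peak_amp)
  }
  # interpolation consistency at the acquired slices
  for (s in seq_along(waves)) {
    w <- waves[[s]]
    i <- which.min(abs(stf$z - w$z))
    rms <- sqrt(mean((stf$Q[i, ] - w$Q)^2))
    amp <- diff(range(w$Q))
    expect_lt(rms, 0.05 * amp)
  }
  # zero net flow preserved at every interpolated level
  expect_lt(max(abs(rowMeans(stf$Q))), 1e-9)
})

test_that("amplitude varying linearly in z interpolates to the linear law", {
  zs <- seq(0, 200, by = 40)
  amp <- function(z) 1 - z / 400
  waves <- make_waves(zs, function(z, tt) -amp(z) * sin(2 * pi * tt / 0.5))
  stf <- fit_spatiotemporal(waves)
  for (zm in c(20, 100, 180)) {
    i <- which.min(abs(stf$z - zm))
    got <- (max(stf$Q[i, ]) - min(stf$Q[i, ])) / 2
    expect_equal(got, amp(zm), tolerance = 0.05)
  }
})

test_that("peak arrival follows a prescribed delay and excludes flat rows", {
  zs <- seq(0, 250, by = 50)
  period <- 0.5
  waves <- make_waves(zs, function(z, tt)
    -sin(2 * pi * (tt - z / 2000) / period))
  stf <- fit_spatiotemporal(waves)
  arr <- peak_arrival(stf)
  half_step <- period / 24 / 2
  sel <- seq(1, nrow(arr), by = 10)
  fitted_delay <- arr$t_arrival[sel] - arr$t_arrival[1]
  expect_true(all(abs(fitted_delay - arr$z[sel] / 2000) < half_step))
  # zero-delay field: constant arrival
  waves0 <- make_waves(zs, function(z, tt) -sin(2 * pi * tt / period))
  arr0 <- peak_arrival(fit_spatiotemporal(waves0))
  expect_lt(diff(range(arr0$t_arrival)), half_step)
  # a flat surface row is excluded, rest unchanged
  stf2 <- stf
  stf2$Q[5, ] <- 0
  arr2 <- peak_arrival(stf2)
  expect_true(is.na(arr2$t_arrival[5]))
  expect_equal(arr2$t_arrival[-5], arr$t_arrival[-5])
})

test_that("pulse wave velocity inverts a constructed arrival line exactly", {
  arr <- data.frame(z = 0:250, t_arrival = 0.1 + (0:250) / 2000)
  pw <- pulse_wave_velocity(arr)
  expect_equal(pw$slope, 5e-4, tolerance = 1e-12)
  expect_equal(pw$pwv, 2.0, tolerance = 1e-9)
  expect_equal(pw$r_squared, 1, tolerance = 1e-12)
  # standing wave: flagged undefined, no error
  flat <- data.frame(z = 0:100, t_arrival = 0.2)
  expect_true(is.na(pulse_wave_velocity(flat)$pwv))
  # too few points
  expect_error(pulse_wave_velocity(flat[1, ]), ">= 2")
  # z_range restriction
  bent <- data.frame(z = 0:200,
                     t_arrival = c(0.1 + (0:100) / 2000, rep(0.15, 100)))
  pwr <- pulse_wave_velocity(bent, z_range = c(0, 100))
  expect_equal(pwr$pwv, 2.0, tolerance = 1e-9)
})

test_that("noise-free phantom PWV is recovered within 2% across 0.5-5 m/s", {
  for (pwv in c(0.5, 2, 5)) {
    cfg <- phantom_config(noise_sd = 0, pwv = pwv)
    fl <- generate_flow(cfg, slice_zs = seq(0, 300, length.out = 6))
    waves <- lapply(fl$rois,
                    function(r) offset_correct(waveform_from_pixels(r))$waveform)
    stf <- fit_spatiotemporal(waves)
    pw <- pulse_wave_velocity(peak_arrival(stf, at = stf$source_z))
    expect_equal(pw$pwv, pwv, tolerance = 0.02)
  }
})

test_that("hydrodynamic profile matches single-slice features on a constant field", {
  zs <- seq(0, 100, by = 20)
  period <- 0.5
  waves <- make_waves(zs, function(z, tt) -0.5 * sin(2 * pi * tt / period))
  stf <- fit_spatiotemporal(waves)
  geom <- data.frame(z = stf$z, A_sas = 30, D_h = 3)
  hy <- hydrodynamic_profile(stf, geom)
  ref <- waveform_features(waves[[1]], A_sas = 30, D_h = 3)
  expect_lt(max(abs(hy$SV - ref$SV)), 0.01 * ref$SV)
  expect_lt(max(abs(hy$Q_sys - ref$Q_sys)), 0.01 * abs(ref$Q_sys))
  # mean velocity inversely tracks area for fixed flow
  geom2 <- geom; geom2$A_sas <- 60
  hy2 <- hydrodynamic_profile(stf, geom2)
  expect_equal(hy2$U_sys, hy$U_sys / 2, tolerance = 1e-6)
  # disjoint grids rejected
  expect_error(hydrodynamic_profile(stf, data.frame(z = 500:600, A_sas = 1, D_h = 1)),
               "no overlap")
})
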