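test_that("pixel summation reproduces uniform and zero fields exactly", {
  v <- matrix(1, 10, 24)
  roi <- velocity_roi(v, cbind(1:10, 1:10), pixel_area = 0.2, period = 0.5, z = 0)
  w <- waveform_from_pixels(roi)
  expect_equal(w$Q, rep(0.02, 24))  # 10 x 0.2 mm^2 x 1 cm/s = 0.02 ml/s
  roi$velocity[] <- 0
  expect_equal(waveform_from_pixels(roi)$Q, rep(0, 24))
  expect_error(velocity_roi(v[0, , drop = FALSE], cbind(1, 1)[0, ], 0.2, 0.5, 0),
               "at least one pixel")
})

test_that("offset correction subtracts the cycle mean and reports it", {
  w <- sine_wave(Q0 = 1, period = 0.5)
  shifted <- flow_waveform(w$Q + 0.1, w$period, w$z)
  oc <- offset_correct(shifted)
  expect_equal(oc$offset, 0.1, tolerance = 1e-12)
  expect_equal(oc$waveform$Q, w$Q, tolerance = 1e-12)
  expect_lt(abs(mean(oc$waveform$Q)), 1e-9 * max(abs(oc$waveform$Q)))
  # already zero-mean: identity, offset 0
  oc2 <- offset_correct(w)
  expect_equal(oc2$offset, 0, tolerance = 1e-15)
  expect_equal(oc2$waveform$Q, w$Q)
  expect_true(is.finite(oc$offset_pct))
})

test_that("injected per-slice offsets are recovered exactly without noise", {
  cfg <- phantom_config(L = 60, noise_sd = 0, offset = c(0.05, -0.02, 0.1),
                        cord_radius = data.frame(z = c(0, 60), value = c(2, 2)),
                        sas_area = data.frame(z = c(0, 60), value = c(40, 40)))
  fl <- generate_flow(cfg, slice_zs = c(0, 25, 50))
  off <- vapply(fl$rois,
                function(r) offset_correct(waveform_from_pixels(r))$offset, 0)
  expect_equal(off, c(0.05, -0.02, 0.1), tolerance = 1e-10)
})

test_that("cycle resampling preserves shape and scales SV by T_target/T", {
  w <- sine_wave(Q0 = 0.4, period = 0.5)
  expect_equal(resample_cycle(w, 0.5)$Q, w$Q)          # identity
  # period change with equal phase count: samples untouched, period updated
  r <- resample_cycle(w, 0.6)
  expect_equal(r$Q, w$Q)
  expect_equal(r$period, 0.6)
  sv <- function(x) mean(abs(x$Q)) * x$period
  expect_equal(sv(r) / sv(w), 0.6 / 0.5, tolerance = 1e-12)
  # period change through a different phase grid: amplitude within 1%
  w2 <- sine_wave(Q0 = 1, period = 0.4, n = 24, phase = 0.0083)
  r2 <- resample_cycle(w2, 0.6, n_phases = 36)
  expect_equal(r2$period, 0.6)
  expect_equal(max(r2$Q) - min(r2$Q), 2, tolerance = 0.01)
})

test_that("waveform features match sinusoid closed forms", {
  # grid-aligned sinusoid: extrema exact, |sin| quadrature within 0.6%
  w <- sine_wave(Q0 = 0.5, period = 0.5)
  ft <- waveform_features(w, A_sas = 30, D_h = 3)
  expect_equal(ft$Q_sys, -0.5)
  expect_equal(ft$Q_dia, 0.5)
  expect_equal(ft$Q_a, 1.0)
  expect_equal(ft$SV, 2 * 0.5 * 0.5 / pi, tolerance = 0.006)
  expect_equal(ft$U_sys, 100 * -0.5 / 30, tolerance = 1e-12)
  # sv_half halves SV only
  ft2 <- waveform_features(w, A_sas = 30, D_h = 3, sv_half = TRUE)
  expect_equal(ft2$SV, ft$SV / 2)
  expect_equal(ft2$Q_a, ft$Q_a)
  # zero waveform: all features 0 except alpha
  z0 <- flow_waveform(rep(0, 24), 0.5)
  f0 <- waveform_features(z0, A_sas = 30, D_h = 3)
  expect_equal(f0$SV, 0); expect_equal(f0$Q_a, 0); expect_equal(f0$Re, 0)
  expect_gt(f0$alpha, 0)
})

test_that("Reynolds and Womersley numbers are dimensionally consistent", {
  w <- sine_wave(Q0 = 0.269, period = 0.55)   # U_sys = -2.69 cm/s over 10 mm^2
  ft <- waveform_features(w, A_sas = 10, D_h = 2.04)
  expect_equal(ft$U_sys, -2.69)
  expect_equal(ft$Re, 79.2, tolerance = 1e-3)
  # Re linear in |U_sys| (via Q0) and in D_h
  ft2 <- waveform_features(sine_wave(Q0 = 0.538, period = 0.55), 10, D_h = 2.04)
  expect_equal(ft2$Re, 2 * ft$Re, tolerance = 1e-9)
  ft3 <- waveform_features(w, 10, D_h = 4.08)
  expect_equal(ft3$Re, 2 * ft$Re, tolerance = 1e-9)
  # alpha linear in D_h and in sqrt(1/T)
  a1 <- waveform_features(sine_wave(period = 0.5), 30, D_h = 2)$alpha
  a2 <- waveform_features(sine_wave(period = 0.5), 30, D_h = 4)$alpha
  a3 <- waveform_features(sine_wave(period = 0.125), 30, D_h = 2)$alpha
  expect_equal(a2, 2 * a1, tolerance = 1e-9)
  expect_equal(a3, 2 * a1, tolerance = 1e-9)
  # diameter convention doubles alpha
  ad <- waveform_features(sine_wave(period = 0.5), 30, D_h = 2,
                          womersley_convention = "diameter")$alpha
  expect_equal(ad, 2 * a1, tolerance = 1e-12)
  # undefined geometry -> NA markers
  fna <- waveform_features(w, A_sas = 0, D_h = 2)
  expect_true(is.na(fna$U_sys) && is.na(fna$Re))
})

test_that("every corrected waveform has zero net flow", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(c(12, 24, 32), 1)
    w <- flow_waveform(rnorm(n), period = runif(1, 0.4, 0.7))
    cQ <- offset_correct(w)$waveform$Q
    expect_lt(abs(mean(cQ)), 1e-12)
  }
})
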