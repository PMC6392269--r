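ramp_profile <- function(L, slope = 1, intercept = 0) {
  z <- seq(0, L, by = 1)
  data.frame(z = z, A_sas = intercept + slope * z)
}

test_that("length normalisation is the identity at the reference length", {
  p <- ramp_profile(100, slope = 0.5, intercept = 10)
  out <- normalize_length(p, L_subject = 100, L_mean = 100)
  expect_equal(out$z, p$z)
  expect_equal(out$A_sas, p$A_sas, tolerance = 1e-12)
})

test_that("length normalisation rescales positions but preserves values", {
  # a linear ramp over L = 200 maps onto the same endpoints over L = 100
  p <- ramp_profile(200, slope = 0.1)
  out <- normalize_length(p, L_subject = 200, L_mean = 100)
  expect_equal(range(out$z), c(0, 100))
  expect_equal(out$A_sas[out$z == 0], 0, tolerance = 1e-12)
  expect_equal(out$A_sas[out$z == 100], 20, tolerance = 1e-12)
  # values are interpolated on the stretched axis: still exactly linear
  expect_equal(out$A_sas, 0.2 * out$z, tolerance = 1e-9)
  # a constant profile stays constant under any rescaling
  k <- ramp_profile(150, slope = 0, intercept = 7)
  outk <- normalize_length(k, 150, 300)
  expect_true(all(abs(outk$A_sas - 7) < 1e-12))
  expect_error(normalize_length(p, 0, 100), "positive")
})

test_that("cohort statistics: single subject, known two-subject case, mismatch", {
  p1 <- ramp_profile(50, slope = 0, intercept = 1)
  s1 <- cohort_stats(list(p1))
  expect_equal(s1$n_subjects, 1L)
  expect_true(all(s1$sd$A_sas == 0))
  expect_equal(s1$scalars$average, 1)
  # two constant profiles at 1 and 3: mean 2, sample sd sqrt(2)
  p2 <- ramp_profile(50, slope = 0, intercept = 3)
  s2 <- cohort_stats(list(p1, p2))
  expect_true(all(abs(s2$mean$A_sas - 2) < 1e-12))
  expect_true(all(abs(s2$sd$A_sas - sqrt(2)) < 1e-12))
  expect_equal(s2$scalars$maximum, 2)
  expect_equal(s2$scalars$minimum, 2)
  # profiles on different grids are rejected
  p3 <- ramp_profile(60)
  expect_error(cohort_stats(list(p1, p3)), "share one z grid")
  expect_error(cohort_stats(list()), "at least one")
})

test_that("cohort extrema are extrema of the mean profile, with FM-excluded variants", {
  z <- 0:100
  # subject A peaks at z = 30, subject B at z = 70; the mean peaks at both
  pa <- data.frame(z = z, A_sas = 10 + 20 * exp(-((z - 30) / 10)^2))
  pb <- data.frame(z = z, A_sas = 10 + 20 * exp(-((z - 70) / 10)^2))
  s <- cohort_stats(list(pa, pb))
  m <- s$mean$A_sas
  expect_equal(s$scalars$maximum, max(m))
  expect_lt(s$scalars$maximum, 30)  # mean extremum < any individual extremum
  # a spike confined to the first 5 mm dominates maximum but not maximum_no_fm
  pc <- pa; pc$A_sas[pc$z < 5] <- 100
  s2 <- cohort_stats(list(pc, pb))
  expect_gt(s2$scalars$maximum, s2$scalars$maximum_no_fm)
  expect_equal(s2$scalars$maximum_no_fm,
               max(s2$mean$A_sas[s2$mean$z >= 5]))
})

test_that("reliability regression recovers identity and proportional relations", {
  set.seed(11)
  z <- 0:80
  base <- lapply(1:3, function(i)
    data.frame(z = z, A_sas = 20 + 10 * sin(z / 15) + rnorm(length(z), 0, 2)))
  # follow-up identical to baseline: slope 1, R^2 = 1
  rid <- reliability_regression(base, base)
  expect_equal(rid$table$slope, 1, tolerance = 1e-12)
  expect_equal(rid$table$r_squared, 1, tolerance = 1e-12)
  expect_equal(rid$table$n, 3 * length(z))
  # follow-up = 0.9 x baseline: slope 0.9, still R^2 = 1
  fup <- lapply(base, function(p) { p$A_sas <- 0.9 * p$A_sas; p })
  rpr <- reliability_regression(base, fup)
  expect_equal(rpr$table$slope, 0.9, tolerance = 1e-12)
  expect_equal(rpr$table$r_squared, 1, tolerance = 1e-12)
  # with noise, R^2 is symmetric under swapping arms but the slope is not
  fn <- lapply(base, function(p) { p$A_sas <- p$A_sas + rnorm(nrow(p), 0, 3); p })
  fwd <- reliability_regression(base, fn)
  rev <- reliability_regression(fn, base)
  expect_equal(fwd$table$r_squared, rev$table$r_squared, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(fwd$table$slope, rev$table$slope)))
  # mismatched inputs
  expect_error(reliability_regression(base, base[1:2]), "matched subjects")
  tiny <- list(data.frame(z = 0:1, A_sas = c(1, 2)))
  expect_error(reliability_regression(tiny, tiny), "fewer than 3")
})

test_that("vertebral lookup maps landmark distances to the tabulated levels", {
  expect_equal(vertebral_lookup(0), "FM")
  expect_equal(vertebral_lookup(22.3), "C3")
  expect_equal(vertebral_lookup(301), "coccyx")
  expect_equal(vertebral_lookup(1000), "coccyx")  # beyond the chart: nearest
  expect_equal(vertebral_lookup(c(10.3, 141.4)), c("C2", "T10"))
  # exact midpoint between C1 (5.7) and C2 (10.3) goes cranial
  expect_equal(vertebral_lookup(8.0), "C1")
  expect_error(vertebral_lookup(-1), "nonnegative")
  tab <- vertebral_table()
  expect_true(all(diff(tab$z_mean) > 0))
  expect_equal(nrow(tab), 27L)
})
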