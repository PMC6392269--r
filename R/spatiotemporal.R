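#' Fit a smooth spatio-temporal flow surface Q(z, t)
#'
#' Fuses per-slice flow waveforms (all resampled to a common cardiac cycle,
#' see [resample_cycle()]) into a two-dimensional smoothing-spline surface
#' over axial position and cardiac phase, evaluated on a regular
#' `dz` x phase grid spanning the measured z range only (no extrapolation).
#' The temporal basis is cyclic, so the surface is periodic in t by
#' construction; each evaluated z-row is re-offset to zero mean so the
#' zero-net-flow property survives smoothing.
#'
#' The smoothing amount is chosen by restricted maximum likelihood unless a
#' fixed smoothing parameter is supplied; the value used is recorded on the
#' returned object.
#'
#' @param waveforms list of [flow_waveform()]s at >= 3 distinct z, all with
#'   the same period and phase count.
#' @param dz output axial grid spacing, mm (default 1).
#' @param smoothing `NULL` (default, REML-selected) or numeric smoothing
#'   parameter(s) passed to the spline fit (`sp`; length 1 recycled to both
#'   marginals).
#' @param k basis dimensions `c(k_z, k_t)`; defaults to
#'   `c(min(n_slices, 10), min(n_phases, 16))`.
#' @return An object of class `stf_surface`: fields `z`, `t`, `Q`
#'   (matrix, z x t, ml/s), `period`, `sp` (smoothing parameters used),
#'   `source_z`.
#' @export
fit_spatiotemporal <- function(waveforms, dz = 1, smoothing = NULL, k = NULL) {
  if (length(waveforms) < 3L)
    stop_validation("need at least 3 waveforms at distinct z")
  zs <- vapply(waveforms, function(w) w$z, 0)
  if (anyNA(zs)) stop_validation("all waveforms must carry a z position")
  if (anyDuplicated(zs)) stop_validation("duplicate slice z positions")
  periods <- vapply(waveforms, function(w) w$period, 0)
  nph <- vapply(waveforms, function(w) length(w$Q), 0L)
  if (diff(range(periods)) > 1e-9 || length(unique(nph)) != 1L)
    stop_validation("waveforms must share one cycle period and phase count; ",
                    "resample_cycle() them to the common cycle first")
  period <- periods[1]; nph <- nph[1]
  tt <- (seq_len(nph) - 1) / nph * period
  dat <- data.frame(z = rep(zs, each = nph),
                    t = rep(tt, length(zs)),
                    Q = unlist(lapply(waveforms, function(w) w$Q)))
  if (is.null(k)) k <- c(min(length(zs), 10L), min(nph, 16L))
  sp <- if (is.null(smoothing)) NULL else rep(as.numeric(smoothing), length.out = 2)
  fit <- mgcv::gam(Q ~ te(z, t, bs = c("cr", "cc"), k = k),
                   data = dat, sp = sp, method = "REML",
                   knots = list(t = seq(0, period, length.out = k[2])))
  csf_log("spatio-temporal smoothing parameters: ",
          paste(signif(fit$sp, 4), collapse = ", "))
  zg <- seq(min(zs), max(zs), by = dz)
  grid <- expand.grid(t = tt, z = zg)
  Q <- matrix(predict(fit, grid), nrow = length(zg), ncol = nph, byrow = TRUE)
  Q <- Q - rowMeans(Q)  # restore zero net flow per level
  structure(list(z = zg, t = tt, Q = Q, period = period,
                 sp = as.numeric(fit$sp), source_z = sort(zs)),
            class = "stf_surface")
}

#' @export
print.stf_surface <- function(x, ...) {
  cat(sprintf("<stf_surface> %d z-levels (%.0f..%.0f mm) x %d phases, T = %.3f s\n",
              length(x$z), min(x$z), max(x$z), length(x$t), x$period))
  invisible(x)
}

#' Extract one z-row of a surface as a waveform
#'
#' @param stf an `stf_surface`.
#' @param z requested level (nearest grid level is used).
#' @return A [flow_waveform()].
#' @export
stf_waveform <- function(stf, z) {
  stopifnot(inherits(stf, "stf_surface"))
  i <- which.min(abs(stf$z - z))
  flow_waveform(stf$Q[i, ], stf$period, stf$z[i])
}

# time of the minimum of one periodic row, with 3-point parabolic
# sub-sample refinement; NA for a flat row
row_peak_time <- function(q, period) {
  if (diff(range(q)) <= 1e-12 * max(abs(q), 1e-300)) return(NA_real_)
  n <- length(q)
  i <- which.min(q)                      # first minimum = earliest tie
  qm <- q[(i - 2L) %% n + 1L]; q0 <- q[i]; qp <- q[i %% n + 1L]
  den <- qm - 2 * q0 + qp
  d <- if (den > 0) (qm - qp) / (2 * den) else 0
  d <- max(min(d, 0.5), -0.5)
  ((i - 1 + d) * period / n) %% period
}

#' Arrival time of peak systolic flow along the spine
#'
#' For every z-level of the surface, the time at which Q is most negative
#' (peak systolic, caudal flow), refined to sub-phase resolution by
#' three-point parabolic interpolation around the discrete minimum
#' (neighbours taken periodically; ties broken toward the earliest phase).
#' Because arrival times live on a circle of circumference T, the curve is
#' unwrapped along z so that delays accumulate monotonically rather than
#' jumping by a full cycle.  Flat rows give `NA` and are excluded from any
#' downstream fit.
#'
#' @param stf an `stf_surface` from [fit_spatiotemporal()].
#' @param at optional axial positions (mm): compute arrivals only on the
#'   surface rows nearest these (typically `stf$source_z`).  Between widely
#'   spaced slices, especially where the flow amplitude is small, the
#'   smoothed surface can drift the peak gradually by a large fraction of
#'   the cycle, defeating unwrapping of the dense curve; unwrapping across
#'   the acquired levels only is robust whenever the true inter-slice delay
#'   is below half a cycle.
#' @return Data frame with columns `z` (mm) and `t_arrival` (s; may exceed
#'   T after unwrapping).
#' @export
peak_arrival <- function(stf, at = NULL) {
  stopifnot(inherits(stf, "stf_surface"))
  rows <- if (is.null(at)) seq_along(stf$z) else
    sort(unique(vapply(at, function(z) which.min(abs(stf$z - z)), 0L)))
  arr0 <- apply(stf$Q[rows, , drop = FALSE], 1L, row_peak_time,
                period = stf$period)
  arr <- rep(NA_real_, length(stf$z)); arr[rows] <- arr0
  T <- stf$period
  ok <- which(!is.na(arr))
  if (length(ok) > 1L) {
    for (j in seq_along(ok)[-1]) {
      prev <- arr[ok[j - 1L]]
      arr[ok[j]] <- arr[ok[j]] + T * round((prev - arr[ok[j]]) / T)
    }
  }
  out <- data.frame(z = stf$z, t_arrival = arr)
  if (!is.null(at)) out <- out[rows, , drop = FALSE]
  out
}

#' Pulse wave velocity from the peak-arrival slope
#'
#' Ordinary least-squares fit of arrival time against axial position over
#' `z_range` (default: the full measured span, FM to the most caudal
#' level).  The slope is in s/mm; `PWV = 1 / slope`, reported in m/s.
#' z is the controlled variable, so t is regressed on z, not the reverse.
#' A slope at or below tolerance (standing wave) flags the PWV as
#' undefined rather than raising an error.
#'
#' @param arrival data frame from [peak_arrival()].
#' @param z_range optional `c(min, max)` in mm restricting the fit.  For
#'   PWV estimation prefer arrivals computed at the acquired slice
#'   locations (`peak_arrival(stf, at = stf$source_z)`): between widely
#'   spaced slices the smoothed surface advects the peak nonlinearly,
#'   which biases a fit pooled over every interpolated level.
#' @param slope_tol slope below which PWV is flagged undefined (s/mm).
#' @return Object of class `pulse_wave`: `slope` (s/mm), `intercept` (s),
#'   `pwv` (m/s, `NA` when undefined), `r_squared`, `n`, `z_range`,
#'   `arrival` (the points used).
#' @export
pulse_wave_velocity <- function(arrival, z_range = NULL, slope_tol = 1e-9) {
  pts <- arrival[!is.na(arrival$t_arrival), , drop = FALSE]
  if (!is.null(z_range))
    pts <- pts[pts$z >= z_range[1] & pts$z <= z_range[2], , drop = FALSE]
  if (nrow(pts) < 2L) stop_validation("need >= 2 valid arrival points in range")
  fit <- lm(t_arrival ~ z, data = pts)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  # suppressWarnings: summary.lm warns on essentially perfect fits
  r2 <- if (nrow(pts) > 2L) suppressWarnings(summary(fit)$r.squared) else 1
  pwv <- if (is.finite(slope) && slope > slope_tol) 1e-3 / slope else NA_real_
  structure(list(slope = slope, intercept = intercept, pwv = pwv,
                 r_squared = r2, n = nrow(pts),
                 z_range = z_range %||% range(pts$z), arrival = pts),
            class = "pulse_wave")
}

#' @export
print.pulse_wave <- function(x, ...) {
  cat(sprintf("<pulse_wave> PWV = %s m/s (slope %.3g s/mm, R^2 %.3f, n = %d)\n",
              if (is.na(x$pwv)) "undefined" else sprintf("%.3f", x$pwv),
              x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Per-level hydrodynamic profile from surface and geometry
#'
#' Applies [waveform_features()] to every z-row of the flow surface that
#' also has local geometry, using that level's `A_sas` and `D_h`.  Grids
#' are matched by position (to within half a grid step).
#'
#' @param stf an `stf_surface`.
#' @param geom a `geometric_profile` from [slice_profiles()].
#' @param fluid a [fluid_properties()].
#' @param ... passed on to [waveform_features()] (`sv_half`,
#'   `womersley_convention`).
#' @return A `hydrodynamic_profile`: data frame with `z`, `SV`, `Q_sys`,
#'   `Q_dia`, `Q_a`, `U_sys`, `U_dia`, `Re`, `alpha` on the overlap grid.
#' @export
hydrodynamic_profile <- function(stf, geom, fluid = fluid_properties(), ...) {
  stopifnot(inherits(stf, "stf_surface"))
  tol <- 0.5 * min(diff(stf$z))
  idx <- vapply(stf$z, function(z) {
    j <- which.min(abs(geom$z - z))
    if (abs(geom$z[j] - z) <= tol) j else NA_integer_
  }, 0L)
  keep <- which(!is.na(idx))
  if (length(keep) == 0L) stop_validation("no overlap between flow and geometry grids")
  rows <- lapply(keep, function(i) {
    g <- geom[idx[i], ]
    cbind(z = stf$z[i],
          waveform_features(flow_waveform(stf$Q[i, ], stf$period, stf$z[i]),
                            A_sas = g$A_sas, fluid = fluid, D_h = g$D_h, ...))
  })
  out <- do.call(rbind, rows)
  attr(out, "dz") <- min(diff(stf$z))
  class(out) <- c("hydrodynamic_profile", "data.frame")
  out
}
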