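#' CSF fluid properties
#'
#' CSF at body temperature is water-like; the default dynamic viscosity is
#' 0.693 mPa s with density 1000 kg/m^3, giving a kinematic viscosity
#' nu = 0.693e-6 m^2/s.
#'
#' @param mu_mPas dynamic viscosity, mPa s.
#' @param rho density, kg/m^3.
#' @return List with `mu_mPas`, `rho` and derived `nu` (m^2/s), class
#'   `fluid_properties`.
#' @export
fluid_properties <- function(mu_mPas = 0.693, rho = 1000) {
  if (mu_mPas <= 0 || rho <= 0) stop_validation("viscosity and density must be positive")
  structure(list(mu_mPas = mu_mPas, rho = rho, nu = mu_mPas * 1e-3 / rho),
            class = "fluid_properties")
}

#' Flow waveform container
#'
#' Volumetric CSF flow over one cardiac cycle at one axial location,
#' sampled at uniform phases on `[0, T)`.
#'
#' @param Q flow per phase, ml/s (caudal negative).
#' @param period cycle period T, s.
#' @param z axial location, mm caudal of the FM (`NA` if unplaced).
#' @return Object of class `flow_waveform` with fields `Q`, `t`, `period`, `z`.
#' @export
flow_waveform <- function(Q, period, z = NA_real_) {
  if (length(Q) < 2L) stop_validation("waveform needs at least 2 phases")
  if (period <= 0) stop_validation("cycle period must be positive")
  structure(list(Q = as.numeric(Q),
                 t = (seq_along(Q) - 1) / length(Q) * period,
                 period = period, z = as.numeric(z)),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("<flow_waveform> z = %s mm, %d phases, T = %.3f s, Q in [%.3g, %.3g] ml/s\n",
              format(x$z), length(x$Q), x$period, min(x$Q), max(x$Q)))
  invisible(x)
}

#' Flow waveform from per-pixel velocities
#'
#' `Q(t) = sum over ROI pixels of A_pixel * V_pixel(t)`, converted to ml/s
#' (pixel areas in mm^2, velocities in cm/s: 1 mm^2 cm/s = 0.01 ml/s).
#' The result is not yet offset-corrected.
#'
#' @param roi a [velocity_roi()].
#' @return A [flow_waveform()] at the ROI's z.
#' @export
waveform_from_pixels <- function(roi) {
  stopifnot(inherits(roi, "velocity_roi"))
  Q <- colSums(roi$velocity) * roi$pixel_area * 0.01
  flow_waveform(Q, roi$period, roi$z)
}

#' Zero-net-flow (eddy-current) offset correction
#'
#' Spinal CSF flow is oscillatory with approximately zero net flow over the
#' cycle; any nonzero cycle mean is a constant phase-offset artefact
#' (eddy currents) and is subtracted.  For QC the offset is also reported
#' relative to the arithmetic mean of |Q|.
#'
#' @param w a [flow_waveform()].
#' @return List with `waveform` (corrected), `offset` (ml/s) and
#'   `offset_pct` (100 |offset| / mean|Q|, NA for an all-zero waveform).
#' @export
offset_correct <- function(w) {
  stopifnot(inherits(w, "flow_waveform"))
  off <- mean(w$Q)
  mabs <- mean(abs(w$Q))
  corrected <- flow_waveform(w$Q - off, w$period, w$z)
  list(waveform = corrected, offset = off,
       offset_pct = if (mabs > 0) 100 * abs(off) / mabs else NA_real_)
}

#' Resample a waveform onto a different cycle period
#'
#' Re-expresses the waveform on uniform phases of a cycle of period
#' `T_target` by scaling the time axis `t -> t * T_target / T` and
#' periodic linear interpolation; amplitudes are unchanged.  Used to
#' normalise waveforms acquired at different heart rates onto the cohort's
#' average cycle before spatio-temporal fusion.  With the same output phase
#' count this leaves the samples untouched (only T changes); stroke volume
#' scales exactly by `T_target / T`.
#'
#' @param w a [flow_waveform()].
#' @param T_target target period, s.
#' @param n_phases output phase count (default: same as input).
#' @return A [flow_waveform()] with period `T_target`.
#' @export
resample_cycle <- function(w, T_target, n_phases = length(w$Q)) {
  stopifnot(inherits(w, "flow_waveform"))
  if (T_target <= 0) stop_validation("T_target must be positive")
  n_in <- length(w$Q)
  # interpolate on the phase fraction u in [0,1), periodic
  u_out <- (seq_len(n_phases) - 1) / n_phases
  u_in <- c((seq_len(n_in) - 1) / n_in, 1)
  Q_in <- c(w$Q, w$Q[1])
  Q_out <- approx(u_in, Q_in, xout = u_out)$y
  flow_waveform(Q_out, T_target, w$z)
}

#' Hydrodynamic features of a flow waveform
#'
#' From an offset-corrected waveform and the local geometry:
#' peak systolic flow `Q_sys = min Q` (caudal, <= 0), peak diastolic
#' `Q_dia = max Q`, amplitude `Q_a = Q_dia - Q_sys`; stroke volume
#' `SV = integral |Q| dt` over one cycle (periodic trapezoid, which on a
#' uniform phase grid is `mean(|Q|) * T`); spatial mean velocities
#' `U_sys = Q_sys / A_sas`, `U_dia = Q_dia / A_sas` (cm/s); Reynolds number
#' `Re = |U_sys| D_h / nu` and Womersley number
#' `alpha = (D_h / 2) sqrt(omega / nu)` with `omega = 2 pi / T`.
#'
#' @param w offset-corrected [flow_waveform()].
#' @param A_sas local SAS cross-sectional area, mm^2.
#' @param fluid a [fluid_properties()].
#' @param D_h local hydraulic diameter, mm.
#' @param womersley_convention `"radius"` (default, `alpha = (D_h/2)
#'   sqrt(omega/nu)`) or `"diameter"` (`alpha = D_h sqrt(omega/nu)`), for
#'   sensitivity checks against sources that use the full diameter.
#' @param sv_half if `TRUE`, apply the common 1/2 factor to SV (volume
#'   displaced per direction rather than the full cycle integral of |Q|).
#'   Default `FALSE`: SV is the plain cycle integral.
#' @return One-row data frame: `Q_sys`, `Q_dia`, `Q_a` (ml/s), `SV` (ml),
#'   `U_sys`, `U_dia` (cm/s), `Re`, `alpha`.  Velocity/Re features are `NA`
#'   where `A_sas` or `D_h` is nonpositive or missing.
#' @export
waveform_features <- function(w, A_sas, fluid = fluid_properties(), D_h,
                              womersley_convention = c("radius", "diameter"),
                              sv_half = FALSE) {
  stopifnot(inherits(w, "flow_waveform"))
  womersley_convention <- match.arg(womersley_convention)
  Q_sys <- min(w$Q); Q_dia <- max(w$Q)
  SV <- mean(abs(w$Q)) * w$period * (if (isTRUE(sv_half)) 0.5 else 1)
  ok_A <- is.finite(A_sas) && A_sas > 0
  ok_D <- is.finite(D_h) && D_h > 0
  if (!ok_A || !ok_D)
    csf_log("nonpositive A_sas or D_h at z = ", format(w$z),
            "; velocity features undefined", level = "WARN")
  # Q [ml/s] / A [mm^2] -> cm/s: (1000 mm^3/s) / mm^2 = mm/s = 0.1 cm/s
  U_sys <- if (ok_A) 100 * Q_sys / A_sas else NA_real_
  U_dia <- if (ok_A) 100 * Q_dia / A_sas else NA_real_
  Dh_m <- D_h / 1000
  Re <- if (ok_A && ok_D) abs(U_sys) / 100 * Dh_m / fluid$nu else NA_real_
  omega <- 2 * pi / w$period
  half <- if (womersley_convention == "radius") 2 else 1
  alpha <- if (ok_D) (Dh_m / half) * sqrt(omega / fluid$nu) else NA_real_
  data.frame(Q_sys = Q_sys, Q_dia = Q_dia, Q_a = Q_dia - Q_sys, SV = SV,
             U_sys = U_sys, U_dia = U_dia, Re = Re, alpha = alpha)
}
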