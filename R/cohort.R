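#' Normalise a per-level profile to a reference spine length
#'
#' Subjects differ in subarachnoid-space length, so axial profiles are
#' compared on a common grid: the z-axis is linearly rescaled by
#' `L_mean / L_subject` and every value column is resampled at `dz` spacing
#' on `[0, L_mean]` by linear interpolation.  Values are not rescaled, only
#' positions, so profile extrema are preserved.
#'
#' @param profile data frame with a `z` column (mm) plus numeric value
#'   columns.
#' @param L_subject this subject's SAS length, mm.
#' @param L_mean cohort-average SAS length, mm.
#' @param dz output grid spacing, mm.
#' @return Data frame on `z = seq(0, L_mean, dz)` with the same value
#'   columns.
#' @export
normalize_length <- function(profile, L_subject, L_mean, dz = 1) {
  if (L_subject <= 0 || L_mean <= 0)
    stop_validation("lengths must be positive")
  zq <- seq(0, L_mean, by = dz)
  zs <- profile$z * (L_mean / L_subject)
  out <- data.frame(z = zq)
  for (nm in setdiff(names(profile), "z"))
    out[[nm]] <- approx(zs, profile[[nm]], xout = zq, rule = 2)$y
  out
}

#' Cohort statistics over length-normalised profiles
#'
#' Pointwise mean and sample (n-1) standard deviation across subjects on
#' the common grid, plus the scalar summary used for reporting: the
#' average along the spine of the cross-subject mean profile, and the
#' maximum / minimum of that mean profile (extrema of the mean, not of any
#' individual subject).  Because the levels nearest the foramen magnum can
#' dominate extrema, the extrema are also reported with the first 5 mm
#' omitted.
#'
#' @param profiles list of data frames on one common `z` grid.
#' @param parameters value columns to summarise; default: all shared
#'   numeric columns except `z`.
#' @return Object of class `cohort_summary`: `mean` and `sd` data frames on
#'   the grid, `scalars` (one row per parameter: `average`, `maximum`,
#'   `minimum`, `maximum_no_fm`, `minimum_no_fm`), `n_subjects`.
#' @export
cohort_stats <- function(profiles, parameters = NULL) {
  if (length(profiles) < 1L) stop_validation("need at least one profile")
  z <- profiles[[1]]$z
  for (p in profiles)
    if (nrow(p) != length(z) || max(abs(p$z - z)) > 1e-9)
      stop_validation("profiles must share one z grid")
  parameters <- parameters %||% setdiff(Reduce(intersect, lapply(profiles, names)), "z")
  mu <- data.frame(z = z); sdv <- data.frame(z = z)
  scal <- NULL
  no_fm <- z >= 5
  for (nm in parameters) {
    M <- sapply(profiles, function(p) p[[nm]])
    M <- matrix(M, nrow = length(z))
    mu[[nm]] <- rowMeans(M, na.rm = TRUE)
    sdv[[nm]] <- apply(M, 1L, sd, na.rm = TRUE)
    if (length(profiles) == 1L) sdv[[nm]] <- rep(0, length(z))
    m <- mu[[nm]]
    scal <- rbind(scal, data.frame(
      parameter = nm,
      average = mean(m, na.rm = TRUE),
      maximum = max(m, na.rm = TRUE),
      minimum = min(m, na.rm = TRUE),
      maximum_no_fm = max(m[no_fm], na.rm = TRUE),
      minimum_no_fm = min(m[no_fm], na.rm = TRUE)))
  }
  structure(list(mean = mu, sd = sdv, scalars = scal,
                 n_subjects = length(profiles)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d subject(s), %d levels\n",
              x$n_subjects, nrow(x$mean)))
  print(x$scalars, row.names = FALSE)
  invisible(x)
}

#' Test--retest reliability regression
#'
#' For every parameter, pools (baseline, follow-up) value pairs over
#' subjects and all axial grid points and fits ordinary least squares
#' `followup ~ baseline`.  R-squared is symmetric under swapping the axes;
#' the slope is not (follow-up is regressed on baseline).
#'
#' @param baseline,followup lists of per-subject profiles (same subjects,
#'   same order, one common z grid).
#' @param parameters value columns; default: all shared columns except `z`.
#' @return Object of class `reliability_result`: `table` (data frame with
#'   `parameter`, `slope`, `intercept`, `r_squared`, `n`) and `pairs`
#'   (long data frame `parameter`, `z`, `baseline`, `followup` for
#'   scatter plots coloured by distance from the FM).
#' @export
reliability_regression <- function(baseline, followup, parameters = NULL) {
  if (length(baseline) != length(followup))
    stop_validation("baseline and follow-up must have matched subjects")
  parameters <- parameters %||%
    setdiff(Reduce(intersect, lapply(c(baseline, followup), names)), "z")
  pairs <- NULL
  for (i in seq_along(baseline)) {
    b <- baseline[[i]]; f <- followup[[i]]
    if (nrow(b) != nrow(f) || max(abs(b$z - f$z)) > 1e-9)
      stop_validation("baseline and follow-up profiles must share one z grid")
    for (nm in parameters)
      pairs <- rbind(pairs, data.frame(parameter = nm, z = b$z,
                                       baseline = b[[nm]], followup = f[[nm]]))
  }
  tab <- NULL
  for (nm in parameters) {
    pp <- pairs[pairs$parameter == nm & is.finite(pairs$baseline) &
                  is.finite(pairs$followup), ]
    if (nrow(pp) < 3L) stop_validation("fewer than 3 pairs for parameter ", nm)
    fit <- lm(followup ~ baseline, data = pp)
    tab <- rbind(tab, data.frame(parameter = nm,
                                 slope = unname(coef(fit)[2]),
                                 intercept = unname(coef(fit)[1]),
                                 # suppressWarnings: perfect-fit summary.lm
                                 r_squared = suppressWarnings(summary(fit)$r.squared),
                                 n = nrow(pp)))
  }
  structure(list(table = tab, pairs = pairs), class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat("<reliability_result>\n"); print(x$table, row.names = FALSE)
  invisible(x)
}

#' Reference chart of vertebral disc locations
#'
#' Mean (and SD) axial distance of each vertebral level caudal of the
#' foramen magnum for adult cynomolgus monkeys, FM through coccyx.  Users
#' working in other species can supply their own table of the same shape to
#' [vertebral_lookup()].
#'
#' @return Data frame with `level`, `z_mean` (mm), `z_sd` (mm), ordered
#'   cranially to caudally with strictly increasing `z_mean`.
#' @export
vertebral_table <- function() {
  data.frame(
    level = c("FM", "C1", "C2", "C3", "C4", "C5", "C6", "C7",
              "T1", "T2", "T3", "T4", "T5", "T6", "T7", "T8", "T9",
              "T10", "T11", "T12", "L1", "L2", "L3", "L4", "L5",
              "Sacrum", "coccyx"),
    z_mean = c(0.0, 5.7, 10.3, 22.3, 29.0, 35.2, 42.2, 48.7,
               56.1, 63.4, 72.0, 79.8, 88.5, 97.9, 107.4, 117.6, 128.8,
               141.4, 156.3, 172.0, 189.6, 207.5, 227.1, 247.0, 268.9,
               289.4, 301.0),
    z_sd = c(0.0, 2.4, 2.6, 3.9, 3.6, 3.8, 3.4, 3.8,
             4.2, 4.4, 4.2, 4.2, 4.5, 4.9, 4.5, 4.8, 4.5,
             5.4, 5.0, 5.1, 5.4, 5.8, 6.8, 7.0, 6.2,
             6.7, 6.8),
    stringsAsFactors = FALSE)
}

#' Vertebral level nearest an axial position
#'
#' Maps distance caudal of the foramen magnum to the nearest tabulated
#' vertebral disc level; exact ties go to the more cranial level.
#'
#' @param z axial position(s), mm caudal of the FM; must be >= 0.
#' @param table reference chart, default [vertebral_table()].
#' @return Character vector of level labels.
#' @export
vertebral_lookup <- function(z, table = vertebral_table()) {
  if (any(z < 0)) stop_validation("z must be nonnegative (caudal of the FM)")
  if (is.unsorted(table$z_mean, strictly = TRUE))
    stop_validation("table z_mean must be strictly increasing")
  vapply(z, function(zi) {
    d <- abs(table$z_mean - zi)
    table$level[which.min(d)]  # which.min takes the first = more cranial tie
  }, "")
}
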