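#' Read a study configuration (JSON)
#'
#' A configuration names one subject-session and its input files:
#' \preformatted{
#' {
#'   "subject": "NHP01", "session": "baseline",
#'   "segmentation": "labels.nii.gz",
#'   "velocity": ["slice1.csv", "slice2.csv", ...],
#'   "options": {"dz": 1, "sv_half": false, "smoothing": null,
#'               "mu_mPas": 0.693, "rho": 1000, "seed": 1}
#' }
#' }
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param path JSON file.
#' @return Object of class `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop_format("cannot read config: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  cfg$segmentation <- resolve(cfg$segmentation)
  cfg$velocity <- resolve(unlist(cfg$velocity))
  missing <- c(cfg$segmentation, cfg$velocity)
  missing <- missing[!file.exists(missing)]
  if (length(missing))
    stop_validation("referenced input files not found: ",
                    paste(missing, collapse = ", "))
  opts <- cfg$options %||% list()
  cfg$options <- list(dz = opts$dz %||% 1,
                      sv_half = isTRUE(opts$sv_half),
                      smoothing = opts$smoothing,
                      mu_mPas = opts$mu_mPas %||% 0.693,
                      rho = opts$rho %||% 1000,
                      seed = opts$seed)
  if (cfg$options$dz <= 0) stop_validation("dz must be positive")
  structure(cfg, class = "study_config")
}

#' Run the full single-subject pipeline
#'
#' Segmentation to profiles in one call: reads the label volume and the
#' per-slice velocity exports, builds the geometric profile and totals,
#' converts pixels to offset-corrected flow waveforms, normalises all
#' waveforms to the mean cycle period, fits the spatio-temporal surface,
#' estimates the pulse wave velocity, and evaluates the hydrodynamic
#' profile on every 1-mm level.
#'
#' @param segmentation path to the NIfTI label volume, or a
#'   [segmentation_volume()].
#' @param velocity character vector of velocity CSV paths, or a list of
#'   [velocity_roi()] objects.
#' @param dz axial grid spacing, mm.
#' @param fluid a [fluid_properties()].
#' @param smoothing fixed smoothing parameter(s) for
#'   [fit_spatiotemporal()], or `NULL` for REML selection.
#' @param sv_half passed to [waveform_features()].
#' @param label_map passed to [read_segmentation()].
#' @return Object of class `csf_subject`: `geometry` (profile), `totals`,
#'   `waveforms` (offset-corrected, common cycle), `offsets` (data frame
#'   `z`, `offset_ml_s`, `offset_pct`), `stf`, `arrival`, `pwv`
#'   (a `pulse_wave`), `hydro` (profile).
#' @export
analyze_subject <- function(segmentation, velocity, dz = 1,
                            fluid = fluid_properties(), smoothing = NULL,
                            sv_half = FALSE,
                            label_map = list(cord = 1L, dura = c(1L, 2L))) {
  seg <- if (inherits(segmentation, "segmentation_volume")) segmentation
         else read_segmentation(segmentation, label_map = label_map)
  geom <- slice_profiles(seg, dz = dz)
  totals <- geom_totals(geom, dz = dz)
  rois <- if (is.character(velocity)) lapply(velocity, read_velocity_csv)
          else velocity
  corr <- lapply(rois, function(r) offset_correct(waveform_from_pixels(r)))
  offsets <- data.frame(
    z = vapply(rois, function(r) r$z, 0),
    offset_ml_s = vapply(corr, function(x) x$offset, 0),
    offset_pct = vapply(corr, function(x) x$offset_pct, 0))
  T_common <- mean(vapply(rois, function(r) r$period, 0))
  waves <- lapply(corr, function(x) resample_cycle(x$waveform, T_common))
  stf <- fit_spatiotemporal(waves, dz = dz, smoothing = smoothing)
  arrival <- peak_arrival(stf)
  pwv <- pulse_wave_velocity(peak_arrival(stf, at = stf$source_z))
  hydro <- hydrodynamic_profile(stf, geom, fluid = fluid, sv_half = sv_half)
  structure(list(geometry = geom, totals = totals, waveforms = waves,
                 offsets = offsets, stf = stf, arrival = arrival,
                 pwv = pwv, hydro = hydro),
            class = "csf_subject")
}

#' @export
print.csf_subject <- function(x, ...) {
  cat("<csf_subject>\n")
  print(x$totals)
  print(x$pwv)
  cat(sprintf("  hydro profile: %d levels, max SV %.3f ml at z = %.0f mm\n",
              nrow(x$hydro), max(x$hydro$SV),
              x$hydro$z[which.max(x$hydro$SV)]))
  invisible(x)
}

#' Run the pipeline from a study configuration file
#'
#' @param config path to a JSON configuration ([read_study_config()]) or a
#'   `study_config` object.
#' @param out optional output directory: writes `profiles.csv`
#'   ([write_profiles()]), `surface.csv` (long-format z, t, Q) and
#'   `summary.json` (totals, PWV, offsets).
#' @return A `csf_subject` (invisibly when `out` is given).
#' @export
run_subject <- function(config, out = NULL) {
  cfg <- if (inherits(config, "study_config")) config else read_study_config(config)
  res <- analyze_subject(cfg$segmentation, cfg$velocity,
                         dz = cfg$options$dz,
                         fluid = fluid_properties(cfg$options$mu_mPas,
                                                  cfg$options$rho),
                         smoothing = cfg$options$smoothing,
                         sv_half = cfg$options$sv_half)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    keep <- res$geometry$z %in% res$hydro$z
    write_profiles(res$geometry[keep, ], res$hydro,
                   file.path(out, "profiles.csv"))
    surf <- data.frame(z = rep(res$stf$z, times = length(res$stf$t)),
                       t = rep(res$stf$t, each = length(res$stf$z)),
                       Q = as.vector(res$stf$Q))
    names(surf) <- c("z_mm", "t_s", "Q_ml_s")
    write.csv(surf, file.path(out, "surface.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(subject = cfg$subject, session = cfg$session,
           totals = unclass(res$totals),
           pwv_m_s = res$pwv$pwv, pwv_r_squared = res$pwv$r_squared,
           max_offset_pct = max(res$offsets$offset_pct, na.rm = TRUE)),
      file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    return(invisible(res))
  }
  res
}
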