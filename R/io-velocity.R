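#' Per-pixel velocity series for one PC-MRI region of interest
#'
#' One axial phase-contrast slice: through-plane velocity for every ROI
#' pixel at every cardiac phase, plus the acquisition metadata needed to
#' turn velocities into volumetric flow.
#'
#' @param velocity numeric matrix, pixels x phases, through-plane velocity
#'   in cm/s (caudal flow negative).
#' @param pixel_xy integer matrix, pixels x 2, in-plane pixel indices.
#' @param pixel_area area of one pixel in mm^2.
#' @param period cardiac cycle period T in s (R-R interval).
#' @param z slice position, mm caudal of the foramen magnum.
#' @param venc velocity-encoding limit in cm/s (metadata only), or `NA`.
#' @return An object of class `velocity_roi`.
#' @export
velocity_roi <- function(velocity, pixel_xy, pixel_area, period, z,
                         venc = NA_real_) {
  velocity <- as.matrix(velocity)
  if (nrow(velocity) < 1L) stop_validation("ROI must contain at least one pixel")
  if (!is.numeric(pixel_area) || pixel_area <= 0)
    stop_validation("pixel_area must be positive")
  if (!is.numeric(period) || period <= 0)
    stop_validation("cycle period must be positive")
  if (anyNA(velocity)) stop_validation("velocities contain NA")
  structure(list(velocity = velocity, pixel_xy = pixel_xy,
                 pixel_area = pixel_area, period = period, z = z,
                 venc = venc),
            class = "velocity_roi")
}

#' @export
print.velocity_roi <- function(x, ...) {
  cat(sprintf("<velocity_roi> z = %.1f mm, %d pixels x %d phases, T = %.3f s\n",
              x$z, nrow(x$velocity), ncol(x$velocity), x$period))
  invisible(x)
}

phase_cols <- function(n) sprintf("v%02d", seq_len(n) - 1L)

#' Read a per-pixel velocity export (CSV + JSON sidecar)
#'
#' The CSV carries one row per ROI pixel with columns `x,y,v00..vNN`
#' (velocities in cm/s, one column per cardiac phase).  The sidecar JSON
#' supplies what the scanner keeps in the image header: `pixel_area_mm2`,
#' `rr_ms` (R-R interval), `z_mm` (slice position caudal of the FM) and
#' optionally `venc_cm_s`.
#'
#' @param path path to the velocity CSV.
#' @param sidecar path to the metadata JSON; defaults to `path` with the
#'   extension replaced by `.json`.
#' @return A [velocity_roi()].
#' @export
read_velocity_csv <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop_format("cannot read velocity CSV: ", path)
  sidecar <- sidecar %||% paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar)) stop_format("missing sidecar metadata: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("pixel_area_mm2", "rr_ms", "z_mm"))
    if (is.null(meta[[f]])) stop_format("sidecar lacks field '", f, "'")
  if (meta$rr_ms <= 0) stop_validation("nonpositive R-R interval in sidecar")
  dat <- tryCatch(read.csv(path, check.names = FALSE),
                  error = function(e) stop_format("malformed velocity CSV: ",
                                                  conditionMessage(e)))
  nph <- sum(grepl("^v[0-9]{2}$", names(dat)))
  want <- c("x", "y", phase_cols(nph))
  if (nph < 2L || !all(want %in% names(dat)))
    stop_format("velocity CSV must have header x,y,v00..v", sprintf("%02d", max(nph - 1L, 1L)),
                " with contiguous phase columns")
  if (anyNA(dat[want])) stop_format("velocity CSV has ragged rows / missing values")
  velocity_roi(velocity = as.matrix(dat[phase_cols(nph)]),
               pixel_xy = as.matrix(dat[c("x", "y")]),
               pixel_area = meta$pixel_area_mm2,
               period = meta$rr_ms / 1000,
               z = meta$z_mm,
               venc = meta$venc_cm_s %||% NA_real_)
}

#' Write a velocity ROI series as CSV + JSON sidecar
#'
#' Inverse of [read_velocity_csv()]; a written file re-reads to identical
#' values (velocities are written in full precision).
#'
#' @param roi a [velocity_roi()].
#' @param path output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_velocity_csv <- function(roi, path) {
  stopifnot(inherits(roi, "velocity_roi"))
  v <- roi$velocity
  dat <- data.frame(x = roi$pixel_xy[, 1], y = roi$pixel_xy[, 2])
  dat[phase_cols(ncol(v))] <- as.data.frame(v)
  write.csv(format(dat, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(pixel_area_mm2 = roi$pixel_area,
                            rr_ms = roi$period * 1000,
                            z_mm = roi$z,
                            venc_cm_s = roi$venc),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
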