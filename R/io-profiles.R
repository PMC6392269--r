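# Profile CSV dialect: column names carry units as suffixes so a table is
# self-describing (z_mm, A_sas_mm2, Q_sys_ml_s, ...); Re and alpha are
# dimensionless and keep bare names.

.unit_suffix <- c(z = "mm",
                  A_c = "mm2", A_d = "mm2", A_sas = "mm2",
                  P_c = "mm", P_d = "mm", P_sas = "mm", D_h = "mm",
                  SV = "ml",
                  Q_sys = "ml_s", Q_dia = "ml_s", Q_a = "ml_s",
                  U_sys = "cm_s", U_dia = "cm_s")

encode_colname <- function(nm) {
  sfx <- .unit_suffix[nm]
  ifelse(is.na(sfx), nm, paste(nm, sfx, sep = "_"))
}

decode_colname <- function(nm) {
  for (base in names(.unit_suffix)) {
    full <- paste(base, .unit_suffix[base], sep = "_")
    nm[nm == full] <- base
  }
  nm
}

#' Write per-level profiles to CSV
#'
#' Joins geometric and (optionally) hydrodynamic profiles on their shared z
#' grid and writes one row per level with units encoded in the header
#' (`z_mm`, `A_sas_mm2`, ...).  A written file re-reads to the same values
#' ([read_profiles()]); an empty profile yields a header-only file.
#'
#' @param geom a `geometric_profile` (or any data frame with `z`).
#' @param hydro optional `hydrodynamic_profile` on the same grid.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(geom, hydro = NULL, path) {
  out <- as.data.frame(geom)
  if (!is.null(hydro)) {
    if (nrow(hydro) != nrow(geom) || max(abs(hydro$z - geom$z)) > 1e-9)
      stop_validation("geometric and hydrodynamic profiles must share one z grid")
    out <- cbind(out, hydro[setdiff(names(hydro), "z")])
  }
  names(out) <- encode_colname(names(out))
  write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a profile CSV written by [write_profiles()]
#'
#' @param path CSV path.
#' @return Data frame with unit suffixes stripped from the column names.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop_format("cannot read profile CSV: ", path)
  dat <- read.csv(path, check.names = FALSE)
  names(dat) <- decode_colname(names(dat))
  dat
}

#' Import a deposited parameter workbook
#'
#' Reads axial parameter distributions deposited as one table per
#' parameter: the first column is axial distance (mm caudal of the FM) and
#' every further column is one subject-session.  Two containers are
#' accepted: an `.xlsx` workbook (one sheet per parameter; requires the
#' `readxl` package) or a directory of per-parameter CSV files with the
#' identical layout.  Sheets/files are mapped to parameter names by
#' `pattern` (a named character vector of regular expressions); unmatched
#' sheets keep their own name.  The mapping is logged.
#'
#' @param path workbook path or directory.
#' @param pattern named character vector: `c(parameter = "regex")`.
#' @return Named list of data frames, each `z` plus one column per
#'   subject-session.
#' @export
import_param_workbook <- function(path, pattern = character()) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0L) stop_format("no CSV tables in ", path)
    sheets <- tools::file_path_sans_ext(basename(files))
    readers <- lapply(files, function(f) function() read.csv(f, check.names = FALSE))
  } else if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop_format("reading .xlsx requires the 'readxl' package")
    sheets <- readxl::excel_sheets(path)
    readers <- lapply(sheets, function(s)
      function() as.data.frame(readxl::read_excel(path, sheet = s)))
  } else stop_format("expected an .xlsx workbook or a directory of CSVs: ", path)
  out <- list()
  for (i in seq_along(sheets)) {
    nm <- sheets[i]
    for (p in names(pattern))
      if (grepl(pattern[p], sheets[i], ignore.case = TRUE)) { nm <- p; break }
    dat <- readers[[i]]()
    if (ncol(dat) < 2L)
      stop_format("table '", sheets[i], "' needs a z column plus >= 1 value column")
    names(dat)[1] <- "z"
    csf_log("workbook table '", sheets[i], "' imported as parameter '", nm, "'")
    out[[nm]] <- dat
  }
  out
}
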