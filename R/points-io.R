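# Plain-text landmark points files: an integer count header followed by one
# whitespace-separated "x y" pair per line. BOM and CRLF line endings are
# tolerated on read.

#' Read a landmark points file
#'
#' @param path Path to a points file (count header, then one `x y` pair per
#'   line, coordinates in mm).
#' @param schema A [hip_schema()]; the file's point count must match.
#' @param subject_id Subject identifier attached to the returned tibble;
#'   defaults to the file name without extension.
#' @param flip_y If `TRUE`, negate y on read. Use for image-native
#'   y-down coordinates so that the package's y-superior-positive convention
#'   holds (the centre-edge angle and alpha-angle need an unambiguous
#'   "superior").
#'
#' @return A landmark tibble (`subject_id`, `point`, `x`, `y`).
#' @export
read_points <- function(path, schema = hip_schema(),
                        subject_id = NULL, flip_y = FALSE) {
  if (!file.exists(path)) abort(paste0("Points file not found: ", path))
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines)) {
    lines[1] <- sub("^﻿", "", lines[1]) # BOM
  }
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) abort(paste0("Empty points file: ", path))
  n_declared <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n_declared)) {
    abort(paste0("Parse error in ", path, ", line 1: expected an integer point-count header."))
  }
  body <- lines[-1]
  if (length(body) != n_declared) {
    abort(paste0("Schema mismatch in ", path, ": header declares ", n_declared,
                 " points but file has ", length(body), " data lines."))
  }
  if (n_declared != schema$n_points) {
    abort(paste0("Schema mismatch in ", path, ": file has ", n_declared,
                 " points, schema expects ", schema$n_points, "."))
  }
  xy <- matrix(NA_real_, n_declared, 2)
  for (i in seq_along(body)) {
    tok <- strsplit(trimws(body[i]), "[[:space:],]+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (length(val) != 2 || anyNA(val)) {
      abort(paste0("Parse error in ", path, ", line ", i + 1,
                   ": expected two numeric tokens, got \"", body[i], "\"."))
    }
    xy[i, ] <- val
  }
  if (flip_y) xy[, 2] <- -xy[, 2]
  out <- tibble(subject_id = subject_id, point = seq_len(n_declared),
                x = xy[, 1], y = xy[, 2])
  validate_landmarks(out, schema)
  out
}

#' Write a landmark points file
#'
#' Inverse of [read_points()]: writes the count header followed by one
#' fixed-precision `x y` pair per line. Round-trips coordinates to the stored
#' precision.
#'
#' @param landmarks Landmark tibble for a single subject.
#' @param path Output path.
#' @param digits Number of decimal places stored (default 4; ~0.1 um, far
#'   below annotation precision).
#' @return `path`, invisibly.
#' @export
write_points <- function(landmarks, path, digits = 4) {
  if (nrow(landmarks) == 0) abort("Refusing to write an empty landmark configuration.")
  if (length(unique(landmarks$subject_id)) != 1) {
    abort("`write_points()` writes one subject per file.")
  }
  landmarks <- landmarks[order(landmarks$point), ]
  lines <- c(
    as.character(nrow(landmarks)),
    sprintf(paste0("%.", digits, "f %.", digits, "f"), landmarks$x, landmarks$y)
  )
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) abort(paste0("Cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# ---- cohort tables -----------------------------------------------------------

cohort_required_cols <- function() {
  c("subject_id", "age", "sex", "height", "weight", "ethnicity_white",
    "osteo_area_lat_acetabulum", "osteo_area_sup_lat_head",
    "osteo_area_inf_med_head", "hoa_hospital", "thr_event", "thr_time")
}

#' Read a cohort covariate/outcome table
#'
#' Reads a CSV of per-subject covariates (age in years, sex `"M"`/`"F"`,
#' height in cm, weight in kg, binary white/other ethnicity), osteophyte areas
#' in mm^2 at the three graded sites, and outcomes (hospital-diagnosed hip OA
#' flag, total-hip-replacement event flag and follow-up time in years).
#' Rows with missing values in any mandatory column are dropped
#' (complete-case analysis) and the exclusion count is reported.
#'
#' @param path CSV path.
#' @return A tibble of complete-case rows with attributes `n_input` and
#'   `n_excluded`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("Cohort file not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(cohort_required_cols(), names(tab))
  if (length(miss)) {
    abort(paste0("Cohort table is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")))
  }
  n_input <- nrow(tab)
  keep <- complete.cases(tab[cohort_required_cols()])
  out <- tab[keep, , drop = FALSE]
  if (any(out$height <= 0) || any(out$weight <= 0)) {
    abort("Heights and weights must be positive.")
  }
  if (any(out$thr_time < 0)) abort("`thr_time` must be non-negative.")
  n_excluded <- n_input - nrow(out)
  inform(paste0("read_cohort: ", n_input, " rows read, ", n_excluded,
                " excluded (incomplete), ", nrow(out), " analyzed."))
  attr(out, "n_input") <- n_input
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write a cohort table to CSV
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}
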