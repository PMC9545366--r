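# Radiographic hip OA grading: osteophyte areas at three sites and
# (height-adjusted) minimum joint-space width are converted to ordinal
# grades, summed to a 0-12 score, and mapped to an overall rHOA grade.

#' Grading configuration for radiographic hip OA
#'
#' The area thresholds, joint-space-narrowing thresholds and the
#' sum-to-overall-grade map are not universal constants; the defaults here
#' are documented placeholders that keep the pipeline runnable and are pinned
#' by the package's tests. All are configurable.
#'
#' Boundary convention: a value exactly equal to a cut-point takes the lower
#' grade (osteophyte grade = number of thresholds *strictly* exceeded; JSN
#' grade = number of thresholds the adjusted mJSW falls *strictly* below).
#'
#' @param osteophyte_thresholds Named list of length-3 ascending mm^2
#'   cut-points, one per site (`lat_acetabulum`, `sup_lat_head`,
#'   `inf_med_head`), or a single numeric vector recycled to all sites.
#' @param jsn_thresholds Descending mm cut-points on height-adjusted mJSW for
#'   JSN grades 1, 2, 3.
#' @param overall_map Integer vector of length 13 mapping total scores 0..12
#'   to overall rHOA grades (must be exhaustive).
#' @return An object of class `rhoa_grading_config`.
#' @export
grading_config <- function(osteophyte_thresholds = c(1, 4, 9),
                           jsn_thresholds = c(2.5, 2.0, 1.5),
                           overall_map = c(0L, 1L, 1L, 2L, 2L,
                                           3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L)) {
  sites <- c("lat_acetabulum", "sup_lat_head", "inf_med_head")
  if (!is.list(osteophyte_thresholds)) {
    osteophyte_thresholds <- setNames(rep(list(osteophyte_thresholds), 3), sites)
  }
  if (!setequal(names(osteophyte_thresholds), sites)) {
    abort(paste0("`osteophyte_thresholds` must name the sites: ",
                 paste(sites, collapse = ", ")))
  }
  for (s in sites) {
    th <- osteophyte_thresholds[[s]]
    if (length(th) != 3 || any(diff(th) <= 0)) {
      abort("Each site needs 3 strictly increasing area thresholds (mm^2).")
    }
  }
  if (length(jsn_thresholds) != 3 || any(diff(jsn_thresholds) >= 0)) {
    abort("`jsn_thresholds` must be 3 strictly decreasing mm cut-points.")
  }
  if (length(overall_map) != 13 || anyNA(overall_map)) {
    abort("`overall_map` must map every total score 0..12 (length 13, no NA).")
  }
  structure(
    list(osteophyte_thresholds = osteophyte_thresholds,
         jsn_thresholds = jsn_thresholds,
         overall_map = as.integer(overall_map)),
    class = "rhoa_grading_config"
  )
}

#' Grade an osteophyte by area
#'
#' Grade 0-3 as the number of site-specific area thresholds strictly
#' exceeded; an area equal to a cut-point takes the lower grade.
#'
#' @param area_mm2 Osteophyte area(s), mm^2 (vectorised).
#' @param site One of `"lat_acetabulum"`, `"sup_lat_head"`, `"inf_med_head"`.
#' @param config A [grading_config()].
#' @return Integer grade(s) 0-3.
#' @export
grade_osteophyte <- function(area_mm2, site = "lat_acetabulum",
                             config = grading_config()) {
  if (any(area_mm2 < 0)) abort("Osteophyte areas must be non-negative.")
  th <- config$osteophyte_thresholds[[match.arg(
    site, names(config$osteophyte_thresholds))]]
  rowSums(outer(area_mm2, th, ">"))
}

#' Height-adjust minimum joint-space width
#'
#' Removes the linear dependence of mJSW on standing height: returns the
#' residual from the least-squares regression of mJSW on height plus the
#' cohort mean mJSW, so adjusted values are height-decorrelated but keep the
#' original scale and centre. With (near) zero height variance the
#' adjustment is skipped with a warning and raw values are returned.
#'
#' @param mjsw mJSW values, mm.
#' @param height Standing heights, cm (same length).
#' @return Adjusted mJSW values, mm.
#' @export
height_adjust_mjsw <- function(mjsw, height) {
  if (length(mjsw) != length(height)) abort("`mjsw` and `height` lengths differ.")
  if (length(mjsw) < 10) abort("Height adjustment needs >= 10 subjects.")
  if (sd(height) < 1e-10) {
    warn("Zero height variance; mJSW height adjustment skipped.")
    return(mjsw)
  }
  fit <- lm(mjsw ~ height)
  as.numeric(residuals(fit)) + mean(mjsw)
}

grade_jsn <- function(adjusted_mjsw, config = grading_config()) {
  rowSums(outer(adjusted_mjsw, config$jsn_thresholds, "<"))
}

#' Combine site osteophyte grades and JSN grade into an overall rHOA grade
#'
#' Sums the three site grades and the joint-space-narrowing grade into a
#' total score 0-12, maps the total to an overall grade, and sets the two
#' mutually exclusive binary outcome flags (grade 2 only; grade >= 3).
#'
#' @param osteophyte_grades Length-3 integer vector (or 3-column matrix, one
#'   row per subject) of site grades 0-3.
#' @param jsn_grade Integer grade(s) 0-3.
#' @param config A [grading_config()].
#' @return Tibble with `osteo_grade_*`, `jsn_grade`, `total_score`,
#'   `overall_grade`, `rhoa_grade2_only`, `rhoa_ge3`.
#' @export
grade_rhoa <- function(osteophyte_grades, jsn_grade, config = grading_config()) {
  g <- if (is.matrix(osteophyte_grades)) osteophyte_grades else
    matrix(osteophyte_grades, nrow = 1)
  if (ncol(g) != 3) abort("Expected 3 site osteophyte grades.")
  if (any(g < 0 | g > 3) || any(jsn_grade < 0 | jsn_grade > 3)) {
    abort("All grades must lie in 0..3.")
  }
  total <- rowSums(g) + jsn_grade
  if (any(total < 0 | total > 12)) abort("Total score outside the mapped 0..12 range.")
  overall <- config$overall_map[total + 1]
  tibble(
    osteo_grade_lat_acetabulum = g[, 1],
    osteo_grade_sup_lat_head = g[, 2],
    osteo_grade_inf_med_head = g[, 3],
    jsn_grade = as.integer(jsn_grade),
    total_score = as.integer(total),
    overall_grade = as.integer(overall),
    rhoa_grade2_only = as.integer(overall == 2L),
    rhoa_ge3 = as.integer(overall >= 3L)
  )
}

#' Grade a whole cohort from measures and osteophyte areas
#'
#' Convenience wrapper: grades the three osteophyte areas, height-adjusts
#' mJSW over the cohort, grades joint-space narrowing, and returns the
#' per-subject grading table.
#'
#' @param measures Per-subject measures from [measure_hips()] (needs `mjsw`).
#' @param cohort Cohort tibble with `subject_id`, `height` and the three
#'   `osteo_area_*` columns.
#' @param config A [grading_config()].
#' @return Tibble: `subject_id`, adjusted mJSW, grades and flags.
#' @export
grade_cohort <- function(measures, cohort, config = grading_config()) {
  df <- inner_join(
    select(measures, "subject_id", "mjsw"),
    select(cohort, "subject_id", "height", starts_with("osteo_area_")),
    by = "subject_id"
  )
  g <- cbind(
    grade_osteophyte(df$osteo_area_lat_acetabulum, "lat_acetabulum", config),
    grade_osteophyte(df$osteo_area_sup_lat_head, "sup_lat_head", config),
    grade_osteophyte(df$osteo_area_inf_med_head, "inf_med_head", config)
  )
  adj <- height_adjust_mjsw(df$mjsw, df$height)
  jsn <- grade_jsn(adj, config)
  bind_cols(tibble(subject_id = df$subject_id, mjsw_adjusted = adj),
            grade_rhoa(g, jsn, config))
}
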