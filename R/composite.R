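# Composite "OA risk shapes": all modes associated with an outcome below the
# multiplicity-corrected p threshold are combined into one shape offset,
# beta (log-odds/log-hazard per SD) x raw mode SD x a visual factor, added to
# the mean shape.

#' Build a composite shape for one outcome
#'
#' Selects the modes whose association p value is strictly below
#' `p_threshold` for `outcome`, and combines their log-scale coefficients
#' into a single offset vector:
#' `offset = sum(beta_i * raw_sd_i * factor * mode_i)`. The raw mode SD
#' weights each mode by its contribution to overall shape variance; the
#' factor (default 5) exaggerates the displacement for visualisation only and
#' is stored so the rendering is never mistaken for physical mm.
#'
#' With no significant modes the composite equals the mean shape with an
#' empty inclusion list (not an error).
#'
#' @param model A fitted [fit_shape_model()].
#' @param results Association tibble (from [fit_hsm_logistic()] /
#'   [fit_hsm_cox()]), containing `log_effect` and `p_value`.
#' @param outcome Outcome name to select from `results`.
#' @param factor Visual multiplication factor (default 5).
#' @param p_threshold Inclusion threshold (default 0.005 = 0.05 / 10 modes).
#' @return Object of class `hip_composite`: `outcome`, `included_hsms`,
#'   `coefficients`, `factor`, `offset` (2p vector), `mean_points` and
#'   `composite_points` (landmark tibbles, aligned frame).
#' @export
build_composite <- function(model, results, outcome, factor = 5,
                            p_threshold = 0.005) {
  res <- results[results$outcome == outcome & results$estimable, , drop = FALSE]
  res <- res[!is.na(res$p_value) & res$p_value < p_threshold, , drop = FALSE]
  offset <- numeric(length(model$mean_shape))
  if (nrow(res)) {
    w <- res$log_effect * model$raw_sd[res$hsm] * factor
    offset <- drop(model$modes[, res$hsm, drop = FALSE] %*% w)
  }
  comp <- model$mean_shape + offset
  structure(
    list(outcome = outcome, included_hsms = res$hsm,
         coefficients = res$log_effect, factor = factor, offset = offset,
         mean_points = xy_to_landmarks(vec_to_xy(model$mean_shape), "mean"),
         composite_points = xy_to_landmarks(vec_to_xy(comp),
                                            paste0("composite_", outcome))),
    class = "hip_composite"
  )
}

#' @export
print.hip_composite <- function(x, ...) {
  cat("<hip_composite> outcome ", x$outcome, ": ",
      length(x$included_hsms), " mode(s) included",
      if (length(x$included_hsms)) paste0(" (", paste(x$included_hsms, collapse = ", "), ")"),
      ", factor ", x$factor, "\n", sep = "")
  invisible(x)
}

#' Plot mean versus composite outline(s)
#'
#' @param object A `hip_composite`, or a list of them (e.g. one per outcome
#'   or sex stratum) to overlay on the shared mean.
#' @param ... Unused.
#' @return A ggplot object (closed-polyline style outlines, legend by group).
#' @exportS3Method ggplot2::autoplot
autoplot.hip_composite <- function(object, ...) {
  composites <- if (inherits(object, "hip_composite")) list(object) else object
  shapes <- bind_rows(
    composites[[1]]$mean_points,
    list_rbind(map(composites, function(cc) cc$composite_points))
  )
  plot_outline(shapes) +
    labs(title = "Mean versus composite hip shape",
         subtitle = sprintf("visual factor %s (exaggerated, not mm)",
                            paste(unique(map_dbl(composites, "factor")),
                                  collapse = "/")),
         colour = NULL)
}

#' Render mean and composite outlines to a file
#'
#' @param composites A `hip_composite` or list of them.
#' @param path Output file (format by extension, e.g. `.pdf`, `.png`).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_outlines <- function(composites, path, width = 5, height = 5) {
  p <- autoplot.hip_composite(composites)
  ok <- tryCatch({
    ggsave(path, plot = p, width = width, height = height)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(paste0("Could not write outline plot to: ", path))
  invisible(path)
}
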