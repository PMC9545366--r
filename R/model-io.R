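# JSON serialisation of fitted shape models (mean, modes, per-mode SDs,
# variance fractions, alignment settings).

#' Write a fitted shape model to JSON
#'
#' @param model A [fit_shape_model()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shape_model <- function(model, path) {
  obj <- list(
    n_points = model$n_points,
    mean_shape = model$mean_shape,
    modes = model$modes,
    raw_sd = model$raw_sd,
    var_frac = model$var_frac,
    k = model$k,
    n_effective = model$n_effective,
    allow_scaling = model$alignment$allow_scaling
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a shape model from JSON
#'
#' Restores a model written by [write_shape_model()]; training scores and
#' subject lists are not serialised.
#'
#' @param path JSON path.
#' @return A `hip_shape_model` (without training scores).
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(mean_shape = obj$mean_shape, modes = obj$modes, raw_sd = obj$raw_sd,
         var_frac = obj$var_frac, k = obj$k, n_effective = obj$n_effective,
         alignment = list(allow_scaling = obj$allow_scaling, iterations = NA),
         scores = NULL, subjects = NULL, n_points = obj$n_points),
    class = "hip_shape_model"
  )
}

#' Match fitted modes to generating deformation fields
#'
#' For a model fitted on synthetic data, identifies which fitted mode best
#' matches each generating field by the largest absolute cosine between the
#' fitted mode vector and the field vector.
#'
#' @param model A fitted [fit_shape_model()].
#' @param shape_spec The [generative_shape_spec()] used to simulate.
#' @return Tibble: `mode` (generating name), `hsm` (fitted index),
#'   `cosine` (signed; negative means the fitted mode points opposite to the
#'   generating field, so fitted scores anti-correlate with generating
#'   scores), `abs_cosine`.
#' @export
match_modes <- function(model, shape_spec) {
  # fitted modes live in the Procrustes-aligned (unit-size) frame; cosines
  # are scale-free so the generating fields can be compared directly
  cosmat <- crossprod(shape_spec$modes, model$modes[, seq_len(model$k), drop = FALSE])
  best <- apply(abs(cosmat), 1, which.max)
  tibble(
    mode = shape_spec$mode_names,
    hsm = best,
    cosine = cosmat[cbind(seq_along(best), best)],
    abs_cosine = abs(cosmat[cbind(seq_along(best), best)])
  )
}
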