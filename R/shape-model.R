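#' Fit a statistical shape model (hip shape modes)
#'
#' Runs generalized Procrustes alignment ([gpa_align()]) followed by principal
#' component analysis of the aligned point coordinates. The principal
#' components are the hip shape modes: an orthonormal basis of deformations
#' ordered by explained variance. Raw per-mode score SDs (the
#' "non-standardized mode-specific SDs") and variance fractions are stored;
#' scores are standardized to mean 0, SD 1 over the training set.
#'
#' A deterministic sign convention is applied: each mode's element of largest
#' absolute value is made positive, so refits of the same data give identical
#' models.
#'
#' @param landmarks Landmark tibble (>= 2 subjects).
#' @param schema A [hip_schema()].
#' @param allow_scaling Passed to [gpa_align()].
#' @param k Number of modes retained for analysis (default 10, or fewer if
#'   the data support fewer); the full basis is stored regardless.
#' @return An object of class `hip_shape_model` with elements `mean_shape`
#'   (2p vector, aligned frame), `modes` (2p x K orthonormal matrix),
#'   `raw_sd`, `var_frac`, `k`, `alignment` (settings record), `scores`
#'   (training-set standardized scores, long tibble), `subjects`.
#' @export
#' @examples
#' sim <- sample_cohort(n = 50, seed = 1)
#' mod <- fit_shape_model(sim$landmarks)
#' glance(mod)
fit_shape_model <- function(landmarks, schema = hip_schema(),
                            allow_scaling = TRUE, k = 10) {
  gpa <- gpa_align(landmarks, schema, allow_scaling = allow_scaling)
  if (nrow(gpa$aligned) < 2) abort("Shape model needs at least 2 subjects.")
  pca <- prcomp(gpa$aligned, center = TRUE, scale. = FALSE)

  modes <- pca$rotation
  scores <- pca$x
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(modes))) {
    i <- which.max(abs(modes[, j]))
    if (modes[i, j] < 0) {
      modes[, j] <- -modes[, j]
      scores[, j] <- -scores[, j]
    }
  }
  raw_sd <- pca$sdev
  total_var <- sum(raw_sd^2)
  if (total_var <= 0) {
    var_frac <- rep(0, length(raw_sd))
  } else {
    var_frac <- raw_sd^2 / total_var
  }
  n_effective <- sum(raw_sd > max(raw_sd[1] * 1e-8, 1e-12))
  k_ret <- min(k, max(n_effective, 1L), ncol(modes))

  std <- scores
  for (j in seq_len(ncol(std))) {
    std[, j] <- if (raw_sd[j] > 0) scores[, j] / raw_sd[j] else 0
  }
  score_tbl <- tibble(
    subject_id = rep(gpa$subjects, times = ncol(std)),
    hsm = rep(seq_len(ncol(std)), each = nrow(std)),
    score_raw = as.vector(scores),
    score_std = as.vector(std)
  ) |> filter(.data$hsm <= k_ret)

  structure(
    list(mean_shape = as.numeric(pca$center), modes = modes, raw_sd = raw_sd,
         var_frac = var_frac, k = k_ret, n_effective = n_effective,
         alignment = list(allow_scaling = allow_scaling,
                          iterations = gpa$iterations,
                          gpa_mean = gpa$mean),
         scores = score_tbl, subjects = gpa$subjects,
         n_points = gpa$n_points),
    class = "hip_shape_model"
  )
}

#' Score landmark configurations against a fitted shape model
#'
#' Each configuration is aligned to the model's mean shape (translation,
#' rotation and, if the model removed scale, scaling), the mean is
#' subtracted, and the residual is projected onto the mode basis. Raw scores
#' are standardized by the training-set mode SDs.
#'
#' @param landmarks Landmark tibble.
#' @param model A fitted [fit_shape_model()] object.
#' @param schema A [hip_schema()].
#' @return Long tibble: `subject_id`, `hsm`, `score_raw`, `score_std` for the
#'   model's retained modes.
#' @export
score_shapes <- function(landmarks, model, schema = hip_schema()) {
  if (!inherits(model, "hip_shape_model")) {
    abort("`model` must be a fitted hip_shape_model (fit the model before scoring).")
  }
  cm <- landmark_coord_matrices(landmarks, schema)
  k <- model$k
  out <- vector("list", length(cm$subjects))
  for (i in seq_along(cm$subjects)) {
    m <- cbind(cm$X[i, ], cm$Y[i, ])
    v <- align_config_to_mean(m, model$mean_shape,
                              model$alignment$allow_scaling)
    raw <- unname(drop(crossprod(model$modes[, seq_len(k), drop = FALSE],
                                 v - model$mean_shape)))
    std <- ifelse(model$raw_sd[seq_len(k)] > 0,
                  raw / model$raw_sd[seq_len(k)], 0)
    out[[i]] <- tibble(subject_id = cm$subjects[i], hsm = seq_len(k),
                       score_raw = raw, score_std = std)
  }
  list_rbind(out)
}

#' Reconstruct a landmark configuration from mode scores
#'
#' Returns `mean + sum(z_i * mode_i)` over the first `n_modes` modes, in the
#' aligned frame.
#'
#' @param model A fitted [fit_shape_model()].
#' @param z_raw Numeric vector of raw (unstandardized) mode scores; length
#'   must not exceed `n_modes`.
#' @param n_modes Number of modes used (default `length(z_raw)`); must not
#'   exceed the model's full basis.
#' @param subject_id Identifier for the returned configuration.
#' @return A landmark tibble in the aligned frame.
#' @export
reconstruct_shape <- function(model, z_raw, n_modes = length(z_raw),
                              subject_id = "reconstruction") {
  K <- ncol(model$modes)
  if (n_modes > K) abort(paste0("`n_modes` exceeds the model's ", K, " modes."))
  if (length(z_raw) > n_modes) abort("`z_raw` is longer than `n_modes`.")
  z <- numeric(n_modes)
  z[seq_along(z_raw)] <- z_raw
  v <- model$mean_shape +
    drop(model$modes[, seq_len(n_modes), drop = FALSE] %*% z)
  xy_to_landmarks(vec_to_xy(v), subject_id = subject_id)
}

#' Pivot long mode scores to one column per mode
#'
#' @param scores Long score tibble from [score_shapes()].
#' @param which Score column to spread, `"score_std"` (default) or
#'   `"score_raw"`.
#' @return Wide tibble with columns `subject_id`, `hsm1`, `hsm2`, ...
#' @export
hsm_wide <- function(scores, which = "score_std") {
  scores |>
    mutate(hsm = sprintf("hsm%d", .data$hsm)) |>
    select("subject_id", "hsm", all_of(which)) |>
    pivot_wider(names_from = "hsm", values_from = all_of(which))
}

#' @export
print.hip_shape_model <- function(x, ...) {
  cat("<hip_shape_model> ", length(x$subjects), " subjects, ", x$n_points,
      " points, ", x$n_effective, " effective mode(s), ", x$k, " retained\n",
      sep = "")
  cat("  top-10 cumulative variance: ",
      sprintf("%.1f%%", 100 * sum(x$var_frac[seq_len(min(10, length(x$var_frac)))])),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted shape model: one row per mode
#'
#' @param x A `hip_shape_model`.
#' @param ... Unused.
#' @return Tibble with `hsm`, `raw_sd`, `var_frac`, `cum_var_frac`.
#' @exportS3Method generics::tidy
tidy.hip_shape_model <- function(x, ...) {
  tibble(hsm = seq_along(x$raw_sd), raw_sd = x$raw_sd, var_frac = x$var_frac,
         cum_var_frac = cumsum(x$var_frac))
}

#' One-row summary of a fitted shape model
#'
#' @param x A `hip_shape_model`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.hip_shape_model <- function(x, ...) {
  tibble(
    n_subjects = length(x$subjects), n_points = x$n_points,
    k_retained = x$k, n_effective_modes = x$n_effective,
    cum_var_top10 = sum(x$var_frac[seq_len(min(10, length(x$var_frac)))]),
    allow_scaling = x$alignment$allow_scaling,
    gpa_iterations = x$alignment$iterations
  )
}

#' Plot a shape mode as mean +/- a multiple of its SD
#'
#' @param object A `hip_shape_model`.
#' @param hsm Mode index to display.
#' @param sd_multiple Score offset in raw-SD units (default 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hip_shape_model <- function(object, hsm = 1, sd_multiple = 3, ...) {
  offs <- c(-sd_multiple, 0, sd_multiple)
  shapes <- list_rbind(map(offs, function(s) {
    z <- numeric(hsm)
    z[hsm] <- s * object$raw_sd[hsm]
    reconstruct_shape(object, z, n_modes = hsm,
                      subject_id = sprintf("%+.0f SD", s))
  }))
  plot_outline(shapes) +
    labs(title = sprintf("Hip shape mode %d (%.1f%% of variance)",
                         hsm, 100 * object$var_frac[hsm]),
         colour = "score")
}

# shared outline plotting: femur points 1..77 as one path, acetabulum 78..85
# as another, grouped and coloured by subject_id
plot_outline <- function(landmarks, acetab_from = 78) {
  landmarks <- landmarks |>
    mutate(segment = ifelse(.data$point >= acetab_from, "acetabulum", "femur"))
  ggplot(landmarks, aes(x = .data$x, y = .data$y, colour = .data$subject_id,
                        group = interaction(.data$subject_id, .data$segment))) +
    geom_path(linewidth = 0.5) +
    coord_equal() +
    labs(x = "x (medial +, mm or aligned units)",
         y = "y (superior +, mm or aligned units)") +
    theme_minimal()
}
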