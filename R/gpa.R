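# Generalized Procrustes analysis for 2-D landmark sets. The optimal 2-D
# rotation of a centred shape onto a target has the closed form
# theta = atan2(sum(x*my - y*mx), sum(x*mx + y*my)), which lets the whole
# cohort be rotated with vectorised matrix products.

# rotate each row-shape (X, Y are n x p coordinate matrices) onto the target
# (mx, my length-p vectors); returns rotated X, Y
rotate_onto <- function(X, Y, mx, my) {
  a <- X %*% mx + Y %*% my
  b <- X %*% my - Y %*% mx
  th <- atan2(b, a)
  cs <- cos(th)[, 1]
  sn <- sin(th)[, 1]
  list(X = cs * X - sn * Y, Y = sn * X + cs * Y)
}

#' Generalized Procrustes alignment of landmark configurations
#'
#' Iteratively removes translation, rotation and (optionally) scale from a
#' set of landmark configurations: all shapes are centred (and scaled to unit
#' centroid size when `allow_scaling`), then alternately rotated onto the
#' current mean shape until the mean changes by less than `tol` (or
#' `max_iter` iterations). The mean shape is centred at the origin and, with
#' scaling, has unit centroid size.
#'
#' @param landmarks Landmark tibble (>= 2 subjects).
#' @param schema A [hip_schema()].
#' @param allow_scaling Remove size by scaling each shape to unit centroid
#'   size (default `TRUE`, classical shape-model practice). Millimetre
#'   measures are always taken in original coordinates, never the aligned
#'   frame.
#' @param tol Convergence tolerance on the root-mean-square change of the
#'   mean shape.
#' @param max_iter Maximum number of alignment sweeps.
#' @return An object of class `hip_gpa`: `aligned` (n x 2p matrix of
#'   interleaved aligned coordinates), `mean` (2p vector), `subjects`,
#'   `centroid_sizes`, `allow_scaling`, `iterations`.
#' @export
gpa_align <- function(landmarks, schema = hip_schema(), allow_scaling = TRUE,
                      tol = 1e-10, max_iter = 100) {
  cm <- landmark_coord_matrices(landmarks, schema)
  X <- cm$X
  Y <- cm$Y
  n <- nrow(X)
  if (n < 2) abort("Generalized Procrustes alignment needs at least 2 configurations.")

  X <- X - rowMeans(X)
  Y <- Y - rowMeans(Y)
  sizes <- sqrt(rowSums(X^2) + rowSums(Y^2))
  if (any(sizes < 1e-12)) {
    abort("Degenerate configuration: all points coincident (zero centroid size).")
  }
  if (allow_scaling) {
    X <- X / sizes
    Y <- Y / sizes
  }

  mx <- X[1, ]
  my <- Y[1, ]
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    r <- rotate_onto(X, Y, mx, my)
    X <- r$X
    Y <- r$Y
    nmx <- colMeans(X)
    nmy <- colMeans(Y)
    nmx <- nmx - mean(nmx)
    nmy <- nmy - mean(nmy)
    if (allow_scaling) {
      s <- sqrt(sum(nmx^2) + sum(nmy^2))
      nmx <- nmx / s
      nmy <- nmy / s
    }
    delta <- sqrt(mean((nmx - mx)^2 + (nmy - my)^2))
    mx <- nmx
    my <- nmy
    if (delta < tol) break
  }

  p <- ncol(X)
  aligned <- matrix(0, n, 2 * p)
  aligned[, seq(1, 2 * p, 2)] <- X
  aligned[, seq(2, 2 * p, 2)] <- Y
  rownames(aligned) <- cm$subjects
  mean_vec <- numeric(2 * p)
  mean_vec[seq(1, 2 * p, 2)] <- mx
  mean_vec[seq(2, 2 * p, 2)] <- my

  structure(
    list(aligned = aligned, mean = mean_vec, subjects = cm$subjects,
         centroid_sizes = sizes, allow_scaling = allow_scaling,
         iterations = iterations, n_points = p),
    class = "hip_gpa"
  )
}

#' @export
print.hip_gpa <- function(x, ...) {
  cat("<hip_gpa> ", length(x$subjects), " configurations, ", x$n_points,
      " points, scaling ", if (x$allow_scaling) "on" else "off",
      ", converged in ", x$iterations, " iteration(s)\n", sep = "")
  invisible(x)
}

# align a single p x 2 configuration onto a mean vector (interleaved),
# honouring the model's scaling setting; returns the interleaved vector
align_config_to_mean <- function(m, mean_vec, allow_scaling) {
  m <- sweep(m, 2, colMeans(m))
  size <- sqrt(sum(m^2))
  if (size < 1e-12) abort("Degenerate configuration: zero centroid size.")
  mm <- vec_to_xy(mean_vec)
  # scale to the mean's centroid size (not unit) so the model mean itself
  # scores exactly zero
  if (allow_scaling) m <- m * (sqrt(sum(sweep(mm, 2, colMeans(mm))^2)) / size)
  a <- sum(m[, 1] * mm[, 1] + m[, 2] * mm[, 2])
  b <- sum(m[, 1] * mm[, 2] - m[, 2] * mm[, 1])
  th <- atan2(b, a)
  rot <- cbind(cos(th) * m[, 1] - sin(th) * m[, 2],
               sin(th) * m[, 1] + cos(th) * m[, 2])
  xy_to_vec(rot)
}
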