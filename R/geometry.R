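# Automated geometric morphometrics from a single landmark configuration.
# All measures are taken in original (mm) coordinates, never the Procrustes-
# aligned frame. Alpha angle, neck-shaft angle, neck width and joint-space
# width are rigid-motion invariant; the lateral centre-edge angle is, by its
# radiographic definition, measured against the image vertical and is
# therefore translation- (not rotation-) invariant.

#' Least-squares circle fit to the femoral head points
#'
#' Algebraic (Kasa) fit solved linearly, followed by geometric refinement
#' minimising the sum of squared radial residuals (Nelder-Mead over the
#' centre with the radius profiled out as the mean radial distance).
#'
#' @param config Landmark tibble (one subject) or an n x 2 coordinate matrix.
#' @param schema A [hip_schema()]; the fit uses `schema$head_circle_idx`.
#' @return An object of class `head_circle`: list with `center` (x, y),
#'   `radius` and `rms_residual`, all in mm.
#' @export
fit_head_circle <- function(config, schema = hip_schema()) {
  m <- as_config_matrix(config)
  pts <- m[schema$head_circle_idx, , drop = FALSE]
  if (nrow(pts) < 3) abort("Circle fit needs at least 3 head points.")
  # collinearity check: all points within numerical tolerance of one line
  dir <- principal_direction(pts)
  cen0 <- colMeans(pts)
  perp <- cbind(pts[, 1] - cen0[1], pts[, 2] - cen0[2]) %*% c(-dir[2], dir[1])
  spread <- sqrt(sum((pts[, 1] - cen0[1])^2 + (pts[, 2] - cen0[2])^2))
  if (max(abs(perp)) < 1e-9 * max(spread, 1)) {
    abort("Degenerate circle fit: head points are collinear.")
  }

  # Kasa algebraic fit: x^2 + y^2 + D x + E y + F = 0
  A <- cbind(pts[, 1], pts[, 2], 1)
  b <- -(pts[, 1]^2 + pts[, 2]^2)
  sol <- qr.solve(A, b)
  cx <- -sol[1] / 2
  cy <- -sol[2] / 2

  obj <- function(cc) {
    d <- sqrt((pts[, 1] - cc[1])^2 + (pts[, 2] - cc[2])^2)
    sum((d - mean(d))^2)
  }
  ref <- optim(c(cx, cy), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-13, maxit = 300))
  cc <- ref$par
  d <- sqrt((pts[, 1] - cc[1])^2 + (pts[, 2] - cc[2])^2)
  r <- mean(d)
  structure(
    list(center = c(x = cc[1], y = cc[2]), radius = r,
         rms_residual = sqrt(mean((d - r)^2))),
    class = "head_circle"
  )
}

#' @export
print.head_circle <- function(x, ...) {
  cat(sprintf("<head_circle> center (%.2f, %.2f) mm, radius %.2f mm, rms %.3g mm\n",
              x$center[1], x$center[2], x$radius, x$rms_residual))
  invisible(x)
}

as_config_matrix <- function(config) {
  if (is.matrix(config)) return(config)
  if (length(unique(config$subject_id)) != 1) {
    abort("Geometric measures operate on one subject at a time; see measure_hips().")
  }
  config_matrix(config)
}

#' Narrowest neck width and femoral neck axis
#'
#' The narrowest neck width (NNW) is the minimum distance between the
#' superior and inferior neck-border polylines (point-to-segment, both
#' directions). The neck axis is the line through the head-circle centre and
#' the midpoint of the minimising segment -- the best available definition of
#' the "centre of the neck".
#'
#' @inheritParams fit_head_circle
#' @param circle Optionally a precomputed [fit_head_circle()] result.
#' @return List with `nnw` (mm), `midpoint` (x, y), `center` (head centre)
#'   and `dir` (unit vector from head centre towards the neck).
#' @export
neck_axis <- function(config, schema = hip_schema(), circle = NULL) {
  m <- as_config_matrix(config)
  if (is.null(circle)) circle <- fit_head_circle(m, schema)
  sup <- m[schema$superior_neck_idx, , drop = FALSE]
  inf <- m[schema$inferior_neck_idx, , drop = FALSE]
  if (polylines_intersect(sup, inf)) {
    abort("Neck borders cross (negative neck width).")
  }
  r <- polyline_min_distance(sup, inf)
  midpoint <- (r$from + r$to) / 2
  cen <- as.numeric(circle$center)
  d <- midpoint - cen
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) abort("Neck midpoint coincides with head centre; axis undefined.")
  list(nnw = r$dist, midpoint = midpoint, center = cen, dir = d / nd)
}

#' Narrowest neck width (mm)
#'
#' @inheritParams neck_axis
#' @return NNW in mm.
#' @export
narrowest_neck_width <- function(config, schema = hip_schema()) {
  neck_axis(config, schema)$nnw
}

#' Alpha angle (degrees)
#'
#' Fits the head circle, walks the outline from the superior head towards and
#' along the superior neck border, and takes the junction as the point where
#' the contour first leaves the departure circle of radius
#' `radius * (1 + delta)`: the crossing is located by linear interpolation
#' along the first outline segment that passes from inside to outside the
#' tolerance (landmarks sample a continuous contour, so the junction need
#' not coincide with a landmark). The alpha angle is the angle at the circle
#' centre between the neck axis (towards the neck) and the ray to the
#' junction. Large values indicate cam morphology.
#'
#' `delta` defaults to `max(0.02, 3 * rms_residual / radius)`, tying the
#' departure tolerance to the circle-fit quality so landmark noise does not
#' trigger spurious junctions; for the same reason the departure must be
#' sustained (the next walked point must also lie outside the tolerance,
#' unless the junction is the last walked point).
#'
#' @inheritParams neck_axis
#' @param delta Relative circle-departure tolerance; `NULL` for the default.
#' @param axis Optionally a precomputed [neck_axis()] result.
#' @return Alpha angle in degrees, or `NA` with attribute
#'   `diagnostic = "no departure"` if no walked point leaves the circle.
#' @export
alpha_angle <- function(config, schema = hip_schema(), delta = NULL,
                        circle = NULL, axis = NULL) {
  m <- as_config_matrix(config)
  if (is.null(circle)) circle <- fit_head_circle(m, schema)
  ax <- if (is.null(axis)) neck_axis(m, schema, circle = circle) else axis
  if (is.null(delta)) {
    delta <- max(0.02, 3 * circle$rms_residual / circle$radius)
  }
  walk <- seq(min(schema$superior_head_idx), max(schema$superior_neck_idx))
  cen <- as.numeric(circle$center)
  thresh <- circle$radius * (1 + delta)
  d <- sqrt((m[walk, 1] - cen[1])^2 + (m[walk, 2] - cen[2])^2)
  outside <- d > thresh
  sustained <- outside & c(outside[-1], TRUE)
  if (any(sustained)) {
    k <- which(sustained)[1]
    if (k == 1) {
      junction <- m[walk[1], ]
    } else {
      # interpolate the tolerance crossing on the entering segment
      a <- m[walk[k - 1], ]
      b <- m[walk[k], ]
      tt <- (thresh - d[k - 1]) / (d[k] - d[k - 1])
      tt <- min(1, max(0, tt))
      junction <- a + tt * (b - a)
    }
    ray <- junction - cen
    return(unname(angle_between_deg(vec_angle_deg(ax$dir[1], ax$dir[2]),
                                    vec_angle_deg(ray[1], ray[2]))))
  }
  out <- NA_real_
  attr(out, "diagnostic") <- "no departure: no walked point leaves the head circle"
  out
}

#' Lateral centre-edge angle (degrees)
#'
#' Signed angle between the vertical through the femoral head centre
#' (perpendicular to the image x-axis) and the ray from the head centre to
#' the lateral acetabular edge (schema point 78 by default). Positive when
#' the edge lies lateral of the vertical (x medial-positive convention);
#' negative values (true dysplasia) are reported, not clipped.
#'
#' @inheritParams neck_axis
#' @return LCEA in degrees, or `NA` with a diagnostic attribute when the
#'   acetabular edge lies below the head centre.
#' @export
lcea_angle <- function(config, schema = hip_schema(), circle = NULL) {
  m <- as_config_matrix(config)
  if (is.null(circle)) circle <- fit_head_circle(m, schema)
  edge <- m[schema$lateral_acetabular_edge_idx, ]
  e <- edge - as.numeric(circle$center)
  if (e[2] <= 0) {
    out <- NA_real_
    attr(out, "diagnostic") <- "acetabular edge below head centre"
    return(out)
  }
  ang <- vec_angle_deg(e[1], e[2]) # 90 = straight up; >90 = lateral (-x)
  unname(ang - 90)
}

#' Neck-shaft angle (degrees)
#'
#' Angle between the femoral neck axis and the shaft axis, reported as the
#' obtuse anatomical angle. The shaft axis is the total-least-squares line
#' through the midpoints of positionally paired medial/lateral shaft border
#' points.
#'
#' @inheritParams neck_axis
#' @return NSA in degrees (90--180).
#' @export
neck_shaft_angle <- function(config, schema = hip_schema(), axis = NULL) {
  m <- as_config_matrix(config)
  med <- m[schema$shaft_medial_idx, , drop = FALSE]
  lat <- m[schema$shaft_lateral_idx, , drop = FALSE]
  mid <- (med + lat) / 2
  if (nrow(mid) < 2) abort("Neck-shaft angle needs at least 2 shaft midpoints.")
  shaft_dir <- principal_direction(mid)
  ax <- if (is.null(axis)) neck_axis(m, schema) else axis
  acute <- line_angle_deg(ax$dir, shaft_dir)
  180 - acute
}

#' Minimum joint-space width (mm)
#'
#' Minimum point-to-segment distance between the superior femoral head
#' polyline (schema points 22--31 by default) and the acetabular polyline
#' (points 78--84). A proxy for cartilage thickness; intersecting polylines
#' yield 0 with a warning.
#'
#' @inheritParams neck_axis
#' @return mJSW in mm.
#' @export
min_joint_space_width <- function(config, schema = hip_schema()) {
  m <- as_config_matrix(config)
  sup <- m[schema$superior_head_idx, , drop = FALSE]
  ace <- m[schema$acetabulum_idx, , drop = FALSE]
  if (polylines_intersect(sup, ace)) {
    warn("Superior head and acetabular polylines intersect; mJSW set to 0.")
    return(0)
  }
  polyline_min_distance(sup, ace)$dist
}

#' Geometric morphometrics for every subject in a landmark table
#'
#' Computes, per subject: alpha angle (AA, degrees), lateral centre-edge
#' angle (LCEA, degrees), neck-shaft angle (NSA, degrees), narrowest neck
#' width (NNW, mm), minimum joint-space width (mJSW, mm), and the head-circle
#' fit (centre, radius, rms residual).
#'
#' @param landmarks Landmark tibble (any number of subjects).
#' @param schema A [hip_schema()].
#' @param delta Alpha-angle departure tolerance; `NULL` for the adaptive
#'   default.
#' @return Tibble with one row per subject.
#' @export
measure_hips <- function(landmarks, schema = hip_schema(), delta = NULL) {
  validate_landmarks(landmarks, schema)
  cm <- landmark_coord_matrices(landmarks, schema)
  n <- length(cm$subjects)
  cols <- matrix(NA_real_, n, 9,
                 dimnames = list(NULL, c("alpha_angle", "lcea", "nsa", "nnw",
                                         "mjsw", "head_cx", "head_cy",
                                         "head_radius", "head_rms")))
  for (i in seq_len(n)) {
    m <- cbind(cm$X[i, ], cm$Y[i, ])
    circle <- fit_head_circle(m, schema)
    ax <- neck_axis(m, schema, circle = circle)
    cols[i, ] <- c(
      as.numeric(alpha_angle(m, schema, delta = delta,
                             circle = circle, axis = ax)),
      as.numeric(lcea_angle(m, schema, circle = circle)),
      neck_shaft_angle(m, schema, axis = ax),
      ax$nnw,
      suppressWarnings(min_joint_space_width(m, schema)),
      circle$center[["x"]], circle$center[["y"]],
      circle$radius, circle$rms_residual
    )
  }
  bind_cols(tibble(subject_id = cm$subjects), as_tibble(cols))
}
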