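#' Landmark point schema for the proximal femur outline
#'
#' Defines the 85-point annotation scheme used throughout the package: an
#' ordered outline of the left proximal femur (medial shaft, lesser
#' trochanter, inferior neck border, femoral head, superior neck border,
#' greater trochanter, lateral shaft, distal cut) followed by a separate
#' superior acetabular arc. All indices are 1-based, matching the way the
#' anatomical point sets are conventionally quoted (e.g. "femoral head points
#' 15--28").
#'
#' The head-circle, superior-head and acetabular sets follow the published
#' convention (15--28, 22--31 and 78--84, with point 78 the lateral acetabular
#' edge). The remaining sets (neck borders, shaft borders, trochanters) are
#' not enumerated anywhere authoritative; the defaults here describe the
#' template produced by [hip_template()] and are configurable.
#'
#' @param n_points Total number of landmark points (default 85).
#' @param head_circle_idx Indices of femoral head points used for the
#'   least-squares head circle fit (default `15:28`).
#' @param superior_head_idx Indices of the superior femoral head polyline used
#'   for minimum joint-space width (default `22:31`).
#' @param acetabulum_idx Indices of the acetabular polyline used for minimum
#'   joint-space width (default `78:84`).
#' @param lateral_acetabular_edge_idx Single index of the lateral acetabular
#'   edge used for the lateral centre-edge angle (default 78).
#' @param superior_neck_idx,inferior_neck_idx Ordered indices of the superior
#'   and inferior femoral neck borders (narrowest neck width).
#' @param shaft_medial_idx,shaft_lateral_idx Ordered indices of the medial and
#'   lateral femoral shaft borders; the two sets are paired positionally to
#'   form shaft mid-points, so they must have equal length.
#' @param lesser_troch_idx,greater_troch_idx Indices of the lesser and greater
#'   trochanter outlines.
#'
#' @return An object of class `hip_schema` (a validated list of index sets).
#' @export
#' @examples
#' sch <- hip_schema()
#' sch$head_circle_idx
hip_schema <- function(n_points = 85L,
                       head_circle_idx = 15:28,
                       superior_head_idx = 22:31,
                       acetabulum_idx = 78:84,
                       lateral_acetabular_edge_idx = 78L,
                       superior_neck_idx = 33:40,
                       inferior_neck_idx = 10:14,
                       shaft_medial_idx = 1:5,
                       shaft_lateral_idx = c(62L, 61L, 60L, 59L, 58L),
                       lesser_troch_idx = 6:9,
                       greater_troch_idx = 41:50) {
  schema <- structure(
    list(
      n_points = as.integer(n_points),
      head_circle_idx = as.integer(head_circle_idx),
      superior_head_idx = as.integer(superior_head_idx),
      acetabulum_idx = as.integer(acetabulum_idx),
      lateral_acetabular_edge_idx = as.integer(lateral_acetabular_edge_idx),
      superior_neck_idx = as.integer(superior_neck_idx),
      inferior_neck_idx = as.integer(inferior_neck_idx),
      shaft_medial_idx = as.integer(shaft_medial_idx),
      shaft_lateral_idx = as.integer(shaft_lateral_idx),
      lesser_troch_idx = as.integer(lesser_troch_idx),
      greater_troch_idx = as.integer(greater_troch_idx)
    ),
    class = "hip_schema"
  )
  validate_hip_schema(schema)
}

validate_hip_schema <- function(schema) {
  idx_fields <- setdiff(names(schema), "n_points")
  if (!is.integer(schema$n_points) || schema$n_points < 1) {
    abort("`n_points` must be a positive integer.")
  }
  for (f in idx_fields) {
    idx <- schema[[f]]
    if (length(idx) == 0) {
      abort(paste0("Schema index set `", f, "` must not be empty."))
    }
    if (anyNA(idx) || any(idx < 1L) || any(idx > schema$n_points)) {
      abort(paste0("Schema index set `", f, "` must lie within [1, ",
                   schema$n_points, "]."))
    }
  }
  if (length(schema$head_circle_idx) < 3) {
    abort("`head_circle_idx` needs at least 3 points for an identifiable circle fit.")
  }
  if (length(schema$shaft_medial_idx) != length(schema$shaft_lateral_idx)) {
    abort("`shaft_medial_idx` and `shaft_lateral_idx` must have equal length (paired mid-points).")
  }
  schema
}

#' @export
print.hip_schema <- function(x, ...) {
  cat("<hip_schema> ", x$n_points, " landmark points\n", sep = "")
  for (f in setdiff(names(x), "n_points")) {
    cat("  ", format(f, width = 28), paste(x[[f]], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

# ---- landmark tibble helpers -------------------------------------------------

#' Validate a landmark tibble against a schema
#'
#' A landmark configuration is a tibble with columns `subject_id`, `point`,
#' `x`, `y` (coordinates in mm; y superior-positive, x medial-positive for a
#' left hip AP view). Multiple subjects may be stacked in one tibble.
#'
#' @param landmarks Landmark tibble.
#' @param schema A [hip_schema()].
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_landmarks <- function(landmarks, schema = hip_schema()) {
  need <- c("subject_id", "point", "x", "y")
  miss <- setdiff(need, names(landmarks))
  if (length(miss)) {
    abort(paste0("Landmark tibble is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(is.finite(landmarks$x)) || !all(is.finite(landmarks$y))) {
    abort("All landmark coordinates must be finite.")
  }
  counts <- table(landmarks$subject_id)
  bad <- names(counts)[counts != schema$n_points]
  if (length(bad)) {
    abort(paste0("Schema mismatch: subject(s) ", paste(head(bad, 3), collapse = ", "),
                 " do not have ", schema$n_points, " points."))
  }
  # consecutive outline points must not coincide
  ok <- landmarks |>
    arrange(.data$subject_id, .data$point) |>
    group_by(.data$subject_id) |>
    summarise(min_step = min(sqrt(diff(.data$x)^2 + diff(.data$y)^2)),
              .groups = "drop")
  if (any(ok$min_step <= 0)) {
    abort("Consecutive outline points must be non-coincident.")
  }
  invisible(landmarks)
}

# single-subject landmark tibble -> n_points x 2 matrix in point order
config_matrix <- function(landmarks, subject = NULL) {
  if (!is.null(subject)) {
    landmarks <- landmarks[landmarks$subject_id == subject, , drop = FALSE]
  }
  landmarks <- landmarks[order(landmarks$point), , drop = FALSE]
  cbind(x = landmarks$x, y = landmarks$y)
}

# many subjects -> list(X = n x p, Y = n x p) coordinate matrices, row order =
# unique subject order of appearance
landmark_coord_matrices <- function(landmarks, schema = hip_schema()) {
  validate_landmarks(landmarks, schema)
  subjects <- unique(landmarks$subject_id)
  landmarks <- landmarks[order(match(landmarks$subject_id, subjects), landmarks$point), ]
  p <- schema$n_points
  X <- matrix(landmarks$x, ncol = p, byrow = TRUE)
  Y <- matrix(landmarks$y, ncol = p, byrow = TRUE)
  rownames(X) <- rownames(Y) <- subjects
  list(X = X, Y = Y, subjects = subjects)
}

# interleaved flat vector (x1, y1, x2, y2, ...) <-> p x 2 matrix
vec_to_xy <- function(v) matrix(v, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
xy_to_vec <- function(m) as.vector(t(m))

xy_to_landmarks <- function(m, subject_id = "shape") {
  tibble(subject_id = subject_id, point = seq_len(nrow(m)),
         x = m[, 1], y = m[, 2])
}
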