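# Low-level planar geometry used by the morphometric measures.
# All functions work in plain numeric matrices (rows = points, cols = x, y).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# direction angle of (x, y) in degrees, in [0, 360)
vec_angle_deg <- function(x, y) (rad2deg(atan2(y, x))) %% 360

# unsigned angle between two direction angles (degrees), in [0, 180]
angle_between_deg <- function(a, b) abs((a - b + 180) %% 360 - 180)

# angle between two *lines* given by direction vectors, in [0, 90]
line_angle_deg <- function(u, v) {
  cosang <- abs(sum(u * v)) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

centroid_size <- function(m) {
  cen <- colMeans(m)
  sqrt(sum(sweep(m, 2, cen)^2))
}

# Distances from every point in P (m x 2) to every segment A[i,] -> B[i,]
# (k x 2 each). Returns list(d = m x k distance matrix, fx, fy = foot points).
dist_points_segments <- function(P, A, B) {
  m <- nrow(P)
  k <- nrow(A)
  abx <- B[, 1] - A[, 1]
  aby <- B[, 2] - A[, 2]
  len2 <- abx^2 + aby^2
  len2[len2 == 0] <- .Machine$double.eps
  apx <- outer(P[, 1], A[, 1], "-")
  apy <- outer(P[, 2], A[, 2], "-")
  tt <- (apx * rep(abx, each = m) + apy * rep(aby, each = m)) /
    rep(len2, each = m)
  tt <- pmin(1, pmax(0, tt))
  fx <- rep(A[, 1], each = m) + tt * rep(abx, each = m)
  fy <- rep(A[, 2], each = m) + tt * rep(aby, each = m)
  dim(fx) <- dim(fy) <- c(m, k)
  d <- sqrt((P[, 1] - fx)^2 + (P[, 2] - fy)^2)
  list(d = d, fx = fx, fy = fy)
}

# Minimum distance between two polylines P and Q (open, ordered vertices).
# Considers vertices of each against segments of the other, so the result is
# the true polyline-to-polyline distance. Returns the minimizing pair as well
# (from = point on P side, to = point on Q side).
polyline_min_distance <- function(P, Q) {
  segP <- nrow(P) >= 2
  segQ <- nrow(Q) >= 2
  best <- list(dist = Inf, from = NULL, to = NULL)
  if (segQ) {
    r <- dist_points_segments(P, Q[-nrow(Q), , drop = FALSE], Q[-1, , drop = FALSE])
    i <- arrayInd(which.min(r$d), dim(r$d))
    if (r$d[i] < best$dist) {
      best <- list(dist = r$d[i], from = P[i[1], ], to = c(r$fx[i], r$fy[i]))
    }
  }
  if (segP) {
    r <- dist_points_segments(Q, P[-nrow(P), , drop = FALSE], P[-1, , drop = FALSE])
    i <- arrayInd(which.min(r$d), dim(r$d))
    if (r$d[i] < best$dist) {
      best <- list(dist = r$d[i], from = c(r$fx[i], r$fy[i]), to = Q[i[1], ])
    }
  }
  if (!segP && !segQ) {
    d <- sqrt(outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2)
    i <- arrayInd(which.min(d), dim(d))
    best <- list(dist = d[i], from = P[i[1], ], to = Q[i[2], ])
  }
  best
}

# TRUE if any segment of polyline P properly intersects any segment of Q.
# Orientation tests vectorised over all segment pairs.
polylines_intersect <- function(P, Q) {
  np <- nrow(P) - 1
  nq <- nrow(Q) - 1
  if (np < 1 || nq < 1) return(FALSE)
  ax <- rep(P[seq_len(np), 1], times = nq)
  ay <- rep(P[seq_len(np), 2], times = nq)
  bx <- rep(P[-1, 1], times = nq)
  by <- rep(P[-1, 2], times = nq)
  cx <- rep(Q[seq_len(nq), 1], each = np)
  cy <- rep(Q[seq_len(nq), 2], each = np)
  dx <- rep(Q[-1, 1], each = np)
  dy <- rep(Q[-1, 2], each = np)
  o1 <- sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  o2 <- sign((bx - ax) * (dy - ay) - (by - ay) * (dx - ax))
  o3 <- sign((dx - cx) * (ay - cy) - (dy - cy) * (ax - cx))
  o4 <- sign((dx - cx) * (by - cy) - (dy - cy) * (bx - cx))
  any(o1 != o2 & o3 != o4 & o1 != 0 & o2 != 0)
}

# First principal direction of a 2-D point cloud (total-least-squares line),
# robust to vertical lines where lm() would fail.
principal_direction <- function(m) {
  cen <- sweep(m, 2, colMeans(m))
  e <- eigen(crossprod(cen), symmetric = TRUE)
  e$vectors[, 1]
}
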