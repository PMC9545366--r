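# Independent brute-force oracles. These deliberately avoid the package's
# vectorised geometry code paths: plain loops and grid searches only.

# geometric least-squares circle by grid search around a starting guess,
# radius profiled out as the mean radial distance
oracle_circle_grid <- function(pts, center_guess, half_width = 2,
                               steps = c(0.2, 0.02, 0.002)) {
  best <- center_guess
  for (st in steps) {
    gx <- seq(best[1] - half_width, best[1] + half_width, by = st)
    gy <- seq(best[2] - half_width, best[2] + half_width, by = st)
    obj <- Inf
    for (x in gx) for (y in gy) {
      d <- sqrt((pts[, 1] - x)^2 + (pts[, 2] - y)^2)
      s <- sum((d - mean(d))^2)
      if (s < obj) {
        obj <- s
        cand <- c(x, y)
      }
    }
    best <- cand
    half_width <- 2 * st
  }
  d <- sqrt((pts[, 1] - best[1])^2 + (pts[, 2] - best[2])^2)
  list(center = best, radius = mean(d))
}

# naive point-to-segment distance
oracle_pt_seg <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(1, max(0, t))
  f <- a + t * ab
  sqrt(sum((p - f)^2))
}

# exhaustive polyline-to-polyline minimum distance
oracle_polyline_min <- function(P, Q) {
  best <- Inf
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(nrow(Q) - 1)) {
      best <- min(best, oracle_pt_seg(P[i, ], Q[j, ], Q[j + 1, ]))
    }
  }
  for (j in seq_len(nrow(Q))) {
    for (i in seq_len(nrow(P) - 1)) {
      best <- min(best, oracle_pt_seg(Q[j, ], P[i, ], P[i + 1, ]))
    }
  }
  best
}

# independent proper-intersection test between two polylines (ccw orient)
oracle_polylines_intersect <- function(P, Q) {
  ccw <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  for (i in seq_len(nrow(P) - 1)) {
    for (j in seq_len(nrow(Q) - 1)) {
      o1 <- sign(ccw(P[i, ], P[i + 1, ], Q[j, ]))
      o2 <- sign(ccw(P[i, ], P[i + 1, ], Q[j + 1, ]))
      o3 <- sign(ccw(Q[j, ], Q[j + 1, ], P[i, ]))
      o4 <- sign(ccw(Q[j, ], Q[j + 1, ], P[i + 1, ]))
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0) return(TRUE)
    }
  }
  FALSE
}

# total-least-squares line direction by angle grid search
oracle_tls_direction <- function(pts) {
  cen <- colMeans(pts)
  px <- pts[, 1] - cen[1]
  py <- pts[, 2] - cen[2]
  best <- 0
  half <- pi / 2
  for (st in c(0.01, 0.001, 0.0001, 0.00001)) {
    th <- seq(best - half, best + half, by = st)
    obj <- vapply(th, function(a) sum((-sin(a) * px + cos(a) * py)^2), numeric(1))
    best <- th[which.min(obj)]
    half <- 2 * st
  }
  c(cos(best), sin(best))
}

# angle between two lines from direction vectors, degrees in [0, 90]
oracle_line_angle <- function(u, v) {
  ca <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, ca))) * 180 / pi
}

# full-Procrustes mean of two centred shapes by rotation grid search:
# mean(theta) = (X + R(theta) Y) / 2 minimising the summed squared distance
oracle_procrustes_mean2 <- function(X, Y, n_grid = 100000) {
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  X <- X / sqrt(sum(X^2))
  Y <- Y / sqrt(sum(Y^2))
  thetas <- seq(0, 2 * pi, length.out = n_grid)
  obj <- vapply(thetas, function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    sum((X - Y %*% t(R))^2)
  }, numeric(1))
  th <- thetas[which.min(obj)]
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  (X + Y %*% t(R)) / 2
}

# Procrustes distance between two configurations (translation/rotation/scale
# removed), used to compare shapes irrespective of frame
procrustes_dist <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); A <- A / sqrt(sum(A^2))
  B <- sweep(B, 2, colMeans(B)); B <- B / sqrt(sum(B^2))
  s <- svd(crossprod(B, A))
  sqrt(max(0, 2 - 2 * sum(s$d)))
}

# largest principal angle (radians) between the column spaces of A and B
max_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  max(acos(pmin(1, sv)))
}

rotate_landmarks <- function(landmarks, theta, dx = 0, dy = 0) {
  ct <- cos(theta); st <- sin(theta)
  dplyr::mutate(landmarks,
                x0 = .data$x, y0 = .data$y,
                x = ct * .data$x0 - st * .data$y0 + dx,
                y = st * .data$x0 + ct * .data$y0 + dy) |>
    dplyr::select("subject_id", "point", "x", "y")
}
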