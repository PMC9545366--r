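# Geometric measures against analytic cases and independent brute-force
# oracles, plus the invariance properties.

test_that("circle fit recovers exact and noisy circles", {
  sch <- hip_schema(n_points = 14, head_circle_idx = 1:14,
                    superior_head_idx = 1:5, acetabulum_idx = 6:10,
                    lateral_acetabular_edge_idx = 6L, superior_neck_idx = 11:12,
                    inferior_neck_idx = 13:14, shaft_medial_idx = 1L,
                    shaft_lateral_idx = 2L, lesser_troch_idx = 3L,
                    greater_troch_idx = 4L)
  th <- seq(0.3, 2.8, length.out = 14)
  pts <- cbind(25 * cos(th), 25 * sin(th))
  fit <- fit_head_circle(pts, sch)
  expect_equal(as.numeric(fit$center), c(0, 0), tolerance = 1e-9)
  expect_equal(fit$radius, 25, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9)

  set.seed(4)
  for (i in 1:5) {
    cen <- runif(2, -10, 10)
    r <- runif(1, 20, 30)
    noisy <- cbind(cen[1] + r * cos(th), cen[2] + r * sin(th)) +
      matrix(rnorm(28, 0, 0.5), ncol = 2)
    fit <- fit_head_circle(noisy, sch)
    oracle <- oracle_circle_grid(noisy, cen)
    expect_lt(max(abs(as.numeric(fit$center) - oracle$center)), 0.05)
    expect_lt(abs(fit$radius - oracle$radius), 0.05)
  }

  col <- cbind(seq_len(14), 2 * seq_len(14) + 1)
  expect_error(fit_head_circle(col, sch), "collinear")
})

test_that("narrowest neck width matches parallel-line and brute-force oracles", {
  # two parallel horizontal polylines 30 mm apart
  tpl <- hip_template()
  m <- hipshapes:::config_matrix(tpl)
  m[hip_schema()$superior_neck_idx, ] <- cbind(seq(-40, -5, length.out = 8), 15)
  m[hip_schema()$inferior_neck_idx, ] <- cbind(seq(-35, -10, length.out = 5), -15)
  r <- hipshapes:::polyline_min_distance(
    m[hip_schema()$superior_neck_idx, ], m[hip_schema()$inferior_neck_idx, ])
  expect_equal(r$dist, 30, tolerance = 1e-12)

  # template neck equals the exhaustive pairwise minimum
  sup <- hipshapes:::config_matrix(tpl)[hip_schema()$superior_neck_idx, ]
  inf <- hipshapes:::config_matrix(tpl)[hip_schema()$inferior_neck_idx, ]
  expect_equal(narrowest_neck_width(tpl), oracle_polyline_min(sup, inf),
               tolerance = 1e-12)

  # symmetric template: axis passes through the symmetry line (head centre
  # to neck midpoint lies on the neck axis by construction)
  ax <- neck_axis(tpl)
  u <- c(cos(pi / 4), sin(pi / 4))
  expect_lt(abs(ax$midpoint[1] * u[2] - ax$midpoint[2] * u[1]), 1e-6)

  # crossing neck borders are an error
  m2 <- hipshapes:::config_matrix(tpl)
  tmp <- m2[33, ]
  m2[33, ] <- m2[14, ] + c(0.5, -8)
  m2[14, ] <- tmp + c(0.2, 8)
  expect_error(neck_axis(m2), "cross")
})

test_that("alpha angle reproduces a planted 60-degree junction exactly", {
  # plant the junction point exactly at the departure radius on the ray 60
  # degrees from the neck axis, with all following points pushed well
  # outside the tolerance: the interpolated crossing is the planted point
  tpl <- hip_template()
  sch <- hip_schema()
  m <- hipshapes:::config_matrix(tpl)
  # neck axis (towards the neck) points at 225 deg; junction ray at 165 deg
  phi <- hipshapes:::deg2rad(165)
  walk <- seq(min(sch$superior_head_idx), max(sch$superior_neck_idx))
  j <- 31
  m[j, ] <- 25 * 1.02 * c(cos(phi), sin(phi)) # exactly at radius * (1 + delta)
  for (i in (j + 1):max(walk)) {
    v <- m[i, ]
    m[i, ] <- v / sqrt(sum(v^2)) * max(sqrt(sum(v^2)), 27)
  }
  aa <- alpha_angle(m, sch)
  expect_equal(aa, 60, tolerance = 1e-6)
})

test_that("alpha angle is monotone in the cam weight and flags no departure", {
  spec <- generative_shape_spec()
  weights <- seq(0, 12, by = 1.5)
  aa <- vapply(weights, function(w) {
    alpha_angle(hipshapes:::config_matrix(
      apply_mode_weights(spec, c(cam_bump = w))), hip_schema())
  }, numeric(1))
  expect_true(all(diff(aa) >= -1e-12))
  expect_gt(aa[length(aa)], aa[1])

  # a pure circle + far-away acetabulum never leaves the circle
  sch <- hip_schema(n_points = 20, head_circle_idx = 1:14,
                    superior_head_idx = 1:10, acetabulum_idx = 15:20,
                    lateral_acetabular_edge_idx = 15L, superior_neck_idx = 5:10,
                    inferior_neck_idx = 11:14, shaft_medial_idx = 1L,
                    shaft_lateral_idx = 2L, lesser_troch_idx = 3L,
                    greater_troch_idx = 4L)
  th <- seq(0.1, 2 * pi - 0.3, length.out = 14)
  m <- rbind(cbind(25 * cos(th), 25 * sin(th)),
             cbind(seq(-5, 5, length.out = 6), 40))
  aa2 <- alpha_angle(m, sch)
  expect_true(is.na(aa2))
  expect_match(attr(aa2, "diagnostic"), "no departure")
})

test_that("LCEA matches analytic positions and its sign convention", {
  tpl <- hip_template()
  m0 <- hipshapes:::config_matrix(tpl)

  # lateral edge directly above the head centre -> 0 degrees
  m <- m0
  m[78, ] <- c(0, 29)
  expect_equal(lcea_angle(m), 0, tolerance = 1e-6)

  # 45 degrees lateral elevation -> 45
  m[78, ] <- 29 * c(cos(hipshapes:::deg2rad(135)), sin(hipshapes:::deg2rad(135)))
  expect_equal(lcea_angle(m), 45, tolerance = 1e-6)

  # medial of vertical -> negative
  m[78, ] <- 29 * c(cos(hipshapes:::deg2rad(80)), sin(hipshapes:::deg2rad(80)))
  expect_equal(lcea_angle(m), -10, tolerance = 1e-6)

  # edge below the head centre -> sentinel
  m[78, ] <- c(-20, -5)
  out <- lcea_angle(m)
  expect_true(is.na(out))
  expect_match(attr(out, "diagnostic"), "below")

  # monotone in the acetabular coverage score
  spec <- generative_shape_spec()
  lc <- vapply(seq(-6, 6, by = 2), function(w) {
    lcea_angle(hipshapes:::config_matrix(
      apply_mode_weights(spec, c(acetab_coverage = w))))
  }, numeric(1))
  expect_true(all(diff(lc) > 0))
})

test_that("neck-shaft angle matches the analytic template and an oracle", {
  tpl <- hip_template()
  expect_equal(neck_shaft_angle(tpl), 135, tolerance = 1e-9)

  # rigid rotation leaves NSA unchanged
  rot <- rotate_landmarks(tpl, 0.83, dx = 12, dy = -7)
  expect_equal(neck_shaft_angle(rot), 135, tolerance = 1e-9)

  # brute-force two-line oracle on randomly rotated templates
  set.seed(9)
  sch <- hip_schema()
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi)
    cfg <- rotate_landmarks(tpl, th)
    m <- hipshapes:::config_matrix(cfg)
    ax <- neck_axis(m, sch)
    mid <- (m[sch$shaft_medial_idx, ] + m[sch$shaft_lateral_idx, ]) / 2
    shaft_dir <- mid[nrow(mid), ] - mid[1, ]
    acute <- oracle_line_angle(ax$dir, shaft_dir)
    expect_equal(neck_shaft_angle(m, sch), 180 - acute, tolerance = 1e-6)
  }
})

test_that("mJSW matches concentric arcs, brute force, and detects contact", {
  # finely sampled concentric arcs of radii 25 and 29 -> 4 mm
  n <- 1200
  th_in <- seq(0.9, 1.9, length.out = n)
  th_out <- seq(1.0, 1.8, length.out = n)
  P <- cbind(25 * cos(th_in), 25 * sin(th_in))
  Q <- cbind(29 * cos(th_out), 29 * sin(th_out))
  expect_equal(hipshapes:::polyline_min_distance(P, Q)$dist, 4, tolerance = 1e-6)

  # random configurations equal the exhaustive oracle
  set.seed(21)
  sims <- sample_cohort(n = 12, seed = 33)
  sch <- hip_schema()
  for (id in unique(sims$landmarks$subject_id)[1:6]) {
    m <- hipshapes:::config_matrix(sims$landmarks, id)
    expect_equal(min_joint_space_width(m, sch),
                 oracle_polyline_min(m[sch$superior_head_idx, ],
                                     m[sch$acetabulum_idx, ]),
                 tolerance = 1e-12)
  }

  # intersecting polylines give zero with a warning
  tpl <- hip_template()
  m <- hipshapes:::config_matrix(tpl)
  ace <- sch$acetabulum_idx
  m[ace, 1] <- seq(-20, 15, length.out = length(ace))
  m[ace, 2] <- seq(30, 10, length.out = length(ace))
  expect_warning(w <- min_joint_space_width(m, sch), "intersect")
  expect_equal(w, 0)
})

test_that("measures are invariant under rigid motion and scale as lengths", {
  tpl <- hip_template()
  base <- measure_hips(tpl)
  moved <- rotate_landmarks(tpl, -1.2, dx = 40, dy = -60)
  m2 <- measure_hips(moved)
  for (v in c("alpha_angle", "nsa", "nnw", "mjsw")) {
    expect_equal(m2[[v]], base[[v]], tolerance = 1e-7)
  }
  # LCEA is frame-anchored (image vertical): translation-invariant only
  shifted <- dplyr::mutate(tpl, x = x + 40, y = y - 60)
  expect_equal(measure_hips(shifted)$lcea, base$lcea, tolerance = 1e-9)

  # uniform scaling: mm measures scale, angles unchanged
  scaled <- dplyr::mutate(tpl, x = 2 * x, y = 2 * y)
  ms <- measure_hips(scaled)
  expect_equal(ms$nnw, 2 * base$nnw, tolerance = 1e-9)
  expect_equal(ms$mjsw, 2 * base$mjsw, tolerance = 1e-9)
  expect_equal(ms$alpha_angle, base$alpha_angle, tolerance = 1e-7)
  expect_equal(ms$lcea, base$lcea, tolerance = 1e-9)
  expect_equal(ms$nsa, base$nsa, tolerance = 1e-9)
})
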