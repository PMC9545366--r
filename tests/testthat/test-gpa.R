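test_that("rigid transforms of one shape align to machine precision", {
  tpl <- hip_template()
  set.seed(5)
  shapes <- dplyr::bind_rows(lapply(1:6, function(i) {
    r <- rotate_landmarks(tpl, runif(1, 0, 2 * pi),
                          dx = runif(1, -50, 50), dy = runif(1, -50, 50))
    r$subject_id <- paste0("c", i)
    r
  }))
  g <- gpa_align(shapes, allow_scaling = FALSE)
  spread <- apply(g$aligned, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-9)

  # no effective shape variation -> zero effective modes
  mod <- fit_shape_model(shapes, allow_scaling = FALSE)
  expect_equal(mod$n_effective, 0)
})

test_that("the model is invariant to rotations/translations of the inputs", {
  sim <- fixture_cohort()
  lm50 <- sim$landmarks[sim$landmarks$subject_id %in%
                          unique(sim$landmarks$subject_id)[1:50], ]
  m1 <- fit_shape_model(lm50, k = 6)
  set.seed(8)
  jumbled <- lm50 |>
    dplyr::group_by(subject_id) |>
    dplyr::group_modify(function(d, k) {
      rotate_landmarks(dplyr::mutate(d, subject_id = k$subject_id),
                       runif(1, 0, 2 * pi), runif(1, -30, 30),
                       runif(1, -30, 30))[c("point", "x", "y")]
    }) |>
    dplyr::ungroup()
  m2 <- fit_shape_model(jumbled, k = 6)
  # the two fits can differ by one global rotation of the aligned frame;
  # undo it (mean2 -> mean1) before comparing mode subspaces
  A1 <- hipshapes:::vec_to_xy(m1$mean_shape)
  A2 <- hipshapes:::vec_to_xy(m2$mean_shape)
  s <- svd(crossprod(A2, A1))
  R <- s$u %*% t(s$v)
  modes2_rot <- apply(m2$modes[, 1:6], 2, function(v) {
    hipshapes:::xy_to_vec(hipshapes:::vec_to_xy(v) %*% R)
  })
  ang <- max_principal_angle(m1$modes[, 1:6], modes2_rot)
  expect_lt(ang, 1e-6)
  expect_equal(m2$raw_sd[1:6], m1$raw_sd[1:6], tolerance = 1e-8)
})

test_that("two-shape Procrustes mean matches the grid-search oracle", {
  X <- rbind(c(0, 0), c(4, 0), c(1, 3))
  Y <- rbind(c(0.2, -0.1), c(3.1, 1.4), c(-0.5, 2.6))
  lms <- dplyr::bind_rows(lm_from_matrix(X, "a"), lm_from_matrix(Y, "b"))
  sch <- hip_schema(n_points = 3, head_circle_idx = 1:3, superior_head_idx = 1:2,
                    acetabulum_idx = 3L, lateral_acetabular_edge_idx = 3L,
                    superior_neck_idx = 1L, inferior_neck_idx = 2L,
                    shaft_medial_idx = 1L, shaft_lateral_idx = 2L,
                    lesser_troch_idx = 3L, greater_troch_idx = 3L)
  g <- gpa_align(lms, schema = sch, allow_scaling = TRUE)
  mean_fit <- hipshapes:::vec_to_xy(g$mean)
  mean_oracle <- oracle_procrustes_mean2(X, Y)
  expect_lt(procrustes_dist(mean_fit, mean_oracle), 1e-4)
})

test_that("pairwise alignment agrees with an established Procrustes routine", {
  skip_if_not_installed("vegan")
  set.seed(12)
  X <- matrix(rnorm(170), ncol = 2)
  th <- 1.1
  Y <- sweep(X %*% t(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)),
             2, c(-3, 9), "+") + matrix(rnorm(170, 0, 0.2), ncol = 2)
  Xc <- sweep(X, 2, colMeans(X)); Xc <- Xc / sqrt(sum(Xc^2))
  Yc <- sweep(Y, 2, colMeans(Y)); Yc <- Yc / sqrt(sum(Yc^2))
  v <- hipshapes:::align_config_to_mean(Y, hipshapes:::xy_to_vec(Xc),
                                        allow_scaling = TRUE)
  # rotation-only alignment of the pre-normalised shape (partial Procrustes)
  ref <- vegan::procrustes(Xc, Yc, scale = FALSE, symmetric = FALSE)
  aligned_pkg <- hipshapes:::vec_to_xy(v)
  expect_lt(max(abs(aligned_pkg - ref$Yrot)), 1e-10)
})

test_that("degenerate configurations are rejected", {
  flat <- tibble::tibble(subject_id = rep(c("a", "b"), each = 85),
                         point = rep(1:85, 2), x = 1, y = 2)
  expect_error(suppressWarnings(gpa_align(flat)), "non-coincident|Degenerate")
  one <- hip_template()
  expect_error(gpa_align(one), "at least 2")
})
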