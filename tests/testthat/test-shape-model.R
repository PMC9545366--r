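test_that("PCA recovers a 3-mode generating subspace and its SDs", {
  spec3 <- generative_shape_spec(
    score_sd = c(cam_bump = 3, acetab_coverage = 5, neck_width = 2),
    point_noise_sd = 1e-9
  )
  sim <- sample_cohort(spec3, outcome_model_spec(), n = 2000, seed = 7)
  mod <- fit_shape_model(sim$landmarks, k = 10)

  ang <- max_principal_angle(spec3$modes, mod$modes[, 1:3])
  expect_lt(ang, 0.05)

  # raw SDs in the aligned (unit-centroid-size) frame recover the generating
  # SDs after undoing the template's centroid size
  m <- hipshapes:::config_matrix(spec3$template)
  cs0 <- sqrt(sum(sweep(m, 2, colMeans(m))^2))
  got <- sort(mod$raw_sd[1:3] * cs0, decreasing = TRUE)
  expect_equal(got, sort(unname(spec3$score_sd), decreasing = TRUE),
               tolerance = 0.05)

  expect_equal(sum(mod$var_frac), 1, tolerance = 1e-12)
  expect_true(all(diff(mod$var_frac) <= 1e-12))
})

test_that("standardized training scores have mean 0 and SD 1", {
  sim <- fixture_cohort()
  mod <- fit_shape_model(sim$landmarks, k = 6)
  st <- mod$scores |>
    dplyr::group_by(hsm) |>
    dplyr::summarise(m = mean(score_std), s = sd(score_std))
  expect_lt(max(abs(st$m)), 1e-8)
  expect_lt(max(abs(st$s - 1)), 1e-8)
})

test_that("scoring and reconstruction are mutually consistent", {
  sim <- fixture_cohort()
  mod <- fit_shape_model(sim$landmarks, k = 6)

  # the mean shape scores to exactly zero
  mean_lm <- hipshapes:::xy_to_landmarks(
    hipshapes:::vec_to_xy(mod$mean_shape), "mean")
  s0 <- score_shapes(mean_lm, mod)
  expect_lt(max(abs(s0$score_raw)), 1e-10)

  # score(reconstruct(z)) == z, exactly when size is not renormalised; with
  # scale removal the round trip is exact up to the O(|z|^2) size rescaling
  z <- c(0.03, -0.01, 0.005, 0.002, -0.004, 0.001)
  mod_ns <- fit_shape_model(sim$landmarks, k = 6, allow_scaling = FALSE)
  z_mm <- z * 250 # aligned frame is mm without scaling
  s_ns <- score_shapes(reconstruct_shape(mod_ns, z_mm), mod_ns)
  expect_equal(s_ns$score_raw, z_mm, tolerance = 1e-10)
  s <- score_shapes(reconstruct_shape(mod, z), mod)
  expect_lt(max(abs(s$score_raw - z)), sum(z^2))

  # zero scores reconstruct the mean shape
  rec0 <- reconstruct_shape(mod, numeric(6))
  expect_equal(rec0$x, mean_lm$x, tolerance = 1e-12)

  expect_error(reconstruct_shape(mod, numeric(6), n_modes = 1000), "exceeds")
  expect_error(score_shapes(sim$landmarks, list()), "fitted")
})

test_that("full reconstruction is lossless and error is monotone in modes", {
  sim <- fixture_cohort()
  sub <- sim$landmarks[sim$landmarks$subject_id %in%
                         unique(sim$landmarks$subject_id)[1:60], ]
  g <- gpa_align(sub)
  mod <- fit_shape_model(sub, k = 6)

  target <- g$aligned[7, ]
  raw_all <- drop(crossprod(mod$modes, target - mod$mean_shape))
  K <- ncol(mod$modes)
  errs <- vapply(c(1, 3, 6, 20, 59, K), function(nm) {
    rec <- reconstruct_shape(mod, raw_all[seq_len(nm)], n_modes = nm)
    sqrt(sum((hipshapes:::xy_to_vec(cbind(rec$x, rec$y)) - target)^2))
  }, numeric(1))
  expect_lt(errs[length(errs)], 1e-8)
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("tidy, glance and the JSON round trip expose the model", {
  sim <- fixture_cohort()
  mod <- fit_shape_model(sim$landmarks, k = 6)
  td <- tidy(mod)
  expect_equal(td$cum_var_frac[length(td$cum_var_frac)], 1, tolerance = 1e-10)
  gl <- glance(mod)
  expect_equal(gl$k_retained, 6)
  # six generating modes + isotropic landmark noise spread over 170
  # coordinates: the top-10 share is well above the per-mode noise floor
  # but far from 1
  expect_gt(gl$cum_var_top10, 0.5)
  expect_lt(gl$cum_var_top10, 1)

  f <- withr::local_tempfile(fileext = ".json")
  write_shape_model(mod, f)
  back <- read_shape_model(f)
  expect_equal(back$mean_shape, mod$mean_shape, tolerance = 1e-12)
  expect_equal(back$raw_sd, mod$raw_sd, tolerance = 1e-12)
  sc1 <- score_shapes(hip_template(), mod)
  sc2 <- score_shapes(hip_template(), back)
  expect_equal(sc2$score_std, sc1$score_std, tolerance = 1e-10)
})

test_that("autoplot renders mode and composite outlines", {
  sim <- fixture_cohort()
  mod <- fit_shape_model(sim$landmarks, k = 6)
  p <- ggplot2::autoplot(mod, hsm = 1)
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
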