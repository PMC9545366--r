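test_that("sampling is deterministic under a fixed seed and seed-sensitive", {
  a <- sample_cohort(n = 60, seed = 1)
  b <- sample_cohort(n = 60, seed = 1)
  expect_identical(a$landmarks, b$landmarks)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$scores, b$scores)
  c_ <- sample_cohort(n = 60, seed = 2)
  expect_false(identical(a$landmarks, c_$landmarks))
  expect_error(sample_cohort(n = 10), "seed")
})

test_that("empirical score SDs converge to the generating SDs", {
  spec <- generative_shape_spec()
  sim <- sample_cohort(spec, n = 10000, seed = 19, landmarks = FALSE)
  sds <- sim$scores |>
    dplyr::group_by(mode) |>
    dplyr::summarise(s = sd(score_raw))
  sds <- sds[match(spec$mode_names, sds$mode), ]
  # within 3 standard errors of sd at n = 10000: se ~ s / sqrt(2n)
  se <- unname(spec$score_sd) / sqrt(2 * 10000)
  expect_true(all(abs(sds$s - unname(spec$score_sd)) < 3 * se))
})

test_that("marginal outcome prevalences match their calibration targets", {
  os <- outcome_model_spec()
  sim <- sample_cohort(generative_shape_spec(), os, n = 50000, seed = 23,
                       landmarks = FALSE)
  co <- sim$cohort
  # binomial Monte-Carlo standard errors at n = 50000
  chk <- function(x, p) abs(mean(x) - p) < 3 * sqrt(p * (1 - p) / 50000)
  expect_true(chk(co$rhoa_grade2_only, 0.057))
  expect_true(chk(co$rhoa_ge3, 0.017))
  expect_true(chk(co$hoa_hospital, 0.013))
  expect_true(chk(co$thr_event, 0.006))
  # severity ordering of prevalences
  p <- c(mean(co$rhoa_grade2_only), mean(co$rhoa_ge3),
         mean(co$hoa_hospital), mean(co$thr_event))
  expect_true(all(diff(p) < 0))
})

test_that("null effect sizes give per-mode OR confidence intervals covering 1", {
  os <- outcome_model_spec(
    severe = list(target_prev = 0.05, gamma = c(cam_bump = 0),
                  cov = c(age = 0, male = 0, height = 0, weight = 0,
                          ethnicity_white = 0))
  )
  sim <- sample_cohort(generative_shape_spec(), os, n = 20000, seed = 29,
                       landmarks = FALSE)
  sc <- sim$scores |>
    dplyr::transmute(subject_id, hsm = match(mode, unique(mode)),
                     score_std = score_feature)
  res <- fit_hsm_logistic(sc, sim$cohort, "rhoa_ge3")
  covered <- res$ci_low <= 1 & res$ci_high >= 1
  expect_gte(sum(covered), nrow(res) - 1)
})

test_that("measured angles track their generating morphologies", {
  sim <- sample_cohort(n = 1500, seed = 31)
  meas <- measure_hips(sim$landmarks)
  sw <- tidyr::pivot_wider(sim$scores[, c("subject_id", "mode", "score_std")],
                           names_from = "mode", values_from = "score_std")
  d <- dplyr::inner_join(meas, sw, by = "subject_id")
  expect_gt(cor(d$alpha_angle, d$cam_bump, method = "spearman"), 0.5)
  expect_gt(cor(d$lcea, d$acetab_coverage, method = "spearman"), 0.5)
})

test_that("mean alpha angle rises with the cam-mode score SD", {
  lo <- generative_shape_spec(score_sd = c(head_size = 4, neck_width = 3,
                                           cam_bump = 1, acetab_coverage = 5,
                                           troch_size = 2.5, neck_length = 2))
  hi <- generative_shape_spec(score_sd = c(head_size = 4, neck_width = 3,
                                           cam_bump = 6, acetab_coverage = 5,
                                           troch_size = 2.5, neck_length = 2))
  m_lo <- measure_hips(sample_cohort(lo, n = 400, seed = 37)$landmarks)
  m_hi <- measure_hips(sample_cohort(hi, n = 400, seed = 37)$landmarks)
  expect_gt(mean(m_hi$alpha_angle), mean(m_lo$alpha_angle))
})

test_that("intercept calibration hits its target prevalence", {
  set.seed(41)
  eta <- rnorm(100000, 0, 1.3)
  b <- calibrate_intercept(eta, 0.057)
  expect_equal(mean(plogis(b + eta)), 0.057, tolerance = 1e-8)
  expect_error(calibrate_intercept(eta, 1.2), "target")
})
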