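feature_scores_long <- function(sim) {
  sim$scores |>
    dplyr::transmute(subject_id,
                     hsm = match(mode, unique(mode)),
                     score_std = score_feature)
}

test_that("logistic models recover an injected per-SD odds ratio", {
  sim <- sample_cohort(n = 20000, seed = 61, landmarks = FALSE)
  res <- fit_hsm_logistic(feature_scores_long(sim), sim$cohort, "rhoa_ge3")
  cam <- res[res$hsm == 3, ]
  expect_true(cam$ci_low <= 1.5 && 1.5 <= cam$ci_high)
  cov <- res[res$hsm == 4, ]
  expect_true(cov$ci_low <= 0.75 && 0.75 <= cov$ci_high)
  expect_true(all(res$ci_low <= res$effect & res$effect <= res$ci_high))
  expect_true(all(res$effect > 0))
})

test_that("constant outcomes yield flagged non-estimable rows, not errors", {
  sim <- sample_cohort(n = 300, seed = 67, landmarks = FALSE)
  co <- sim$cohort
  co$rhoa_ge3 <- 0L
  res <- fit_hsm_logistic(feature_scores_long(sim), co, "rhoa_ge3")
  expect_true(all(!res$estimable))
  expect_true(all(is.na(res$effect)))

  co$thr_event <- 0L
  rc <- fit_hsm_cox(feature_scores_long(sim), co)
  expect_true(all(!rc$estimable))
})

test_that("Cox models recover an injected log hazard ratio", {
  os <- outcome_model_spec(
    thr = list(target_prev = 0.02, gamma = c(cam_bump = 0.4),
               cov = c(age = 0.04, male = 0, height = 0, weight = 0.01,
                       ethnicity_white = 0), horizon = 6)
  )
  sim <- sample_cohort(generative_shape_spec(), os, n = 20000, seed = 71,
                       landmarks = FALSE)
  res <- fit_hsm_cox(feature_scores_long(sim), sim$cohort)
  cam <- res[res$hsm == 3, ]
  expect_true(cam$ci_low <= exp(0.4) && exp(0.4) <= cam$ci_high)
  # a mode with no hazard effect covers 1
  null_row <- res[res$hsm == 5, ]
  expect_true(null_row$ci_low <= 1 && 1 <= null_row$ci_high)
})

test_that("Bonferroni flag uses a strict 0.05/k threshold", {
  res <- tibble::tibble(hsm = 1:4, outcome = "o", model = "model2",
                        effect = 1, ci_low = 1, ci_high = 1,
                        p_value = c(0.0049, 0.005, 0.5, NA),
                        log_effect = 0, se = 1, estimable = TRUE)
  fl <- bonferroni_flag(res, k_tests = 10)
  expect_equal(fl$significant, c(TRUE, FALSE, FALSE, FALSE))
  fl2 <- bonferroni_flag(res, k_tests = 5)
  expect_equal(fl2$significant[2], TRUE)
  expect_false(any(bonferroni_flag(dplyr::mutate(res, p_value = 0.5))$significant))
})

test_that("attenuation is computed on the excess-odds scale", {
  expect_equal(attenuation_percent(1.49, 1.19), 100 * 0.30 / 0.49,
               tolerance = 1e-12)
  expect_equal(attenuation_percent(1.37, 1.37), 0)
  expect_equal(attenuation_percent(1.5, 1.0), 100)
  # protective ratios share the excess term
  expect_equal(attenuation_percent(0.8, 0.9), 50)
  expect_warning(out <- attenuation_percent(1, 1.2), "undefined")
  expect_true(is.na(out))
})

test_that("cohort description reproduces printed-percentage formatting", {
  expect_identical(count_percent(2314, 40311), "5.7")
  expect_identical(count_percent(0, 100), "0.0")
  sim <- fixture_cohort()
  desc <- describe_cohort(sim$cohort)
  expect_true(all(c("variable", "combined", "male", "female") %in% names(desc)))
  # sex-stratified counts add up to the combined count
  nrow_ <- desc[desc$variable == "n", ]
  expect_equal(as.integer(nrow_$male) + as.integer(nrow_$female),
               as.integer(nrow_$combined))
  ge3 <- desc[desc$variable == "rhoa_ge3", ]
  male_n <- as.integer(sub(" .*", "", ge3$male))
  female_n <- as.integer(sub(" .*", "", ge3$female))
  comb_n <- as.integer(sub(" .*", "", ge3$combined))
  expect_equal(male_n + female_n, comb_n)
})

test_that("type-I error of the per-mode test is near nominal under the null", {
  # replicate-level simulation with all shape effects zero
  os <- outcome_model_spec(
    severe = list(target_prev = 0.05, gamma = c(cam_bump = 0),
                  cov = c(age = 0, male = 0, height = 0, weight = 0,
                          ethnicity_white = 0))
  )
  n_rep <- 120
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- sample_cohort(generative_shape_spec(), os, n = 2000,
                         seed = 1000 + r, landmarks = FALSE)
    sc <- feature_scores_long(sim)
    res <- fit_hsm_logistic(sc[sc$hsm == 3, ], sim$cohort, "rhoa_ge3")
    rej[r] <- res$p_value < 0.05
  }
  # binomial check at alpha = 0.05
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})
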