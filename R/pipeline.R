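# End-to-end orchestration: simulate -> shape model -> measures -> grading ->
# associations -> composites, from a single config with one seed, writing
# CSV/JSON artifacts and a structured log of row counts and exclusions.

#' Pipeline configuration
#'
#' @param n Number of synthetic subjects.
#' @param seed Integer seed funnelled through every stage.
#' @param k Number of shape modes analysed.
#' @param k_tests Number of modes entering the Bonferroni correction
#'   (threshold `0.05 / k_tests`).
#' @param factor Composite visual factor.
#' @param allow_scaling Procrustes scaling flag.
#' @param shape_spec A [generative_shape_spec()].
#' @param outcome_spec An [outcome_model_spec()] (built lazily when `NULL`,
#'   since intercept calibration costs a moment).
#' @param grading A [grading_config()].
#' @param schema A [hip_schema()].
#' @return A `hip_pipeline_config` list.
#' @export
pipeline_config <- function(n = 2000, seed = 1, k = 6, k_tests = 10,
                            factor = 5, allow_scaling = TRUE,
                            shape_spec = NULL, outcome_spec = NULL,
                            grading = grading_config(), schema = hip_schema()) {
  structure(
    list(n = n, seed = as.integer(seed), k = k, k_tests = k_tests,
         factor = factor, allow_scaling = allow_scaling,
         shape_spec = shape_spec, outcome_spec = outcome_spec,
         grading = grading, schema = schema),
    class = "hip_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields (`n_subjects`, `seed`, `k`, `k_tests`, `factor`,
#' `allow_scaling`) and, optionally, generator overrides (`score_sd`,
#' `point_noise_sd`). The subject count key is `n_subjects` because a bare
#' `n` is a YAML 1.1 boolean.
#'
#' @param path YAML file.
#' @return A `hip_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  y <- yaml::read_yaml(path)
  shape_spec <- NULL
  if (!is.null(y$score_sd) || !is.null(y$point_noise_sd)) {
    args <- list()
    if (!is.null(y$score_sd)) args$score_sd <- unlist(y$score_sd)
    if (!is.null(y$point_noise_sd)) args$point_noise_sd <- y$point_noise_sd
    shape_spec <- do.call(generative_shape_spec, args)
  }
  base <- pipeline_config()
  if (!is.null(y$n_subjects)) base$n <- y$n_subjects
  for (f in c("seed", "k", "k_tests", "factor", "allow_scaling")) {
    if (!is.null(y[[f]])) base[[f]] <- y[[f]]
  }
  base$shape_spec <- shape_spec
  base
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Deterministic given the config seed. Stages: (1) simulate landmarks,
#' covariates and outcomes; (2) fit the shape model and score subjects;
#' (3) geometric measures; (4) radiographic OA grading; (5) per-mode
#' logistic / Cox association models (model 2 and the AA/LCEA-adjusted
#' variants) with Bonferroni flags; (6) composite shapes per outcome. Every
#' stage appends a line with row counts to `log.txt` and writes its table
#' under `out_dir`.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with all stage results.
#' @export
run_hip_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (missing(out_dir)) abort("`out_dir` is required.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path)
  logf <- function(stage, ...) {
    line <- paste0("[", stage, "] ", sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    inform(line)
  }

  shape_spec <- config$shape_spec %||% generative_shape_spec()
  outcome_spec <- config$outcome_spec %||% outcome_model_spec()

  sim <- sample_cohort(shape_spec, outcome_spec, n = config$n,
                       seed = config$seed, landmarks = TRUE)
  logf("simulate", "n=%d subjects, %d landmark rows, seed=%d",
       nrow(sim$cohort), nrow(sim$landmarks), config$seed)
  write_cohort(sim$cohort, file.path(out_dir, "cohort.csv"))
  readr::write_csv(sim$scores, file.path(out_dir, "true_scores.csv"), progress = FALSE)

  model <- fit_shape_model(sim$landmarks, config$schema,
                           allow_scaling = config$allow_scaling, k = config$k)
  write_shape_model(model, file.path(out_dir, "model.json"))
  logf("build-ssm", "k=%d retained of %d effective modes; top-10 var %.1f%%",
       model$k, model$n_effective,
       100 * sum(model$var_frac[seq_len(min(10, length(model$var_frac)))]))
  scores <- model$scores
  readr::write_csv(scores, file.path(out_dir, "scores.csv"), progress = FALSE)

  measures <- measure_hips(sim$landmarks, config$schema)
  n_na <- sum(!complete.cases(measures))
  logf("measure", "%d subjects measured, %d with undefined measures",
       nrow(measures), n_na)
  readr::write_csv(measures, file.path(out_dir, "measures.csv"), progress = FALSE)

  grades <- grade_cohort(measures, sim$cohort, config$grading)
  logf("grade", "%d graded; grade2-only %.2f%%, grade>=3 %.2f%%",
       nrow(grades), 100 * mean(grades$rhoa_grade2_only),
       100 * mean(grades$rhoa_ge3))
  readr::write_csv(grades, file.path(out_dir, "grades.csv"), progress = FALSE)

  outcomes <- c("rhoa_grade2_only", "rhoa_ge3", "hoa_hospital")
  assoc <- list()
  for (oc in outcomes) {
    for (ex in c("none", "aa", "lcea")) {
      assoc[[paste(oc, ex)]] <- fit_hsm_logistic(
        scores, sim$cohort, oc, extra = ex, measures = measures)
    }
  }
  for (ex in c("none", "aa", "lcea")) {
    assoc[[paste("thr", ex)]] <- fit_hsm_cox(
      scores, sim$cohort, extra = ex, measures = measures)
  }
  results <- bonferroni_flag(bind_rows(assoc), k_tests = config$k_tests)
  logf("associate", "%d model fits (%d outcomes x 3 adjustments x %d modes), %d significant",
       nrow(results), length(outcomes) + 1, model$k, sum(results$significant))
  readr::write_csv(results, file.path(out_dir, "associations.csv"), progress = FALSE)

  composites <- map(c(outcomes, "thr"), function(oc) {
    build_composite(model, filter(results, .data$model == "model2"), oc,
                    factor = config$factor,
                    p_threshold = 0.05 / config$k_tests)
  })
  names(composites) <- c(outcomes, "thr")
  offsets <- list_rbind(imap(composites, function(cc, oc) {
    tibble(outcome = oc, coord = seq_along(cc$offset), offset = cc$offset)
  }))
  readr::write_csv(offsets, file.path(out_dir, "composite_offsets.csv"), progress = FALSE)
  logf("composite", "%s",
       paste(map_chr(composites, function(cc)
         sprintf("%s:%d modes", cc$outcome, length(cc$included_hsms))),
         collapse = ", "))

  invisible(list(sim = sim, model = model, scores = scores,
                 measures = measures, grades = grades, results = results,
                 composites = composites))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
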