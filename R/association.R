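# Per-mode association models: one exposure at a time (each hip shape mode as
# a standardized score), confounder-adjusted, across outcomes of graded
# severity. Odds/hazard ratios are per 1 SD of mode score with Wald 95% CIs.

default_confounders <- function() c("age", "sex", "height", "weight", "ethnicity_white")

adjustment_columns <- function(extra) {
  switch(extra, none = character(), aa = "alpha_angle", lcea = "lcea",
         abort(paste0("Unknown adjustment: ", extra)))
}

model_label <- function(extra) {
  switch(extra, none = "model2", aa = "model2_aa", lcea = "model2_lcea")
}

assemble_model_frame <- function(scores, cohort, measures, extra) {
  wide <- hsm_wide(scores)
  df <- inner_join(wide, cohort, by = "subject_id")
  extra_cols <- adjustment_columns(extra)
  if (length(extra_cols)) {
    if (is.null(measures)) {
      abort("Angle adjustment requested but `measures` not supplied.")
    }
    df <- inner_join(df, select(measures, "subject_id", all_of(extra_cols)),
                     by = "subject_id")
  }
  df[complete.cases(df[c(grep("^hsm", names(df), value = TRUE),
                         default_confounders(), extra_cols)]), , drop = FALSE]
}

wald_row <- function(est, se, hsm, outcome, label) {
  zcrit <- qnorm(0.975)
  tibble(
    hsm = hsm, outcome = outcome, model = label,
    effect = exp(est), ci_low = exp(est - zcrit * se),
    ci_high = exp(est + zcrit * se),
    p_value = 2 * pnorm(-abs(est / se)),
    log_effect = est, se = se, estimable = TRUE
  )
}

non_estimable_row <- function(hsm, outcome, label, reason) {
  tibble(hsm = hsm, outcome = outcome, model = label,
         effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
         p_value = NA_real_, log_effect = NA_real_, se = NA_real_,
         estimable = FALSE) |>
    mutate(reason = reason)
}

#' Per-mode logistic regression against a binary OA outcome
#'
#' Fits one logistic model per hip shape mode: the standardized mode score as
#' the single exposure, adjusted for age, sex, height, weight and binary
#' white/other ethnicity ("model 2"), optionally further adjusted for the
#' alpha angle or the lateral centre-edge angle. Effects are odds ratios per
#' 1 SD of mode score with Wald 95% CIs and two-sided Wald p values.
#'
#' Outcomes with fewer than 2 events, non-converged fits or separated fits
#' are returned as flagged non-estimable rows rather than errors.
#'
#' @param scores Long standardized score tibble ([score_shapes()] or the
#'   generator's true scores reshaped likewise).
#' @param cohort Cohort tibble containing the outcome and confounders.
#' @param outcome Name of the binary outcome column.
#' @param extra `"none"` (model 2), `"aa"` or `"lcea"`.
#' @param measures Per-subject [measure_hips()] output; required when
#'   `extra != "none"`.
#' @param k Number of modes tested (default: all modes present).
#' @return Tibble of class `hip_association`: one row per mode with `effect`
#'   (OR), `ci_low`, `ci_high`, `p_value`, `log_effect`, `se`, `estimable`.
#' @export
fit_hsm_logistic <- function(scores, cohort, outcome,
                             extra = c("none", "aa", "lcea"),
                             measures = NULL, k = NULL) {
  extra <- match.arg(extra)
  df <- assemble_model_frame(scores, cohort, measures, extra)
  if (!outcome %in% names(df)) abort(paste0("Outcome column not found: ", outcome))
  hsm_cols <- grep("^hsm[0-9]+$", names(df), value = TRUE)
  if (!is.null(k)) hsm_cols <- hsm_cols[seq_len(min(k, length(hsm_cols)))]
  label <- model_label(extra)
  rhs_base <- c(default_confounders(), adjustment_columns(extra))

  rows <- map(seq_along(hsm_cols), function(j) {
    hj <- as.integer(sub("hsm", "", hsm_cols[j]))
    yv <- df[[outcome]]
    if (length(unique(yv)) < 2 || sum(yv) < 2 || sum(1 - yv) < 2) {
      return(non_estimable_row(hj, outcome, label, "fewer than 2 events"))
    }
    fm <- stats::reformulate(c(hsm_cols[j], rhs_base), response = outcome)
    # separation / non-convergence is detected from the fit itself below;
    # muffle glm.fit's warnings rather than surfacing them per mode
    fit <- tryCatch(
      withCallingHandlers(
        glm(fm, data = df, family = binomial()),
        warning = function(w) invokeRestart("muffleWarning")
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      return(non_estimable_row(hj, outcome, label, "fit did not converge"))
    }
    est <- coef(fit)[[hsm_cols[j]]]
    se <- sqrt(diag(vcov(fit)))[[hsm_cols[j]]]
    if (!is.finite(est) || !is.finite(se) || abs(est) > 15 || se > 10) {
      return(non_estimable_row(hj, outcome, label, "separation"))
    }
    wald_row(est, se, hj, outcome, label)
  })
  structure(bind_rows(rows), class = c("hip_association", class(tibble())))
}

#' Per-mode Cox proportional-hazards regression for time to hip replacement
#'
#' One Cox model per mode (Efron tie handling), standardized mode score as
#' the exposure plus the model-2 confounders, optionally further adjusted for
#' alpha angle or lateral centre-edge angle. Hazard ratios per 1 SD with
#' partial-likelihood Wald CIs.
#'
#' @inheritParams fit_hsm_logistic
#' @param time,event Names of the follow-up time (years, >= 0) and event
#'   indicator columns.
#' @return Tibble of class `hip_association` (HR in `effect`).
#' @export
fit_hsm_cox <- function(scores, cohort, time = "thr_time", event = "thr_event",
                        extra = c("none", "aa", "lcea"), measures = NULL,
                        k = NULL) {
  extra <- match.arg(extra)
  df <- assemble_model_frame(scores, cohort, measures, extra)
  if (any(df[[time]] < 0)) abort("Follow-up times must be non-negative.")
  hsm_cols <- grep("^hsm[0-9]+$", names(df), value = TRUE)
  if (!is.null(k)) hsm_cols <- hsm_cols[seq_len(min(k, length(hsm_cols)))]
  label <- model_label(extra)
  rhs_base <- c(default_confounders(), adjustment_columns(extra))
  outcome <- "thr"

  rows <- map(seq_along(hsm_cols), function(j) {
    hj <- as.integer(sub("hsm", "", hsm_cols[j]))
    if (sum(df[[event]]) < 1) {
      return(non_estimable_row(hj, outcome, label, "no events"))
    }
    fm <- stats::reformulate(
      c(hsm_cols[j], rhs_base),
      response = sprintf("Surv(%s, %s)", time, event)
    )
    fit <- tryCatch(
      withCallingHandlers(
        coxph(fm, data = df, ties = "efron"),
        warning = function(w) invokeRestart("muffleWarning")
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(non_estimable_row(hj, outcome, label, "fit failed"))
    }
    est <- coef(fit)[[hsm_cols[j]]]
    se <- sqrt(diag(vcov(fit)))[[hsm_cols[j]]]
    if (!is.finite(est) || !is.finite(se) || abs(est) > 15 || se > 10) {
      return(non_estimable_row(hj, outcome, label, "separation"))
    }
    wald_row(est, se, hj, outcome, label)
  })
  structure(bind_rows(rows), class = c("hip_association", class(tibble())))
}

#' Flag Bonferroni-significant associations
#'
#' Adds a `significant` column: `p_value` strictly below `0.05 / k_tests`
#' (default 0.005 for 10 modes tested; a p value exactly at the threshold is
#' not significant).
#'
#' @param results Association tibble.
#' @param k_tests Number of modes tested (default 10).
#' @return `results` with a logical `significant` column.
#' @export
bonferroni_flag <- function(results, k_tests = 10) {
  thr <- 0.05 / k_tests
  mutate(results, significant = !is.na(.data$p_value) & .data$p_value < thr)
}

#' Attenuation of an odds/hazard ratio on the excess-odds scale
#'
#' `100 * (or_base - or_adjusted) / (or_base - 1)`: the percentage of the
#' excess odds removed by an additional adjustment. The shared excess term
#' handles protective ratios (< 1) with the correct sign. Undefined (NA,
#' with a warning) when the base ratio is exactly 1.
#'
#' @param or_base Base (model 2) odds or hazard ratio.
#' @param or_adjusted Further-adjusted ratio.
#' @return Attenuation percentage (vectorised).
#' @export
attenuation_percent <- function(or_base, or_adjusted) {
  out <- 100 * (or_base - or_adjusted) / (or_base - 1)
  undef <- or_base == 1
  if (any(undef, na.rm = TRUE)) {
    warn("Attenuation undefined for base ratio exactly 1; returning NA.")
    out[undef] <- NA_real_
  }
  out
}

#' Format a count as a percentage with one decimal place
#'
#' @param n Count(s).
#' @param total Denominator.
#' @return Character percentage(s), e.g. `"5.7"`.
#' @export
count_percent <- function(n, total) sprintf("%.1f", 100 * n / total)

fmt_mean_sd <- function(x) sprintf("%.1f (%.1f)", mean(x), sd(x))
fmt_n_pct <- function(n, total) sprintf("%d (%s)", n, count_percent(n, total))

#' Descriptive cohort characteristics, overall and by sex
#'
#' Means (SD) for continuous variables and n (%) for binary outcomes /
#' categorical variables, with percentages to one decimal place -- the
#' standard participant-characteristics layout.
#'
#' @param cohort Cohort tibble.
#' @param measures Optional [measure_hips()] output merged in for the
#'   geometric measures (NSA, NNW, AA, LCEA).
#' @return Tibble with columns `variable`, `combined`, `male`, `female`.
#' @export
describe_cohort <- function(cohort, measures = NULL) {
  if (!is.null(measures)) {
    cohort <- inner_join(cohort,
                         select(measures, "subject_id", "alpha_angle",
                                "lcea", "nsa", "nnw"),
                         by = "subject_id")
  }
  cont <- intersect(c("age", "weight", "height", "nsa", "nnw",
                      "alpha_angle", "lcea"), names(cohort))
  bin <- intersect(c("rhoa_grade2_only", "rhoa_ge3", "hoa_hospital",
                     "thr_event", "ethnicity_white"), names(cohort))
  groups <- list(combined = rep(TRUE, nrow(cohort)),
                 male = cohort$sex == "M",
                 female = cohort$sex == "F")
  one_var <- function(v, type) {
    vals <- map_chr(groups, function(g) {
      x <- cohort[[v]][g]
      if (type == "cont") fmt_mean_sd(x) else fmt_n_pct(sum(x), length(x))
    })
    tibble(variable = v, combined = vals[["combined"]],
           male = vals[["male"]], female = vals[["female"]])
  }
  n_row <- tibble(variable = "n",
                  combined = as.character(sum(groups$combined)),
                  male = as.character(sum(groups$male)),
                  female = as.character(sum(groups$female)))
  bind_rows(n_row,
            list_rbind(map(cont, one_var, type = "cont")),
            list_rbind(map(bin, one_var, type = "bin")))
}
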