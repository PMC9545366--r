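# Synthetic cohort generator: Gaussian mode scores deform the template,
# covariates follow documented population margins, and outcomes follow
# logistic (prevalent disease grades) and exponential proportional-hazards
# (hip replacement) models with per-SD effect sizes.
#
# For the two named morphologies (cam_bump, acetab_coverage) the outcome
# models act on *realized feature scores*: geometric latents of the rendered
# anatomy (the realized junction-departure angle against the true head
# circle, and the realized lateral-coverage angle of the acetabular edge),
# standardized against a fixed reference distribution. This mirrors the
# epidemiology being emulated: risk follows the subject's realized junction /
# coverage morphology -- which the measured alpha angle and centre-edge angle
# estimate directly -- while a global shape-mode score is only a coarse
# summary of it. Effects on all other modes are per SD of the latent score.

# rendered coordinates of a subset of landmarks: returns list(X, Y), each an
# n x length(idx) matrix (template + mode displacements + noise)
render_point_subset <- function(shape_spec, z_raw, noise, idx) {
  cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  tplv <- xy_to_vec(config_matrix(shape_spec$template))[cols]
  flat <- z_raw %*% t(shape_spec$modes[cols, , drop = FALSE]) + noise
  flat <- sweep(flat, 2, tplv, "+")
  odd <- seq(1, ncol(flat), 2)
  list(X = flat[, odd, drop = FALSE], Y = flat[, odd + 1, drop = FALSE])
}

feature_point_idx <- function(schema) {
  sort(unique(c(schema$head_circle_idx,
                seq(min(schema$superior_head_idx), max(schema$superior_neck_idx)),
                schema$superior_neck_idx, schema$inferior_neck_idx,
                schema$lateral_acetabular_edge_idx)))
}

# Unstandardized geometric feature latents (degrees) for each subject:
# cam_bump -> realized alpha-angle morphology: walk the rendered superior
#   outline against the true head circle (centre at the template's origin,
#   departure tolerance 2% above the subject's realized mean head radius),
#   junction interpolated on the first sustained crossing;
# acetab_coverage -> realized centre-edge angle of the rendered lateral
#   acetabular edge about the template head centre.
feature_latents <- function(shape_spec, z_raw, noise_sub, idx) {
  schema <- shape_spec$schema
  rp <- render_point_subset(shape_spec, z_raw, noise_sub, idx)
  out <- list()
  hcol <- match(schema$head_circle_idx, idx)
  hx <- rp$X[, hcol, drop = FALSE]
  hy <- rp$Y[, hcol, drop = FALSE]
  # two per-subject head centres serve the two latents:
  # (i) a vectorized Kasa circle fit over the (noisy) head-circle points --
  #     the junction latent must see the same circle the alpha-angle
  #     measurement will fit, or the measured angle decouples from it;
  # (ii) the deterministic anatomical centre (template origin plus the
  #     mode-driven mean head displacement, noise-free) for the coverage
  #     latent, whose defining landmark (the acetabular edge) is not a
  #     circle-fit point -- keeping the two latents' noise sources disjoint
  hz <- hx^2 + hy^2
  sx <- rowMeans(hx); sy <- rowMeans(hy); sz <- rowMeans(hz)
  sxx <- rowMeans(hx^2) - sx^2
  syy <- rowMeans(hy^2) - sy^2
  sxy <- rowMeans(hx * hy) - sx * sy
  sxz <- rowMeans(hx * hz) - sx * sz
  syz <- rowMeans(hy * hz) - sy * sz
  det <- sxx * syy - sxy^2
  cx <- (sxz * syy - syz * sxy) / (2 * det)
  cy <- (syz * sxx - sxz * sxy) / (2 * det)
  odd <- seq(1, 2 * length(idx), 2)
  tplm <- config_matrix(shape_spec$template)
  cx_det <- rowMeans(hx - noise_sub[, odd, drop = FALSE][, hcol, drop = FALSE]) -
    mean(tplm[schema$head_circle_idx, 1])
  cy_det <- rowMeans(hy - noise_sub[, odd + 1, drop = FALSE][, hcol, drop = FALSE]) -
    mean(tplm[schema$head_circle_idx, 2])
  if ("cam_bump" %in% shape_spec$mode_names) {
    walk <- seq(min(schema$superior_head_idx), max(schema$superior_neck_idx))
    wcol <- match(walk, idx)
    dh <- sqrt((hx - cx)^2 + (hy - cy)^2)
    r_realized <- rowMeans(dh)
    rms_realized <- sqrt(rowMeans((dh - r_realized)^2))
    delta <- pmax(0.02, 3 * rms_realized / r_realized)
    thresh <- r_realized * (1 + delta)
    d <- sqrt((rp$X[, wcol, drop = FALSE] - cx)^2 +
                (rp$Y[, wcol, drop = FALSE] - cy)^2)
    outside <- d > thresh
    sustained <- outside & cbind(outside[, -1, drop = FALSE], TRUE)
    has <- rowSums(sustained) > 0
    k <- max.col(sustained, ties.method = "first")
    k[!has] <- ncol(d) # fall back to the walk end (far outside by design)
    n <- nrow(d)
    rows <- seq_len(n)
    kprev <- pmax(k - 1L, 1L)
    dk <- d[cbind(rows, k)]
    dp <- d[cbind(rows, kprev)]
    tt <- (thresh - dp) / (dk - dp)
    tt[k == 1L | !is.finite(tt)] <- 1
    tt <- pmin(1, pmax(0, tt))
    jx <- rp$X[cbind(rows, wcol[kprev])] +
      tt * (rp$X[cbind(rows, wcol[k])] - rp$X[cbind(rows, wcol[kprev])]) - cx
    jy <- rp$Y[cbind(rows, wcol[kprev])] +
      tt * (rp$Y[cbind(rows, wcol[k])] - rp$Y[cbind(rows, wcol[kprev])]) - cy
    # realized neck-ward axis: Kasa centre towards the midpoint of the two
    # realized neck-border centroids, so the latent rotates with the bone
    # (any constant offset is absorbed by the reference standardization)
    scol <- match(schema$superior_neck_idx, idx)
    icol <- match(schema$inferior_neck_idx, idx)
    nx <- (rowMeans(rp$X[, scol, drop = FALSE]) +
             rowMeans(rp$X[, icol, drop = FALSE])) / 2 - cx
    ny <- (rowMeans(rp$Y[, scol, drop = FALSE]) +
             rowMeans(rp$Y[, icol, drop = FALSE])) / 2 - cy
    out$cam_bump <- angle_between_deg(vec_angle_deg(nx, ny),
                                      vec_angle_deg(jx, jy))
  }
  if ("acetab_coverage" %in% shape_spec$mode_names) {
    ecol <- match(schema$lateral_acetabular_edge_idx, idx)
    out$acetab_coverage <-
      vec_angle_deg(rp$X[, ecol] - cx_det, rp$Y[, ecol] - cy_det) - 90
  }
  out
}

# reference mean/SD of each feature latent under the generator's own
# distribution (fixed private RNG stream, so standardization constants are a
# property of the shape spec, not of any particular sample)
feature_reference_stats <- function(shape_spec, n_mc = 50000L) {
  if (!any(c("cam_bump", "acetab_coverage") %in% shape_spec$mode_names)) {
    return(list())
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(20240086)
  k <- length(shape_spec$mode_names)
  z_raw <- sweep(matrix(rnorm(n_mc * k), n_mc, k), 2, shape_spec$score_sd, "*")
  idx <- feature_point_idx(shape_spec$schema)
  noise_sub <- matrix(rnorm(n_mc * 2 * length(idx), 0, shape_spec$point_noise_sd),
                      n_mc)
  lat <- feature_latents(shape_spec, z_raw, noise_sub, idx)
  lapply(lat, function(x) c(mean = mean(x), sd = sd(x)))
}

# standardized realized feature scores merged over the latent scores;
# noise_sub must already be restricted to feature_point_idx() columns
feature_scores <- function(shape_spec, z_std, z_raw, noise_sub, idx) {
  z_eff <- z_std
  stats <- shape_spec$feature_stats
  if (length(stats)) {
    lat <- feature_latents(shape_spec, z_raw, noise_sub, idx)
    for (nm in names(stats)) {
      z_eff[, nm] <- (lat[[nm]] - stats[[nm]][["mean"]]) / stats[[nm]][["sd"]]
    }
  }
  z_eff
}

covariate_centers <- function() c(age = 63.7, height = 170.1, weight = 75.4)

#' Outcome model specification for the synthetic cohort
#'
#' Defines intercepts, per-mode log-odds/log-hazard effects (per 1 SD of mode
#' score), covariate effects, the exponential baseline hazard and
#' administrative censoring horizon for time-to-replacement, and the
#' conditional gamma distributions of osteophyte areas given case status.
#'
#' Default intercepts are calibrated by Monte-Carlo so the marginal
#' prevalences at the default effect sizes are approximately 5.7% (moderate
#' radiographic OA), 1.7% (grade >= 3), 1.3% (hospital-diagnosed OA) and 0.6%
#' (hip replacement within the 6-year horizon). Default effects place a
#' positive cam-mode and negative coverage-mode effect on the severe
#' outcomes, and neck-width/coverage/trochanter effects on the moderate
#' outcome, mirroring the severity contrast the analysis is designed to
#' detect.
#'
#' @param moderate,severe,hospital Lists with elements `target_prev` (marginal
#'   prevalence used to calibrate the intercept), `gamma` (named per-mode
#'   log-odds per SD; for the cam and coverage modes the SD is of the
#'   realized feature score, see [sample_cohort()]) and `cov` (named
#'   covariate effects on centred age,
#'   male indicator, centred height, centred weight, white-ethnicity
#'   indicator).
#' @param thr List with `target_prev` (cumulative event fraction at the
#'   horizon), `gamma`, `cov`, and `horizon` (administrative censoring, years).
#' @param osteophyte Conditional area model: for each severity class, a
#'   zero-inflation probability `p_zero` and gamma `shape`/`scale` (mm^2).
#' @param shape_spec The [generative_shape_spec()] the outcomes will be
#'   paired with; used to marginalise the realized feature scores during
#'   intercept calibration.
#' @param calibrate_n Monte-Carlo size for intercept calibration.
#' @return An object of class `hip_outcome_spec`.
#' @export
outcome_model_spec <- function(
    moderate = list(target_prev = 0.057,
                    gamma = c(neck_width = log(1.2), acetab_coverage = log(1.2),
                              troch_size = log(1.15)),
                    cov = c(age = 0.03, male = 0.85, height = 0, weight = 0.012,
                            ethnicity_white = 0)),
    severe = list(target_prev = 0.017,
                  gamma = c(cam_bump = log(1.5), acetab_coverage = log(0.75)),
                  cov = c(age = 0.04, male = 0.9, height = 0, weight = 0.01,
                          ethnicity_white = 0)),
    hospital = list(target_prev = 0.013,
                    gamma = c(cam_bump = log(1.3), acetab_coverage = log(0.8)),
                    cov = c(age = 0.05, male = -0.15, height = 0, weight = 0.01,
                            ethnicity_white = 0)),
    thr = list(target_prev = 0.006,
               gamma = c(cam_bump = 0.3, acetab_coverage = -0.25),
               cov = c(age = 0.04, male = 0, height = 0, weight = 0.01,
                       ethnicity_white = 0),
               horizon = 6),
    osteophyte = list(
      control = list(p_zero = 0.70, shape = 0.8, scale = 0.8),
      moderate = list(p_zero = 0.10, shape = 2.0, scale = 2.0),
      severe = list(p_zero = 0.02, shape = 3.0, scale = 4.0)
    ),
    shape_spec = generative_shape_spec(),
    calibrate_n = 100000L) {
  default_args <- missing(moderate) && missing(severe) && missing(hospital) &&
    missing(thr) && missing(osteophyte) && missing(shape_spec) &&
    missing(calibrate_n)
  if (default_args && exists("default_outcome_spec", envir = .hipshapes_cache)) {
    return(get("default_outcome_spec", envir = .hipshapes_cache))
  }
  spec <- structure(
    list(moderate = moderate, severe = severe, hospital = hospital, thr = thr,
         osteophyte = osteophyte),
    class = "hip_outcome_spec"
  )
  spec <- calibrate_outcome_spec(spec, shape_spec, n_mc = calibrate_n)
  if (default_args) assign("default_outcome_spec", spec, envir = .hipshapes_cache)
  spec
}

# linear predictor (without intercept) for one outcome given standardized
# scores (n x K, named cols) and a covariate tibble
outcome_eta <- function(model, z_std, covars) {
  cen <- covariate_centers()
  g <- model$gamma
  eta <- rep(0, nrow(covars))
  for (nm in names(g)) {
    if (nm %in% colnames(z_std)) eta <- eta + g[[nm]] * z_std[, nm]
  }
  cv <- model$cov
  eta +
    cv[["age"]] * (covars$age - cen[["age"]]) +
    cv[["male"]] * (covars$sex == "M") +
    cv[["height"]] * (covars$height - cen[["height"]]) +
    cv[["weight"]] * (covars$weight - cen[["weight"]]) +
    cv[["ethnicity_white"]] * covars$ethnicity_white
}

#' Calibrate a logistic intercept to a marginal prevalence
#'
#' Finds the intercept `b` such that `mean(plogis(b + eta)) == target` for a
#' sample of linear predictors `eta` (Monte-Carlo marginalisation over the
#' score and covariate distributions).
#'
#' @param eta Numeric vector of linear predictors without intercept.
#' @param target Target marginal prevalence in (0, 1).
#' @return The intercept (scalar).
#' @export
calibrate_intercept <- function(eta, target) {
  if (target <= 0 || target >= 1) abort("`target` must be in (0, 1).")
  uniroot(function(b) mean(plogis(b + eta)) - target,
          lower = -30, upper = 10, tol = 1e-10)$root
}

calibrate_outcome_spec <- function(spec, shape_spec, n_mc = 100000L) {
  # marginalise with a private RNG stream so calibration is reproducible and
  # does not disturb the caller's seed
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(20240085)
  k <- length(shape_spec$mode_names)
  z_std <- matrix(rnorm(n_mc * k), n_mc, k,
                  dimnames = list(NULL, shape_spec$mode_names))
  z_raw <- sweep(z_std, 2, shape_spec$score_sd, "*")
  idx <- feature_point_idx(shape_spec$schema)
  noise_sub <- matrix(rnorm(n_mc * 2 * length(idx), 0,
                            shape_spec$point_noise_sd), n_mc)
  z <- feature_scores(shape_spec, z_std, z_raw, noise_sub, idx)
  covars <- sample_covariates(n_mc)

  eta_sev <- outcome_eta(spec$severe, z, covars)
  spec$severe$intercept <- calibrate_intercept(eta_sev, spec$severe$target_prev)
  p_sev <- mean(plogis(spec$severe$intercept + eta_sev))

  # moderate is sampled among non-severe subjects; calibrate the conditional
  # probability so the marginal prevalence hits its target
  eta_mod <- outcome_eta(spec$moderate, z, covars)
  spec$moderate$intercept <-
    calibrate_intercept(eta_mod, spec$moderate$target_prev / (1 - p_sev))

  eta_hosp <- outcome_eta(spec$hospital, z, covars)
  spec$hospital$intercept <- calibrate_intercept(eta_hosp, spec$hospital$target_prev)

  eta_thr <- outcome_eta(spec$thr, z, covars)
  h <- spec$thr$horizon
  spec$thr$log_baseline_rate <- uniroot(
    function(lb) mean(1 - exp(-h * exp(lb + eta_thr))) - spec$thr$target_prev,
    lower = -20, upper = 2, tol = 1e-12
  )$root
  spec
}

sample_covariates <- function(n) {
  male <- rbinom(n, 1, 0.478) == 1
  tibble(
    age = rnorm(n, 63.7, 7.6),
    sex = ifelse(male, "M", "F"),
    height = ifelse(male, rnorm(n, 177.2, 6.6), rnorm(n, 163.6, 6.4)),
    weight = ifelse(male, rnorm(n, 83.2, 13.4), rnorm(n, 68.2, 12.9)),
    ethnicity_white = rbinom(n, 1, 0.968)
  )
}

sample_osteo_area <- function(n, model) {
  zero <- rbinom(n, 1, model$p_zero) == 1
  a <- rgamma(n, shape = model$shape, scale = model$scale)
  a[zero] <- 0
  a
}

#' Sample a synthetic hip-shape cohort
#'
#' Draws per-subject mode scores `z_i ~ N(0, s_i^2)`, renders landmark
#' configurations as `template + sum(z_i * mode_i) + noise`, samples
#' covariates from documented population margins, and generates outcomes from
#' the logistic / proportional-hazards models in `outcome_spec`. Identical
#' seeds give identical output.
#'
#' @param shape_spec A [generative_shape_spec()].
#' @param outcome_spec An [outcome_model_spec()].
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed; required, all randomness is derived from it.
#' @param landmarks If `FALSE`, skip rendering landmark tibbles (much faster
#'   when only scores/outcomes are needed, e.g. association simulations).
#' @return A list with `landmarks` (long tibble or `NULL`), `cohort`
#'   (covariates, osteophyte areas, outcome flags, `thr_event`/`thr_time`),
#'   and `scores` (long format: true standardized and raw mode scores, plus
#'   `score_feature`, the realized morphology score the outcome models act
#'   on -- equal to `score_std` except for the cam and coverage modes, where
#'   it is the standardized realized junction-departure / coverage angle of
#'   the rendered anatomy).
#' @export
sample_cohort <- function(shape_spec = generative_shape_spec(),
                          outcome_spec = outcome_model_spec(),
                          n = 1000, seed, landmarks = TRUE) {
  if (missing(seed)) abort("`seed` is required for reproducible sampling.")
  if (n < 1) abort("`n` must be >= 1.")
  check_mode_orthogonality(shape_spec$modes)
  set.seed(seed)

  k <- length(shape_spec$mode_names)
  p <- shape_spec$schema$n_points
  z_std <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, shape_spec$mode_names))
  z_raw <- sweep(z_std, 2, shape_spec$score_sd, "*")
  noise <- matrix(rnorm(n * 2 * p, 0, shape_spec$point_noise_sd), n)
  covars <- sample_covariates(n)
  ids <- sprintf("S%06d", seq_len(n))

  # realized geometric feature scores for the named morphologic modes
  fidx <- feature_point_idx(shape_spec$schema)
  fcols <- as.vector(rbind(2L * fidx - 1L, 2L * fidx))
  z_eff <- feature_scores(shape_spec, z_std, z_raw,
                          noise[, fcols, drop = FALSE], fidx)

  sev <- rbinom(n, 1, plogis(outcome_spec$severe$intercept +
                               outcome_eta(outcome_spec$severe, z_eff, covars)))
  mod <- rbinom(n, 1, plogis(outcome_spec$moderate$intercept +
                               outcome_eta(outcome_spec$moderate, z_eff, covars)))
  mod[sev == 1] <- 0L
  hosp <- rbinom(n, 1, plogis(outcome_spec$hospital$intercept +
                                outcome_eta(outcome_spec$hospital, z_eff, covars)))
  rate <- exp(outcome_spec$thr$log_baseline_rate +
                outcome_eta(outcome_spec$thr, z_eff, covars))
  t_raw <- rexp(n, rate)
  horizon <- outcome_spec$thr$horizon
  thr_event <- as.integer(t_raw <= horizon)
  thr_time <- pmin(t_raw, horizon)

  status <- ifelse(sev == 1, "severe", ifelse(mod == 1, "moderate", "control"))
  osteo <- vapply(c("osteo_area_lat_acetabulum", "osteo_area_sup_lat_head",
                    "osteo_area_inf_med_head"), function(site) {
    a <- numeric(n)
    for (cls in c("control", "moderate", "severe")) {
      sel <- status == cls
      if (any(sel)) a[sel] <- sample_osteo_area(sum(sel), outcome_spec$osteophyte[[cls]])
    }
    a
  }, numeric(n))

  cohort <- bind_cols(tibble(subject_id = ids), covars,
                      as_tibble(osteo),
                      tibble(rhoa_grade2_only = mod, rhoa_ge3 = sev,
                             hoa_hospital = hosp, thr_event = thr_event,
                             thr_time = thr_time))

  lm_tbl <- NULL
  if (landmarks) {
    tpl <- xy_to_vec(config_matrix(shape_spec$template))
    flat <- matrix(rep(tpl, each = n), n) + z_raw %*% t(shape_spec$modes) + noise
    lm_tbl <- tibble(
      subject_id = rep(ids, each = p),
      point = rep(seq_len(p), times = n),
      x = as.vector(t(flat[, seq(1, 2 * p, by = 2), drop = FALSE])),
      y = as.vector(t(flat[, seq(2, 2 * p, by = 2), drop = FALSE]))
    )
  }

  scores <- tibble(subject_id = rep(ids, times = k),
                   mode = rep(shape_spec$mode_names, each = n),
                   score_std = as.vector(z_std), score_raw = as.vector(z_raw),
                   score_feature = as.vector(z_eff)) |>
    arrange(match(.data$subject_id, ids))

  list(landmarks = lm_tbl, cohort = cohort, scores = scores)
}
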