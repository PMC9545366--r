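# Shared fixtures built in code at test time.

# small cached cohort so several test files can share one simulation
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sample_cohort(n = 400, seed = 101)
    }
    cache
  }
})

# template deformed by given raw weights on named default generator modes
apply_mode_weights <- function(spec, weights, subject_id = "deformed") {
  z <- stats::setNames(numeric(length(spec$mode_names)), spec$mode_names)
  z[names(weights)] <- weights
  v <- hipshapes:::xy_to_vec(hipshapes:::config_matrix(spec$template)) +
    drop(spec$modes %*% z)
  hipshapes:::xy_to_landmarks(hipshapes:::vec_to_xy(v), subject_id = subject_id)
}

# landmark tibble from an n x 2 matrix
lm_from_matrix <- function(m, id = "s1") {
  tibble::tibble(subject_id = id, point = seq_len(nrow(m)),
                 x = m[, 1], y = m[, 2])
}
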