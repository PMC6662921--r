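# Small fixtures built in code, shared across test files.

# Cohort in which every code appears independently at `rate` (no latent
# structure), useful for closed-form probability checks.
background_only_cohort <- function(n_patients, n_codes, rate, seed = 1L,
                                   hidden_flag_rate = 0) {
  cfg <- cohort_config(
    n_patients = n_patients, n_codes = n_codes, n_latent = 1,
    latent_prevalences = 0, emission_probs = matrix(0, 1, n_codes),
    background_rate = rate, hidden_flag_rate = hidden_flag_rate,
    seed = seed
  )
  generate_cohort(cfg)
}

# Cohort built directly from explicit code sets (1-based indices).
codeset_cohort <- function(code_sets, n_codes) {
  as_ehr_cohort(code_sets, n_codes)
}

# Linearly separable two-class toy problem with a wide margin.
separable_toy <- function(n = 200, d = 10, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  # push the two classes apart so a perfect classifier exists with margin
  X[, 1] <- X[, 1] + ifelse(y == 1, 1.5, -1.5)
  list(X = X, y = y,
       X_train = X[1:(n * 0.75), ], y_train = y[1:(n * 0.75)],
       X_val = X[(n * 0.75 + 1):n, ], y_val = y[(n * 0.75 + 1):n])
}

# Brute-force average precision: walk every distinct threshold and
# accumulate precision * recall increments. O(n^2), independent of the
# package implementation.
auprc_bruteforce <- function(labels, scores) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    sel <- scores >= t
    precision <- sum(labels[sel] == 1) / sum(sel)
    recall <- sum(labels[sel] == 1) / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}
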