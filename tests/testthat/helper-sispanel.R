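# Shared fixtures and independent oracles for the test suite.

# Small standardized cohort for model-level tests.
tiny_cohort <- function(p = 10, n_case = 20, n_control = 20,
                        true_markers = 1:2, delta = 2, seed = 42, ...) {
  d <- cohort_design(n_case = n_case, n_control = n_control, p = p,
                     true_markers = true_markers, delta = delta,
                     seed = seed, ...)
  sim <- simulate_cohort(d)
  sim$standardized <- log2_standardize(sim$expression)
  sim
}

# Brute-force O(n^2) pair-count AUC: the independent oracle for
# empirical_auc (ties counted half).
brute_force_auc <- function(scores, y) {
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# Hand-built marker-stat tibble for screening fixtures.
stats_fixture <- function(marker_id, p_t, p_ks = p_t, p_mw = p_t,
                          stat_t = -seq_along(marker_id),
                          stat_ks = seq_along(marker_id) / 10,
                          stat_mw = seq_along(marker_id)) {
  tibble::tibble(marker_id = marker_id, log2fc = 0,
                 stat_t = stat_t, p_t = p_t,
                 stat_ks = stat_ks, p_ks = p_ks,
                 stat_mw = stat_mw, p_mw = p_mw)
}
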