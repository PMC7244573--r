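# Shared fixtures: tiny cells tables and fast Monte Carlo settings.

# One participant's two-measure cells from per-lag success counts.
mk_cells <- function(s1, s2, n = 100, participant = "p1",
                     measures = c("accuracy", "visibility_high"),
                     lags = seq_along(s1)) {
  tibble::tibble(
    participant = participant,
    measure = rep(measures, each = length(s1)),
    lag = rep(lags, 2),
    successes = as.integer(c(s1, s2)),
    trials = as.integer(rep(n, 2 * length(s1)))
  )
}

# Single-axis cells (for validity tests).
mk_axis_cells <- function(s, n = 100, participant = "p1", axis = "accuracy",
                          lags = seq_along(s)) {
  tibble::tibble(
    participant = participant,
    measure = axis,
    lag = lags,
    successes = as.integer(s),
    trials = as.integer(rep(n, length(s)))
  )
}

# Desk-scale MC settings: enough samples for the tolerances used in the
# tests, with a finite cap so strongly informative data return bounds fast.
mc_quick <- function(n = 5e4, seed = 1, cap = 8 * n) {
  mc_settings(n_samples = n, seed = seed, max_total_samples = cap)
}

# Visibility distribution with most mass on rating 1, as in blinked trials.
vis_mass_low <- function(k = 2) {
  m <- matrix(rep(c(0.6, 0.15, 0.1, 0.07, 0.05, 0.03), k),
              nrow = k, byrow = TRUE)
  m / rowSums(m)
}

# Six-trial toy table exercising every conditioning rule.
toy_trials <- function() {
  tibble::tibble(
    participant = "p1",
    lag = c(1L, 1L, 1L, 3L, 3L, 3L),
    t1_correct = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    t2_correct = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    visibility = c(4L, 2L, 6L, 1L, 3L, 5L),
    order_error = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
}
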