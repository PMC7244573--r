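# Shared synthetic dataset: accuracy strongly ordered lag1 > lag2, flat
# elsewhere, 12 participants.
profile_trials <- function(seed = 2) {
  d <- make_design("flat", lags = c(1, 2, 3),
                   theta_acc = c(0.9, 0.1, 0.5),
                   n_participants = 12, n_trials_per_lag = 100,
                   participant_jitter_sd = 0.2)
  simulate_trials(d, seed = seed)
}

test_that("validity profile separates supported and contradicted constraints", {
  cells <- to_cells(condition_t2_trials(profile_trials(), TRUE, FALSE))
  supported <- constraint_validity_profile(
    cells, constraint_set("accuracy: 1 > 2"), mc_quick(2e4, seed = 3))
  contradicted <- constraint_validity_profile(
    cells, constraint_set("accuracy: 2 > 1"), mc_quick(2e4, seed = 3))
  expect_gt(supported$gbf, 1e3)
  expect_lt(contradicted$gbf, 1e-3)
})

test_that("a flat design yields directionless grouped validity", {
  # Under a flat design the posterior probability of a single constraint is
  # asymptotically Uniform(0, 1) per participant, so each log10 validity BF
  # is log10 of standard-logistic odds (sd pi/(sqrt(3) ln 10) ~ 0.79) and
  # the 20-participant group log10 BF has null sd ~ 0.79 * sqrt(20); stay
  # within 3 of those sds.
  d <- make_design("flat", n_participants = 20, n_trials_per_lag = 50)
  cells <- to_cells(condition_t2_trials(simulate_trials(d, seed = 4),
                                        TRUE, FALSE))
  prof <- constraint_validity_profile(
    cells, constraint_set("accuracy: 1 > 2"), mc_quick(2e4, seed = 5))
  null_sd <- (pi / (sqrt(3) * log(10))) * sqrt(20)
  expect_lt(abs(prof$log10_gbf), 3 * null_sd)
})

test_that("profiles from two seeds agree within combined MC error", {
  cells <- to_cells(condition_t2_trials(profile_trials(), TRUE, FALSE))
  cand <- constraint_set("accuracy: 1 > 3")
  p1 <- constraint_validity_profile(cells, cand, mc_quick(4e4, seed = 11))
  p2 <- constraint_validity_profile(cells, cand, mc_quick(4e4, seed = 99))
  se1 <- p1$group[[1]]$mc_se_log10
  se2 <- p2$group[[1]]$mc_se_log10
  expect_lt(abs(p1$log10_gbf - p2$log10_gbf),
            3 * sqrt(se1^2 + se2^2))
})

test_that("reduce_constraints retains by threshold and is idempotent", {
  prof <- tibble::tibble(
    axis = "accuracy",
    greater_lag = c(1L, 4L, 6L),
    lesser_lag = c(2L, 3L, 2L),
    gbf = c(1e5, 0.2, 3.1)
  )
  kept <- reduce_constraints(prof, threshold = 1)
  expect_setequal(format_constraints(kept),
                  c("accuracy: 1 > 2", "accuracy: 6 > 2"))
  # idempotence: re-scoring the retained set leaves it unchanged
  prof2 <- prof[prof$gbf >= 1, ]
  expect_identical(format_constraints(reduce_constraints(prof2, 1)),
                   format_constraints(kept))
  expect_identical(
    format_constraints(reduce_constraints(dplyr::mutate(prof, gbf = 10), 1)),
    format_constraints(constraint_set(prof[c("axis", "greater_lag",
                                             "lesser_lag")])))
  expect_error(reduce_constraints(prof[0, ]), "Empty")
  expect_error(reduce_constraints(prof, 0), "threshold")
})

test_that("split selection recovers the informative 3|4 boundary", {
  # ratings 4-6 carry the constrained ordering; 1-3 are uniform noise
  p_high <- c(0.2, 0.45, 0.7)
  vis_probs <- t(vapply(p_high, function(p) {
    c(rep((1 - p) / 3, 3), p * c(0.3, 0.35, 0.35))
  }, numeric(6)))
  d <- make_design("flat", lags = c(2, 3, 4), vis_probs = vis_probs,
                   n_participants = 12, n_trials_per_lag = 150,
                   participant_jitter_sd = 0.1)
  trials <- condition_t2_trials(simulate_trials(d, seed = 6), TRUE, FALSE)
  cs <- constraint_set(c("visibility_high: 4 > 3", "visibility_high: 3 > 2"))
  sel <- select_visibility_split(trials, cs, mc_quick(2e4, seed = 7))
  expect_equal(sel$split_point, 3)
  expect_equal(nrow(sel$by_split), 5)

  # invariant to participant ordering
  shuffled <- dplyr::arrange(trials, dplyr::desc(participant))
  sel2 <- select_visibility_split(shuffled, cs, mc_quick(2e4, seed = 7))
  expect_equal(sel2$split_point, sel$split_point)

  flat_ratings <- dplyr::mutate(trials, visibility = 4L)
  expect_error(select_visibility_split(flat_ratings, cs, mc_quick(1e3)),
               "identical")
})
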