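test_that("prior region probabilities match the closed form and trivia", {
  cells <- mk_cells(c(0, 0, 0), c(0, 0, 0), n = 0)
  rp <- region_probability(cells, monotone_predicate(),
                           mc_quick(2e5, seed = 5), posterior = FALSE)
  expect_lt(abs(rp$estimate - 1 / 3), 3 * rp$se)

  rp_all <- region_probability(cells, always_true_predicate(),
                               mc_quick(1e4, seed = 6), posterior = FALSE)
  expect_equal(rp_all$estimate, 1)

  # posterior over all-zero cells is the prior
  rp_post <- region_probability(cells, monotone_predicate(),
                                mc_quick(2e5, seed = 7),
                                posterior = TRUE, allow_empty_cells = TRUE)
  expect_lt(abs(rp_post$estimate - 1 / 3),
            3 * sqrt(rp_post$se^2 + rp$se^2) + 1e-12)
  expect_error(
    region_probability(cells, monotone_predicate(), mc_quick(1e3)),
    "allow_empty_cells")
})

test_that("monotonicity BF responds to strong structure in both directions", {
  up <- mk_cells(c(5, 50, 95), c(5, 50, 95))
  bf_up <- bf_monotonic(up, mc = mc_quick(2e5, seed = 2))
  expect_gt(bf_up$bf, 100)

  nm <- mk_cells(c(5, 50, 95), c(50, 5, 95))
  bf_nm <- bf_monotonic(nm, mc = mc_quick(2e5, seed = 3))
  expect_lt(bf_nm$bf, 1 / 20)

  # no data: BF = 1 within MC error
  none <- mk_cells(c(0, 0, 0), c(0, 0, 0), n = 0)
  bf_none <- bf_monotonic(none, mc = mc_quick(2e5, seed = 4),
                          allow_empty_cells = TRUE)
  expect_lt(abs(bf_none$log10_bf), 3 * bf_none$mc_se_log10)
  expect_false(bf_none$bounded)

  expect_error(bf_monotonic(mk_cells(c(5, 6), c(7, 8))), "3 lags")
})

test_that("BF is invariant to which measure is labelled axis 1", {
  cells <- mk_cells(c(20, 60, 85, 40), c(30, 70, 75, 50))
  swapped <- dplyr::mutate(cells, measure = ifelse(
    measure == "accuracy", "visibility_high", "accuracy"))
  b1 <- bf_monotonic(cells, mc = mc_quick(1e5, seed = 8))
  b2 <- bf_monotonic(swapped, mc = mc_quick(1e5, seed = 9))
  tol <- 3 * sqrt(b1$mc_se_log10^2 + b2$mc_se_log10^2)
  expect_lt(abs(b1$log10_bf - b2$log10_bf), tol)
})

test_that("joint MC monotone probability agrees with the factorized oracle", {
  withr::with_seed(21, {
    for (i in 1:3) {
      k <- sample(3:4, 1)
      cells <- mk_cells(sample(10:90, k), sample(10:90, k), n = 100)
      joint <- region_probability(cells, monotone_predicate(),
                                  mc_quick(1e5, seed = 30 + i))
      fact <- oracle_factorized_monotone(cells, 1e5, seed = 60 + i)
      tol <- 3 * sqrt(joint$se^2 + fact$se^2) + 1e-9
      expect_lt(abs(joint$estimate - fact$estimate), tol)
    }
  })
})

test_that("conditioning on constraints changes the contrast to BF_(M/NM)|D", {
  cells <- mk_cells(c(80, 20, 50), c(75, 25, 55), lags = c(1L, 2L, 3L))
  cs <- constraint_set("accuracy: 1 > 2")
  plain <- bf_monotonic(cells, mc = mc_quick(1e5, seed = 12))
  cond <- bf_monotonic(cells, cs, mc = mc_quick(1e5, seed = 13))
  # conditioned prior region is smaller than the full ordering space
  expect_lt(cond$n_prior_samples, 1e5 * 8 + 1)
  expect_true(all(c(plain$bf, cond$bf) > 0))
  # conditioning on an always-true region reproduces the unconstrained BF
  vac <- bf_monotonic(cells, constraint_set(), mc = mc_quick(1e5, seed = 12))
  expect_equal(vac$log10_bf, plain$log10_bf)
})

test_that("validity BF measures evidence for a constraint region", {
  strong <- mk_axis_cells(c(95, 5), lags = c(1L, 2L))
  cs <- constraint_set("accuracy: 1 > 2")
  bf <- bf_validity(strong, cs, mc_quick(1e5, seed = 14))
  expect_gt(bf$bf, 100)
  expect_lt(abs(bf$prior_region_prob - 0.5), 0.01)

  symmetric <- mk_axis_cells(c(50, 50), lags = c(1L, 2L))
  bf_sym <- bf_validity(symmetric, cs, mc_quick(1e5, seed = 15))
  expect_gt(bf_sym$bf, 1 / 3)
  expect_lt(bf_sym$bf, 3)

  expect_error(constraint_set(c("accuracy: 1 > 2", "accuracy: 2 > 1")))
  expect_error(bf_validity(strong, constraint_set()), "non-empty")
})

test_that("rule-of-three bounds replace spuriously finite Bayes factors", {
  # overwhelming data: the posterior non-monotone region collects no hits
  # before the cap, so the result must be flagged as a bound
  strong <- mk_cells(c(10, 500, 990), c(10, 500, 990), n = 1000)
  bf <- bf_monotonic(strong, mc = mc_quick(5e4, seed = 16, cap = 2e5))
  expect_true(bf$bounded)
  expect_gt(bf$bf, 20)
})

test_that("grouped BF obeys the product identities and flags outliers", {
  expect_equal(grouped_bf(c(1, 1, 1))$gbf, 1)
  expect_equal(grouped_bf(c(10, 0.1))$log10_gbf, 0)
  expect_equal(grouped_bf(c(100, 1000))$log10_gbf, 5)

  g <- grouped_bf(c(3, 1 / 3, 20, 1 / 1500, 5000))
  expect_equal(sum(g$bands$n), 5)
  expect_equal(g$bands$n[g$bands$band == "<1/1000"], 1L)
  expect_equal(g$bands$n[g$bands$band == ">1000"], 1L)

  # direction carried by one participant
  driver <- grouped_bf(c(1e6, 1 / 10, 1 / 10))
  expect_true(driver$single_driver)
  homogeneous <- grouped_bf(c(100, 100, 100))
  expect_false(homogeneous$single_driver)
  expect_error(grouped_bf(numeric()))
})

test_that("tidiers expose the engine's results as rectangular summaries", {
  cells <- mk_cells(c(20, 60, 85), c(30, 70, 75))
  b <- bf_monotonic(cells, mc = mc_quick(2e4, seed = 30))
  td <- tidy(b)
  expect_equal(nrow(td), 1)
  expect_named(td, c("participant", "contrast", "bf", "log10_bf",
                     "prior_region_prob", "posterior_region_prob",
                     "mc_se_log10", "n_prior_hits", "n_posterior_hits",
                     "bounded"))
  expect_equal(td$bf, b$bf)

  two <- dplyr::bind_rows(cells,
                          dplyr::mutate(cells, participant = "p2"))
  tab <- bf_by_participant(two, "monotonicity", mc = mc_quick(2e4, seed = 31))
  expect_equal(nrow(tab), 2)
  g <- grouped_bf(tab)
  expect_equal(g$log10_gbf, sum(tab$log10_bf))
  expect_equal(glance(g)$n_participants, 2)
})
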