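test_that("constraint sets reject duplicates, self-loops and contradictions", {
  expect_error(constraint_set("accuracy: 1 > 1"), "itself")
  expect_error(
    constraint_set(c("accuracy: 1 > 2", "accuracy: 1 > 2")), "Duplicate")
  expect_error(
    constraint_set(c("accuracy: 1 > 2", "accuracy: 2 > 1")), "Contradictory")
  cs <- constraint_set(c("accuracy: 1 > 2", "visibility_high: 3 > 2"))
  expect_s3_class(cs, "constraint_set")
  expect_equal(nrow(cs), 2)
  # round trip through the string form
  expect_equal(format_constraints(constraint_set(format_constraints(cs))),
               format_constraints(cs))
})

test_that("published constraint presets match the printed sets", {
  lit <- ab_constraints("colour_marked", "literature", "accuracy")
  expect_setequal(format_constraints(lit),
                  c("accuracy: 1 > 2", "accuracy: 1 > 3", "accuracy: 4 > 2",
                    "accuracy: 4 > 3", "accuracy: 6 > 2", "accuracy: 6 > 3",
                    "accuracy: 1 > 4"))
  emp <- ab_constraints("colour_marked", "empirical", "accuracy")
  expect_setequal(format_constraints(emp),
                  c("accuracy: 1 > 2", "accuracy: 1 > 3", "accuracy: 6 > 2",
                    "accuracy: 6 > 3", "accuracy: 1 > 4"))
  # the empirical reduction drops exactly the lag-4 constraints
  expect_setequal(setdiff(format_constraints(lit), format_constraints(emp)),
                  c("accuracy: 4 > 2", "accuracy: 4 > 3"))

  vis <- ab_constraints("colour_marked", "literature", "visibility")
  expect_setequal(format_constraints(vis),
                  c("visibility_high: 6 > 4", "visibility_high: 4 > 3",
                    "visibility_high: 3 > 2"))

  rep_vis <- ab_constraints("replication", "literature", "visibility")
  expect_setequal(format_constraints(rep_vis),
                  c("visibility_high: 7 > 5", "visibility_high: 5 > 3",
                    "visibility_high: 3 > 2"))
  rep_acc <- ab_constraints("replication", "literature", "accuracy")
  expect_setequal(format_constraints(rep_acc),
                  c("accuracy: 1 > 2", "accuracy: 1 > 3", "accuracy: 5 > 2",
                    "accuracy: 5 > 3", "accuracy: 7 > 2", "accuracy: 7 > 3",
                    "accuracy: 1 > 5"))

  expect_equal(nrow(ab_constraints("replication", "literature", "t1")), 0)
  expect_error(ab_constraints("replication", "empirical", "accuracy"))
  expect_error(ab_constraints("colour_marked", "literature", "t1"))
})

test_that("satisfies checks every strict inequality", {
  theta <- tibble::tibble(
    measure = "accuracy",
    lag = c(1, 2, 3, 4, 6),
    value = c(0.9, 0.4, 0.5, 0.7, 0.8)
  )
  lit <- ab_constraints("colour_marked", "literature", "accuracy")
  expect_true(satisfies(theta, lit))
  # equality on a constrained pair fails (strict)
  theta_eq <- dplyr::mutate(theta, value = replace(value, lag == 2, 0.9))
  expect_false(satisfies(theta_eq, lit))
  expect_true(satisfies(theta, constraint_set()))
  expect_error(satisfies(theta[-1, ], lit), "no unique value")
})

test_that("is_monotone accepts same or reversed orders and rejects ties", {
  expect_true(is_monotone(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8)))
  expect_true(is_monotone(c(0.2, 0.5, 0.8), c(0.8, 0.5, 0.2)))
  expect_false(is_monotone(c(0.2, 0.5, 0.8), c(0.5, 0.2, 0.8)))
  expect_error(is_monotone(c(0.2, 0.2, 0.8), c(0.1, 0.5, 0.9)), "Tie")
  expect_error(is_monotone(c(0.2, 0.5), c(0.1, 0.5, 0.9)), "same number")

  # symmetric in its arguments and invariant to increasing transforms
  withr::with_seed(11, {
    for (i in 1:50) {
      k <- sample(3:6, 1)
      a <- runif(k)
      b <- runif(k)
      m <- is_monotone(a, b)
      expect_identical(is_monotone(b, a), m)
      expect_identical(is_monotone(qlogis(a), exp(b)), m)
    }
  })
})

test_that("monotone prior probability equals 2/n! and matches enumeration", {
  expect_equal(monotone_prior_probability(2), 1)
  expect_equal(monotone_prior_probability(3), 1 / 3)
  expect_equal(monotone_prior_probability(5), 1 / 60)
  for (n in 2:4) {
    expect_equal(monotone_prior_probability(n), enumerate_monotone_fraction(n))
  }
  expect_error(monotone_prior_probability(1))
})
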