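test_that("parameter validation enforces the architecture's constraints", {
  expect_error(sese_params(mask_lateral_inhibition = 0.6,
                           mask_forward_inhibition = 0.5), "weaker")
  expect_error(sese_params(item_decay = 0.005,
                           item_self_excitation = 0.006), "leak")
  expect_error(sese_params(token_base_duration = 150), "200 ms")
  expect_error(sese_params(visibility_duration_cuts = c(50, 40, 60, 70, 80)),
               "increasing")
})

test_that("noise-free trials reproduce the blink, sparing and recovery", {
  p <- sese_params()
  enc <- function(lag) {
    tr <- simulate_sese_trial(make_stream(lag, p), p, noise_on = FALSE)
    ids <- tr$items$id
    list(trial = tr,
         t1 = tr$items$encoded[ids == "T1"],
         t2 = if (lag > 0) tr$items$encoded[ids == "T2"] else NA)
  }
  single <- enc(0)
  expect_true(single$t1)
  # the lone target is also experienced: trace above threshold for > 0 ms
  dur <- serial_experience(single$trial)$durations["T1"]
  expect_gt(dur, 0)

  lag1 <- enc(1)
  expect_true(lag1$t1)
  expect_true(lag1$t2)   # joint encoding inside the blaster window

  lag3 <- enc(3)
  expect_true(lag3$t1)
  expect_false(lag3$t2)  # the blink

  lag8 <- enc(8)
  expect_true(lag8$t2)   # recovery

  # lag 1 T2 is encoded yet barely experienced; at lag 8 it is experienced
  d1 <- serial_experience(lag1$trial)$durations["T2"]
  d8 <- serial_experience(lag8$trial)$durations["T2"]
  expect_lt(d1, d8)
})

test_that("stream and trial contracts are enforced", {
  p <- sese_params()
  expect_error(simulate_sese_trial(
    tibble::tibble(onset = c(0, 0), role = c("T1", "T2")), p), "increasing")
  expect_error(simulate_sese_trial(
    tibble::tibble(onset = c(0.5, 90), role = c("T1", "T2")), p), "grid")
  expect_error(simulate_sese_trial(
    tibble::tibble(onset = c(0, 90), role = c("T2", "T1")), p), "precede")
  # same seed reproduces a noisy trial exactly
  st <- make_stream(2, p)
  a <- simulate_sese_trial(st, p, seed = 5, noise_on = TRUE)
  b <- simulate_sese_trial(st, p, seed = 5, noise_on = TRUE)
  expect_identical(a$traces, b$traces)
})

test_that("serial experience resolves contention as stated", {
  tm <- seq(0, 600, by = 1)
  # A supra-threshold on [100, 400), B on [250, 550): B waits, then claims
  tr <- cbind(A = as.numeric(tm >= 100 & tm < 400),
              B = as.numeric(tm >= 250 & tm < 550))
  out <- serial_experience(tr, phi = 0.5, time = tm)
  expect_equal(out$episodes$item, c("A", "B"))
  expect_equal(out$episodes$start, c(100, 400))
  expect_equal(out$episodes$end, c(400, 550))
  expect_equal(unname(out$durations), c(300, 150))

  # non-overlapping intervals: each item gets its full supra time
  tr2 <- cbind(A = as.numeric(tm >= 100 & tm < 250),
               B = as.numeric(tm >= 300 & tm < 500))
  out2 <- serial_experience(tr2, phi = 0.5, time = tm)
  expect_equal(unname(out2$durations), c(150, 200))

  # never supra-threshold: no episodes, zero duration
  out3 <- serial_experience(cbind(A = rep(0.1, length(tm))),
                            phi = 0.5, time = tm)
  expect_equal(nrow(out3$episodes), 0)
  expect_equal(unname(out3$durations), 0)

  # a waiter that decays before release never gets an episode
  tr4 <- cbind(A = as.numeric(tm >= 100 & tm < 400),
               B = as.numeric(tm >= 150 & tm < 300))
  out4 <- serial_experience(tr4, phi = 0.5, time = tm)
  expect_equal(out4$episodes$item, "A")
  expect_equal(unname(out4$durations), c(300, 0))
})

test_that("event-driven episodes match the per-step occupancy automaton", {
  withr::with_seed(42, {
    for (case in 1:120) {
      rt <- random_traces(n_items = sample(2:4, 1))
      got <- serial_experience(rt$traces, phi = 1, time = rt$time)$episodes
      want <- oracle_serial_experience(rt$traces, 1, rt$time)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        expect_equal(match(got$item, colnames(rt$traces)), want$item_idx)
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
      }
    }
  })
})

test_that("visibility ratings step at the duration cut points", {
  cuts <- c(50, 120, 200, 300, 420)
  expect_equal(visibility_rating(0, cuts), 1L)
  expect_equal(visibility_rating(50, cuts), 2L)   # closed lower boundary
  expect_equal(visibility_rating(1000, cuts), 6L)
  expect_equal(visibility_rating(c(49, 130, 419, 420), cuts),
               c(1L, 3L, 5L, 6L))
  # monotone in duration
  r <- visibility_rating(seq(0, 500, by = 10), cuts)
  expect_true(all(diff(r) >= 0))
  expect_error(visibility_rating(10, c(1, 2, 3, 3, 4)), "increasing")
})

test_that("the virtual P3 is gated by the experience episodes", {
  tm <- seq(0, 400, by = 1)
  a <- 2 * exp(-((tm - 100) / 80)^2)
  b <- 2 * exp(-((tm - 200) / 80)^2)
  tr <- cbind(A = a, B = b)
  eps <- serial_experience(tr, phi = 1, time = tm)$episodes
  erp <- virtual_erp(tr, eps, time = tm)
  # inside A's episode the grand trace equals A's trace even where B is supra
  inside <- tm >= eps$start[1] & tm < eps$end[1]
  expect_equal(erp$amplitude[inside], a[inside])
  # never exceeds the plain sum, equals it where nothing is experienced
  expect_true(all(erp$amplitude <= a + b + 1e-12))
  outside <- tm >= max(eps$end)
  expect_equal(erp$amplitude[outside], (a + b)[outside])
  # with no supra-threshold item, the gated trace is the plain sum
  erp0 <- virtual_erp(tr / 10, eps[0, ], time = tm)
  expect_equal(erp0$amplitude, (a + b) / 10)
})

test_that("run_sese_experiment is seeded and summarises single trials", {
  p <- sese_params(input_strength_sd = 0)
  one <- run_sese_experiment(lags = 3, n_trials = 1, params = p, seed = 2)
  trial <- simulate_sese_trial(make_stream(3, p), p, noise_on = FALSE)
  expect_equal(one$summary$t1_acc,
               as.numeric(trial$items$encoded[trial$items$id == "T1"]))
  expect_equal(one$summary$t2_given_t1_acc,
               as.numeric(trial$items$encoded[trial$items$id == "T2"]))

  a <- run_sese_experiment(lags = c(1, 3), n_trials = 5, seed = 9)
  b <- run_sese_experiment(lags = c(1, 3), n_trials = 5, seed = 9)
  expect_identical(a$summary, b$summary)
  expect_identical(a$trials, b$trials)

  tt <- as_trial_table(a)
  expect_named(tt, c("participant", "lag", "t1_correct", "t2_correct",
                     "visibility", "order_error"))
  expect_equal(nrow(tt), 10)
})
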