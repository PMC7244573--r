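#' Build an RSVP stream for the simulator
#'
#' A stream of `n_items` items at one SOA, with T1 at a fixed serial position
#' and T2 `lag` positions later; all other items are distractors. `lag = 0`
#' gives a single-target stream.
#'
#' @param lag T2 serial-position lag after T1 (0 for no T2).
#' @param params [sese_params()] (supplies the SOA).
#' @param n_items Stream length; extended automatically if the T2 position
#'   would fall outside it.
#' @param t1_position Serial position of T1 (1-based).
#' @return A stream tibble for [simulate_sese_trial()].
#' @export
make_stream <- function(lag, params = sese_params(), n_items = 15,
                        t1_position = 5) {
  if (lag < 0 || lag != round(lag)) abort("`lag` must be a non-negative integer.")
  n_items <- max(n_items, t1_position + lag + 2)
  role <- rep("distractor", n_items)
  role[t1_position] <- "T1"
  if (lag > 0) role[t1_position + lag] <- "T2"
  tibble(
    onset = (seq_len(n_items) - 1) * params$soa,
    role = role
  )
}

#' Run a simulated attentional-blink experiment
#'
#' Simulates `n_trials` noisy trials at each lag, reads out working-memory
#' encoding (report accuracy) and serial-experience visibility per trial, and
#' averages the gated virtual P3 within T1-correct trials split by T2
#' visibility bin (high: rating above `split_point`). Fully seeded: the same
#' seed reproduces the experiment exactly.
#'
#' @param lags Integer lags to simulate.
#' @param n_trials Trials per lag.
#' @param params [sese_params()].
#' @param seed Integer seed.
#' @param split_point Visibility split for the high/low ERP bins and the
#'   `p_high_vis` summary.
#' @return A `sese_experiment` list: `summary` (per-lag behaviour), `erp`
#'   (condition-averaged virtual P3s), `trials` (per-trial outcomes),
#'   `params`, `seed`.
#' @export
run_sese_experiment <- function(lags = c(1, 2, 3, 4, 6, 8), n_trials = 100,
                                params = sese_params(), seed = 1,
                                split_point = 3) {
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  noise_on <- params$input_strength_sd > 0
  trial_rows <- vector("list", length(lags) * n_trials)
  erp_sum <- list()
  erp_n <- list()
  row <- 0

  for (li in seq_along(lags)) {
    lag <- lags[li]
    stream <- make_stream(lag, params)
    for (k in seq_len(n_trials)) {
      row <- row + 1
      trial_seed <- as.integer((seed + 977 * li + 600011 * k) %%
                                 .Machine$integer.max)
      trial <- simulate_sese_trial(stream, params, seed = trial_seed,
                                   noise_on = noise_on)
      exp_out <- serial_experience(trial)
      if (!params$distractors_experienced) {
        keep <- trial$items$id %in% c("T1", "T2")
        exp_out <- serial_experience(
          trial$traces[, keep, drop = FALSE],
          phi = params$subjectivity_threshold, time = trial$time
        )
      }
      t1_ok <- trial$items$encoded[trial$items$id == "T1"]
      t2_ok <- if (lag > 0) trial$items$encoded[trial$items$id == "T2"] else NA
      t2_dur <- if (lag > 0) unname(exp_out$durations["T2"]) else NA_real_
      rating <- if (lag > 0) {
        visibility_rating(t2_dur, params$visibility_duration_cuts)
      } else {
        NA_integer_
      }
      trial_rows[[row]] <- tibble(
        lag = lag, trial = k,
        t1_correct = t1_ok, t2_correct = t2_ok,
        visibility = rating, t2_experience_ms = t2_dur
      )
      if (t1_ok && lag > 0) {
        bin <- if (rating > split_point) "high" else "low"
        key <- paste(lag, bin, sep = "/")
        amp <- virtual_erp(trial, exp_out$episodes)$amplitude
        if (is.null(erp_sum[[key]])) {
          erp_sum[[key]] <- amp
          erp_n[[key]] <- 1L
        } else {
          erp_sum[[key]] <- erp_sum[[key]] + amp
          erp_n[[key]] <- erp_n[[key]] + 1L
        }
      }
    }
  }

  trials <- list_rbind(trial_rows)
  summary <- trials |>
    group_by(.data$lag) |>
    summarise(
      n_trials = dplyr::n(),
      t1_acc = mean(.data$t1_correct),
      t2_given_t1_acc = mean(.data$t2_correct[.data$t1_correct]),
      mean_visibility = mean(.data$visibility[.data$t1_correct]),
      p_high_vis = mean(.data$visibility[.data$t1_correct] > split_point),
      .groups = "drop"
    )

  grid <- make_stream(max(lags), params)
  time <- seq(0, max(grid$onset) + params$trial_tail, by = params$dt)
  erp <- list_rbind(imap(erp_sum, function(total, key) {
    parts <- strsplit(key, "/")[[1]]
    n_avg <- erp_n[[key]]
    tb <- tibble(
      lag = as.integer(parts[1]),
      visibility_bin = parts[2],
      time_ms = seq(0, by = params$dt, length.out = length(total)),
      amplitude = total / n_avg
    )
    tb$n_trials <- n_avg
    tb
  }))

  structure(
    list(summary = summary, erp = erp, trials = trials,
         params = params, seed = seed, split_point = split_point),
    class = "sese_experiment"
  )
}

#' @export
print.sese_experiment <- function(x, ...) {
  cat("<sese_experiment>", nrow(x$trials), "trials, seed", x$seed, "\n")
  print(x$summary)
  invisible(x)
}

#' Convert a simulated experiment to the analysis trial-table format
#'
#' Maps the model's encoding outcomes and visibility ratings onto the same
#' tidy trial schema that [simulate_trials()] produces, so simulated
#' behaviour can be piped straight into the state-trace pipeline. The model
#' has no order-error mechanism, so `order_error` is always `FALSE`.
#'
#' @param x A `sese_experiment`.
#' @param participant Participant label for the pooled simulated observer.
#' @return A trial tibble.
#' @export
as_trial_table <- function(x, participant = "sese") {
  stopifnot(inherits(x, "sese_experiment"))
  x$trials |>
    filter(.data$lag > 0) |>
    mutate(
      participant = participant,
      order_error = FALSE,
      visibility = as.integer(.data$visibility)
    ) |>
    select("participant", "lag", "t1_correct", "t2_correct",
           "visibility", "order_error")
}
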