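#' Simulate a single RSVP trial through STST-lite
#'
#' Runs the discrete-time cascade for one stream of items. Per step, each
#' item's masked input drive (its pulse minus backward inhibition from the
#' following item and weaker lateral inhibition from other concurrent pulses)
#' feeds a leaky, self-excited item stage; the task filter scales targets up
#' and distractors down to give the activation trace. The blaster fires when
#' an undealt-with target's trace first exceeds the detection threshold,
#' multiplying all stimulus drive for `blaster_duration` ms, and is held off
#' while any tokenisation is in progress — the mechanism that produces the
#' blink. Tokenisation starts when a trace crosses the encoding threshold and
#' either no binding is in progress or the blaster window is still open (the
#' lag-1 joint-encoding route); it completes after a trace-strength-dependent
#' time, and an item is encoded (reportable) only if its trace stays above
#' the encoding threshold until completion.
#'
#' @param stream A tibble describing the stream: columns `onset` (ms, on the
#'   `dt` grid, strictly increasing), `role` (`"T1"`, `"T2"` or
#'   `"distractor"`), and optionally `strength` (input strength; default 1).
#' @param params [sese_params()].
#' @param seed Optional integer seed for the trial noise.
#' @param noise_on Apply multiplicative Gaussian noise to input strengths?
#' @return A `sese_trial` list: `time` (ms grid), `traces` (time x items
#'   matrix), `items` tibble (id, role, onset, strength, encoded),
#'   `blaster_windows`, `tokenisations`.
#' @export
simulate_sese_trial <- function(stream, params = sese_params(), seed = NULL,
                                noise_on = TRUE) {
  stopifnot(inherits(params, "sese_params"))
  stream <- as_tibble(stream)
  if (!all(c("onset", "role") %in% names(stream))) {
    abort("`stream` needs `onset` and `role` columns.")
  }
  if (is.unsorted(stream$onset, strictly = TRUE)) {
    abort("Item onsets must be strictly increasing (no overlapping onsets).")
  }
  if (any(stream$onset %% params$dt != 0)) {
    abort("Item onsets must lie on the dt grid.")
  }
  t1_idx <- which(stream$role == "T1")
  t2_idx <- which(stream$role == "T2")
  if (length(t2_idx) && length(t1_idx) &&
      stream$onset[t2_idx[1]] <= stream$onset[t1_idx[1]]) {
    abort("T1 must precede T2.")
  }
  if (!"strength" %in% names(stream)) stream$strength <- 1

  strength <- stream$strength
  if (noise_on) {
    noise <- withr::with_seed(
      seed %||% sample.int(.Machine$integer.max, 1),
      rnorm(nrow(stream), 0, params$input_strength_sd)
    )
    strength <- pmax(strength * (params$input_strength_mean + noise), 0)
  } else {
    strength <- strength * params$input_strength_mean
  }

  dt <- params$dt
  time <- seq(0, max(stream$onset) + params$trial_tail, by = dt)
  n_t <- length(time)
  n_i <- nrow(stream)

  # Input pulses and (state-independent) masked drive.
  u <- matrix(0, n_i, n_t)
  for (i in seq_len(n_i)) {
    on <- time >= stream$onset[i] & time < stream$onset[i] + params$pulse_duration
    u[i, on] <- strength[i]
  }
  total_u <- colSums(u)
  m <- matrix(0, n_i, n_t)
  for (i in seq_len(n_i)) {
    u_next <- if (i < n_i) u[i + 1, ] else 0
    lateral <- total_u - u[i, ] - u_next
    m[i, ] <- pmax(
      u[i, ] - params$mask_forward_inhibition * u_next -
        params$mask_lateral_inhibition * lateral,
      0
    )
  }

  salience <- ifelse(stream$role == "distractor",
                     params$distractor_suppression,
                     params$target_salience_gain)
  leak <- params$item_decay - params$item_self_excitation

  a <- numeric(n_i)
  traces <- matrix(0, n_t, n_i)
  blaster_until <- -Inf
  blaster_windows <- list()
  encoded <- rep(FALSE, n_i)
  binding <- rep(FALSE, n_i)     # tokenisation in progress
  progress <- numeric(n_i)       # binding progress in [0, 1]
  prev_above_det <- rep(FALSE, n_i)
  tok_log <- list()

  for (s in seq_len(n_t)) {
    t_now <- time[s]
    blaster_on <- t_now < blaster_until
    boost <- if (blaster_on) params$blaster_gain else 1
    a <- a + dt * (-leak * a + params$input_gain * boost * m[, s])
    tr <- salience * a
    traces[s, ] <- tr

    # Tokenisation: binding progress accrues at a rate that grows with trace
    # strength (more active items bind faster), aborts when the trace decays
    # below the encoding threshold, and encodes the item on completion.
    for (i in which(binding)) {
      if (tr[i] < params$encoding_threshold) {
        binding[i] <- FALSE
        progress[i] <- 0
      } else {
        rate <- 1 + params$token_speedup *
          (tr[i] / params$encoding_threshold - 1)
        rate <- min(max(rate, 1),
                    params$token_base_duration / params$token_min_duration)
        progress[i] <- progress[i] + dt * rate / params$token_base_duration
        if (progress[i] >= 1) {
          binding[i] <- FALSE
          encoded[i] <- TRUE
        }
      }
    }
    any_binding <- any(binding)

    # Blaster: a fresh target detection (upward crossing of the detection
    # threshold) fires it. Detections arriving while the blaster is already
    # active, or while the binding pool's inhibition holds it down, are lost
    # — losing them during T1's tokenisation is what produces the blink.
    above_det <- tr >= params$detection_threshold
    crossing <- above_det & !prev_above_det & stream$role != "distractor" &
      !encoded & !binding
    prev_above_det <- above_det
    if (!blaster_on && !any_binding && any(crossing)) {
      blaster_until <- t_now + params$blaster_duration
      blaster_windows[[length(blaster_windows) + 1]] <-
        c(start = t_now, end = blaster_until)
      blaster_on <- TRUE
    }

    # Tokenisation onset: serial, except that a second binding may start
    # inside the blaster window (joint encoding at very short lags).
    can_start <- !binding & !encoded & tr >= params$encoding_threshold
    for (i in which(can_start)) {
      if (sum(binding) >= params$max_tokens) break
      if (!any(binding) || blaster_on) {
        binding[i] <- TRUE
        progress[i] <- 0
        tok_log[[length(tok_log) + 1]] <-
          tibble(item = i, start = t_now, trace_at_start = tr[i])
      }
    }
  }

  items <- stream
  items$id <- paste0("item", seq_len(n_i))
  items$id[t1_idx] <- "T1"
  items$id[t2_idx] <- "T2"
  items$strength_used <- strength
  items$encoded <- encoded

  structure(
    list(
      time = time,
      traces = `colnames<-`(traces, items$id),
      items = items,
      blaster_windows = blaster_windows,
      tokenisations = if (length(tok_log)) list_rbind(tok_log) else
        tibble(item = integer(), start = numeric(),
               trace_at_start = numeric()),
      params = params
    ),
    class = "sese_trial"
  )
}
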