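#' Serial-experience readout: exclusive episodes above threshold
#'
#' The strength of an item's subjective experience is the time its activation
#' trace spends above the subjectivity threshold while no other item is being
#' experienced. Experience is exclusively serial: if a second trace is
#' already supra-threshold while another item occupies experience, it waits,
#' and begins an episode at the instant of release only if it is still
#' supra-threshold then; any supra-threshold time spent waiting is lost.
#' Episodes are half-open intervals `[start, end)` and end when the
#' occupant's trace falls below threshold.
#'
#' The implementation is event-driven over the supra-threshold intervals of
#' each trace (not a per-time-step scan): at each release instant, the
#' waiting interval that became supra-threshold earliest claims experience
#' (ties broken by item order).
#'
#' @param traces A time x items matrix of trace amplitudes (as in
#'   [simulate_sese_trial()]`$traces`), or a `sese_trial` object.
#' @param phi Subjectivity threshold; defaults to the trial's parameter.
#' @param time Time grid (ms); required when `traces` is a bare matrix with
#'   no attached trial.
#' @return A list: `episodes` (tibble `item`, `start`, `end`, `duration`) and
#'   `durations` (named total experienced ms per item, zero when never
#'   experienced).
#' @examples
#' tm <- seq(0, 600, by = 1)
#' tr <- cbind(A = as.numeric(tm >= 100 & tm < 400),
#'             B = as.numeric(tm >= 250 & tm < 550))
#' serial_experience(tr, phi = 0.5, time = tm)$durations  # A 300, B 150
#' @export
serial_experience <- function(traces, phi = NULL, time = NULL) {
  if (inherits(traces, "sese_trial")) {
    time <- traces$time
    phi <- phi %||% traces$params$subjectivity_threshold
    traces <- traces$traces
  }
  if (is.null(time) || is.null(phi)) {
    abort("Need `time` and `phi` when `traces` is a bare matrix.")
  }
  if (nrow(traces) != length(time)) abort("`time` must index the trace rows.")
  ids <- colnames(traces) %||% paste0("item", seq_len(ncol(traces)))
  dt <- if (length(time) > 1) time[2] - time[1] else 1

  # Supra-threshold intervals per item, [start, end) on the time grid.
  intervals <- list_rbind(map(seq_len(ncol(traces)), function(j) {
    r <- rle(traces[, j] >= phi)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (!length(keep)) return(NULL)
    tibble(
      item_idx = j,
      start = time[starts[keep]],
      end = time[ends[keep]] + dt
    )
  }))

  episodes <- tibble(item = character(), start = numeric(), end = numeric(),
                     duration = numeric())
  if (!is.null(intervals) && nrow(intervals)) {
    remaining <- intervals
    tau <- -Inf
    out <- list()
    while (nrow(remaining)) {
      remaining <- remaining[remaining$end > tau, , drop = FALSE]
      if (!nrow(remaining)) break
      covering <- remaining$start <= tau
      if (any(covering)) {
        # Waiting items: the one supra-threshold earliest claims experience.
        cand <- which(covering)
        pick <- cand[order(remaining$start[cand], remaining$item_idx[cand])][1]
        s <- tau
      } else {
        pick <- order(remaining$start, remaining$item_idx)[1]
        s <- remaining$start[pick]
      }
      e <- remaining$end[pick]
      out[[length(out) + 1]] <- tibble(
        item = ids[remaining$item_idx[pick]],
        start = s, end = e, duration = e - s
      )
      tau <- e
      remaining <- remaining[-pick, , drop = FALSE]
    }
    if (length(out)) episodes <- list_rbind(out)
  }

  durations <- setNames(numeric(length(ids)), ids)
  if (nrow(episodes)) {
    agg <- episodes |> group_by(.data$item) |>
      summarise(d = sum(.data$duration), .groups = "drop")
    durations[agg$item] <- agg$d
  }
  list(episodes = episodes, durations = durations)
}

#' Map an experienced duration to a 1-6 visibility rating
#'
#' Rating = 1 + the number of cut points at or below the duration, so a
#' duration of zero maps to 1 ("not seen") and anything at or above the top
#' cut to 6 ("maximal visibility"). Cut boundaries are closed from below.
#'
#' @param duration Experienced duration(s) in ms.
#' @param cuts Five strictly increasing duration cut points (ms).
#' @return Integer rating(s) in 1..6.
#' @examples
#' visibility_rating(c(0, 130, 1000), cuts = c(50, 120, 200, 300, 420))
#' @export
visibility_rating <- function(duration, cuts = sese_params()$visibility_duration_cuts) {
  if (length(cuts) != 5 || any(diff(cuts) <= 0)) {
    abort("`cuts` must be five strictly increasing values.")
  }
  vapply(duration, function(d) 1L + sum(cuts <= d), integer(1))
}

#' Compose the gated virtual P3 trace
#'
#' The grand virtual ERP is gated by experience: while an episode is active,
#' only the occupying item's trace contributes; outside any episode the grand
#' trace is the plain sum of all item traces (the ungated composition used
#' before the serial readout was added).
#'
#' @param traces Time x items trace matrix or a `sese_trial`.
#' @param episodes Episode tibble from [serial_experience()]; computed from
#'   the trial when omitted.
#' @param time Time grid, required for a bare matrix.
#' @return A tibble: `time_ms`, `amplitude`.
#' @export
virtual_erp <- function(traces, episodes = NULL, time = NULL) {
  if (inherits(traces, "sese_trial")) {
    trial <- traces
    time <- trial$time
    traces <- trial$traces
    if (is.null(episodes)) episodes <- serial_experience(trial)$episodes
  }
  if (is.null(time)) abort("Need `time` for a bare trace matrix.")
  if (is.null(episodes)) abort("Need `episodes` for a bare trace matrix.")
  ids <- colnames(traces) %||% paste0("item", seq_len(ncol(traces)))
  grand <- rowSums(traces)
  for (k in seq_len(nrow(episodes))) {
    idx <- which(time >= episodes$start[k] & time < episodes$end[k])
    col <- match(episodes$item[k], ids)
    if (is.na(col)) abort("Episode references an item absent from the traces.")
    grand[idx] <- traces[idx, col]
  }
  tibble(time_ms = time, amplitude = grand)
}
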