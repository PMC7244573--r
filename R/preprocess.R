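#' Apply the T2 trial-inclusion conventions
#'
#' Attentional-blink state-trace analyses differ in how they condition the T2
#' trial set. The colour-marked convention keeps only trials where T1 was
#' reported correctly and the two targets were reported in the correct order;
#' the replication convention analyses all trials whatever the report order.
#' Both filters are independently switchable.
#'
#' @param trials A trial table (see [simulate_trials()]).
#' @param require_t1_correct Drop trials with `t1_correct == FALSE`?
#' @param exclude_order_errors Drop trials flagged as order errors?
#' @return The filtered trial tibble.
#' @export
condition_t2_trials <- function(trials, require_t1_correct = TRUE,
                                exclude_order_errors = TRUE) {
  check_trials(trials)
  out <- as_tibble(trials)
  if (require_t1_correct) out <- filter(out, .data$t1_correct)
  if (exclude_order_errors) out <- filter(out, !.data$order_error)
  out
}

check_trials <- function(trials) {
  needed <- c("participant", "lag", "t1_correct", "t2_correct",
              "visibility", "order_error")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    abort(paste0("Trial table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(trials) && (any(trials$visibility < 1) || any(trials$visibility > 6))) {
    abort("`visibility` must be on the 1-6 scale.")
  }
  invisible(trials)
}

#' Bin a 6-point visibility rating into high/low
#'
#' Ratings strictly above `split_point` are "high". The empirically selected
#' split in both experiments is the equal-mass one, `split_point = 3`
#' (ratings 4-6 high, 1-3 low); [select_visibility_split()] re-derives it
#' from data.
#'
#' @param rating Integer vector of ratings in 1..6.
#' @param split_point Integer in 1..5; high bin is `rating > split_point`.
#' @return Character vector of `"high"` / `"low"`.
#' @examples
#' bin_visibility(c(1, 3, 4, 6), split_point = 3)
#' @export
bin_visibility <- function(rating, split_point = 3) {
  if (length(split_point) != 1 || !split_point %in% 1:5) {
    abort("`split_point` must be a single integer in 1..5.")
  }
  if (any(!rating %in% 1:6)) abort("`rating` must be integers in 1..6.")
  ifelse(rating > split_point, "high", "low")
}

#' Aggregate a conditioned trial table into binomial cells
#'
#' Produces the per-(participant, measure, lag) successes/trials counts that
#' the Bayes-factor engine consumes. The `accuracy` measure counts correct T2
#' reports; the `visibility_high` measure counts ratings above `split_point`.
#' Both measures are computed on the same retained trial set, so visibility is
#' conditioned exactly as accuracy is. Lags with no retained trials for a
#' participant are carried as `(0, 0)` cells; the Bayes-factor engine rejects
#' these rather than imputing.
#'
#' @param trials A (typically conditioned) trial table.
#' @param split_point Visibility split passed to [bin_visibility()].
#' @param t2_column Column holding the report-correct flag (default
#'   `t2_correct`; pass `"t1_correct"` for a T1-axis analysis).
#' @return A cells tibble: `participant`, `measure`, `lag`, `successes`,
#'   `trials`.
#' @export
to_cells <- function(trials, split_point = 3, t2_column = "t2_correct") {
  check_trials(trials)
  if (!nrow(trials)) abort("Cannot build cells from an empty trial table.")
  grid <- tidyr::expand_grid(
    participant = unique(trials$participant),
    lag = sort(unique(trials$lag))
  )
  counts <- trials |>
    group_by(.data$participant, .data$lag) |>
    summarise(
      acc_successes = sum(.data[[t2_column]]),
      vis_successes = sum(bin_visibility(.data$visibility, split_point) == "high"),
      trials = dplyr::n(),
      .groups = "drop"
    )
  counts <- left_join(grid, counts, by = c("participant", "lag")) |>
    mutate(across(c("acc_successes", "vis_successes", "trials"),
                  ~ tidyr::replace_na(.x, 0L)))
  cells <- bind_rows(
    counts |>
      mutate(measure = "accuracy") |>
      rename(successes = "acc_successes") |>
      select("participant", "measure", "lag", "successes", "trials"),
    counts |>
      mutate(measure = "visibility_high") |>
      rename(successes = "vis_successes") |>
      select("participant", "measure", "lag", "successes", "trials")
  ) |>
    arrange(.data$participant, .data$measure, .data$lag)
  attr(cells, "split_point") <- split_point
  cells
}

check_cells <- function(cells) {
  needed <- c("participant", "measure", "lag", "successes", "trials")
  missing <- setdiff(needed, names(cells))
  if (length(missing)) {
    abort(paste0("Cells table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(cells$successes > cells$trials) || any(cells$successes < 0)) {
    abort("Cells must satisfy 0 <= successes <= trials.")
  }
  if (anyDuplicated(cells[c("participant", "measure", "lag")])) {
    abort("Duplicate (participant, measure, lag) cells.")
  }
  invisible(cells)
}

#' Drop lags from a cells table
#'
#' The colour-marked experiment excludes lag 8 before analysis: a last lag
#' that is a serial-position outlier attracts a learned reallocation of
#' attention and sits off the blink curve. Dropping a lag that is not present
#' is an error.
#'
#' @param cells A cells tibble from [to_cells()].
#' @param lags_to_drop Integer vector of lag levels to remove (may be empty).
#' @return The cells tibble without those lags, on both measures.
#' @export
drop_lags <- function(cells, lags_to_drop) {
  check_cells(cells)
  if (!length(lags_to_drop)) return(cells)
  absent <- setdiff(lags_to_drop, unique(cells$lag))
  if (length(absent)) {
    abort(paste0("Cannot drop absent lag(s): ", paste(absent, collapse = ", ")))
  }
  filter(cells, !.data$lag %in% lags_to_drop)
}
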