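#' Per-participant T2|T1 accuracy on "not seen" trials
#'
#' Restricts the (already conditioned) trial table to trials where the
#' participant selected the lowest visibility rating — 1, "not seen" — and
#' computes each participant's proportion of correct T2 reports at the given
#' lag. Above-chance accuracy here is the signature of sight-blind recall:
#' correct free recall of a target the participant reports not having seen.
#' Participants with no qualifying trials get `NA` and are excluded from the
#' tests downstream.
#'
#' @param trials A conditioned trial table.
#' @param lag A single lag level present in the table.
#' @return A tibble: `participant`, `lag`, `n_trials` (visibility-1 trials),
#'   `accuracy`.
#' @export
accuracy_at_min_visibility <- function(trials, lag) {
  check_trials(trials)
  if (!lag %in% trials$lag) abort(paste0("Lag ", lag, " absent from table."))
  target_lag <- lag
  trials |>
    filter(.data$lag == target_lag) |>
    group_by(.data$participant) |>
    summarise(
      lag = target_lag,
      n_trials = sum(.data$visibility == 1),
      accuracy = ifelse(n_trials > 0,
                        sum(.data$t2_correct & .data$visibility == 1) / n_trials,
                        NA_real_),
      .groups = "drop"
    )
}

#' One-sample test of accuracy against guessing chance
#'
#' One-sample t-test of the per-participant accuracies against the chance
#' level, one-sided (mean greater than chance) by default since the
#' hypothesis is directional. Cohen's d is (mean - chance) / sd.
#'
#' @param values Per-participant proportions (`NA`s dropped).
#' @param chance Chance probability; 1/21 for a 21-letter report pool.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A tibble: `mean`, `sd`, `n`, `t`, `df`, `p_value`, `cohens_d`.
#' @examples
#' above_chance_test(c(0.10, 0.20, 0.30), chance = 0.0476)
#' @export
above_chance_test <- function(values, chance = guessing_chance(),
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("Need at least 2 non-missing values.")
  s <- sd(values)
  if (s <= 1e-10 * max(1, abs(mean(values)))) {
    # Degenerate sample: constant values. At exactly chance the natural
    # limit t = 0, d = 0 is returned; away from chance t is infinite, so no
    # finite statistic is reported. Both outcomes are flagged.
    at_chance <- abs(mean(values) - chance) <= 1e-12
    return(tibble(mean = mean(values), sd = 0, n = length(values),
                  t = if (at_chance) 0 else NA_real_,
                  df = length(values) - 1,
                  p_value = NA_real_,
                  cohens_d = if (at_chance) 0 else NA_real_,
                  degenerate = TRUE))
  }
  ht <- t.test(values, mu = chance, alternative = alternative)
  tibble(
    mean = mean(values),
    sd = s,
    n = length(values),
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    cohens_d = (mean(values) - chance) / s,
    degenerate = FALSE
  )
}

#' Paired contrast of minimal-visibility accuracy between two lags
#'
#' Paired t-test on per-participant differences (lag a minus lag b),
#' one-sided a > b by default. Pairs with a missing value on either side are
#' dropped listwise. Constant non-zero differences make t infinite; that is
#' flagged as a zero-variance degenerate outcome rather than reported as a
#' statistic.
#'
#' @param values_lag_a,values_lag_b Paired per-participant proportions.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A tibble: `mean_diff`, `n`, `t`, `df`, `p_value`, `cohens_d`,
#'   `degenerate`.
#' @export
lag_contrast_test <- function(values_lag_a, values_lag_b,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(values_lag_a) != length(values_lag_b)) {
    abort("Paired vectors must have equal length.")
  }
  keep <- !is.na(values_lag_a) & !is.na(values_lag_b)
  d <- values_lag_a[keep] - values_lag_b[keep]
  if (length(d) < 2) abort("Need at least 2 complete pairs.")
  s <- sd(d)
  if (s <= 1e-10 * max(1, abs(mean(d)))) {
    return(tibble(mean_diff = mean(d), n = length(d), t = NA_real_,
                  df = length(d) - 1, p_value = NA_real_,
                  cohens_d = NA_real_, degenerate = TRUE))
  }
  ht <- t.test(d, mu = 0, alternative = alternative)
  tibble(
    mean_diff = mean(d),
    n = length(d),
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    cohens_d = mean(d) / s,
    degenerate = FALSE
  )
}

#' Full minimal-visibility ("sight-blind recall") report
#'
#' Convenience wrapper: per-lag accuracies at visibility 1, one-sample tests
#' against chance at each lag, and the paired contrast between the first two
#' lags supplied.
#'
#' @param trials A conditioned trial table.
#' @param lags Lags to analyse (first two are contrasted), default `c(1, 3)`.
#' @param chance Chance level, default 1/21.
#' @return A list: `per_participant`, `chance_tests`, `lag_contrast`,
#'   `chance_level`.
#' @export
min_visibility_report <- function(trials, lags = c(1, 3),
                                  chance = guessing_chance()) {
  per_part <- list_rbind(map(lags, ~ accuracy_at_min_visibility(trials, .x)))
  chance_tests <- list_rbind(map(lags, function(l) {
    vals <- per_part$accuracy[per_part$lag == l]
    mutate(above_chance_test(vals, chance), lag = l, .before = 1)
  }))
  contrast <- NULL
  if (length(lags) >= 2) {
    wide <- tidyr::pivot_wider(per_part[c("participant", "lag", "accuracy")],
                               names_from = "lag", values_from = "accuracy")
    contrast <- lag_contrast_test(wide[[as.character(lags[1])]],
                                  wide[[as.character(lags[2])]])
  }
  list(per_participant = per_part, chance_tests = chance_tests,
       lag_contrast = contrast, chance_level = chance)
}
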