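#' Grouped validity profile of candidate constraints
#'
#' Evaluates each candidate constraint alone on its own axis: per participant
#' a validity Bayes factor BF_c/N(c) for the singleton region {c}, then the
#' grouped product across participants. Because every constraint is scored on
#' a single axis in isolation, the profile never references the cross-axis
#' monotonicity contrast — the orthogonality that makes it legitimate to
#' select a prior from the same data the monotonicity test will use.
#'
#' @param cells A multi-participant cells tibble.
#' @param candidates A non-empty [constraint_set()].
#' @param mc [mc_settings()].
#' @return A tibble, one row per candidate: `axis`, `greater_lag`,
#'   `lesser_lag`, `gbf`, `log10_gbf`, `bounded`, plus a `group` list-column
#'   of the underlying `st_gbf` objects.
#' @export
constraint_validity_profile <- function(cells, candidates, mc = mc_settings()) {
  if (!inherits(candidates, "constraint_set") || !nrow(candidates)) {
    abort("`candidates` must be a non-empty constraint_set.")
  }
  check_cells(cells)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    single <- constraint_set(candidates[i, , drop = FALSE])
    mc_i <- mc
    mc_i$seed <- as.integer((mc$seed + 104729 * i) %% .Machine$integer.max)
    g <- grouped_bf(bf_by_participant(cells, "validity", single, mc_i))
    tibble(
      axis = candidates$axis[i],
      greater_lag = candidates$greater_lag[i],
      lesser_lag = candidates$lesser_lag[i],
      gbf = g$gbf,
      log10_gbf = g$log10_gbf,
      bounded = g$bounded,
      group = list(g)
    )
  })
  list_rbind(rows)
}

#' Reduce a constraint set by its empirical validity
#'
#' Retains exactly the candidates whose grouped validity Bayes factor is at
#' least `threshold`. The default threshold of 1 keeps a constraint unless
#' the evidence is on balance against it — the weakest defensible rule.
#' Reduction is idempotent: the retained constraints' profile values do not
#' change, so a second pass retains the same set.
#'
#' @param profile A tibble from [constraint_validity_profile()].
#' @param threshold Positive retention threshold on the grouped BF.
#' @return A [constraint_set()] of the retained constraints.
#' @export
reduce_constraints <- function(profile, threshold = 1) {
  if (!nrow(profile)) abort("Empty validity profile.")
  if (threshold <= 0) abort("`threshold` must be > 0.")
  keep <- profile$gbf >= threshold
  constraint_set(profile[keep, c("axis", "greater_lag", "lesser_lag")],
                 name = sprintf("empirically reduced (threshold %g)", threshold))
}

#' Select the visibility split point by grouped constraint validity
#'
#' Bins the 6-point visibility scale at every possible split (1|2 through
#' 5|6), rebuilds the high-visibility cells for each, and scores each split
#' by the grouped validity Bayes factor of the supplied visibility
#' constraints. The returned split maximizes that grouped BF; ties go to the
#' more central split (closest to the equal-mass 3|4 boundary). On both
#' experiments' data this procedure selects split 3: top half high, bottom
#' half low.
#'
#' @param trials A conditioned trial table on the full 1-6 rating scale.
#' @param cs_visibility A non-empty [constraint_set()] on the
#'   `visibility_high` axis.
#' @param mc [mc_settings()].
#' @return A list: `split_point` (the winner) and `by_split`, a tibble of
#'   grouped log10 validity BFs for all five splits.
#' @export
select_visibility_split <- function(trials, cs_visibility, mc = mc_settings()) {
  check_trials(trials)
  if (length(unique(trials$visibility)) < 2) {
    abort("All ratings identical: no informative split exists.")
  }
  by_split <- lapply(1:5, function(s) {
    cells <- to_cells(trials, split_point = s)
    vis <- cells[cells$measure == "visibility_high", ]
    # Skip splits that are uninformative for every participant (all-zero or
    # all-full bins throughout).
    degenerate <- all(vis$successes == 0 | vis$successes == vis$trials)
    if (degenerate) {
      return(tibble(split_point = s, log10_gbf = NA_real_, gbf = NA_real_,
                    bounded = NA))
    }
    mc_s <- mc
    mc_s$seed <- as.integer((mc$seed + 15485863 * s) %% .Machine$integer.max)
    g <- grouped_bf(bf_by_participant(cells, "validity", cs_visibility, mc_s))
    tibble(split_point = s, log10_gbf = g$log10_gbf, gbf = g$gbf,
           bounded = g$bounded)
  })
  by_split <- list_rbind(by_split)
  if (all(is.na(by_split$log10_gbf))) {
    abort("Every split produces all-zero or all-full bins for every participant.")
  }
  best <- max(by_split$log10_gbf, na.rm = TRUE)
  winners <- by_split$split_point[
    !is.na(by_split$log10_gbf) & by_split$log10_gbf == best]
  split_point <- winners[order(abs(winners - 3), winners)][1]
  list(split_point = split_point, by_split = by_split)
}
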