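#' End-to-end order-constrained state-trace analysis
#'
#' Orchestrates the full pipeline on a trial table: trial conditioning,
#' visibility binning (fixed or empirically selected split), cell
#' aggregation, lag exclusion, per-participant constraint-validity Bayes
#' factors, per-participant monotonicity Bayes factors conditioned on the
#' constraint region, and the grouped products.
#'
#' @param trials A trial table ([simulate_trials()], [as_trial_table()], or
#'   [read_trials_csv()]).
#' @param constraints A [constraint_set()] (possibly empty) defining the
#'   prior region D; e.g. the union of [ab_constraints()] accuracy and
#'   visibility presets.
#' @param split_point Integer 1-5, or `"auto"` to select the split by grouped
#'   constraint validity on the visibility axis.
#' @param require_t1_correct,exclude_order_errors Trial conditioning flags
#'   (see [condition_t2_trials()]).
#' @param lags_to_drop Lags removed before analysis (e.g. the lag-8 serial
#'   position outlier).
#' @param mc [mc_settings()].
#' @return A `statetrace_analysis` list: `validity` and `monotonicity`
#'   (each an `st_gbf` or `NULL`), `cells`, `split_point`, `split_table`,
#'   `constraints`, and the conditioning flags used (`provenance`).
#' @examples
#' \donttest{
#' trials <- simulate_trials(make_design("nonmonotone_lag1",
#'                                       n_participants = 4,
#'                                       n_trials_per_lag = 60))
#' fit <- statetrace_analysis(trials, constraint_set(),
#'                            mc = mc_settings(n_samples = 2e4))
#' glance(fit$monotonicity)
#' }
#' @export
statetrace_analysis <- function(trials,
                                constraints = constraint_set(),
                                split_point = 3,
                                require_t1_correct = TRUE,
                                exclude_order_errors = TRUE,
                                lags_to_drop = integer(),
                                mc = mc_settings()) {
  conditioned <- condition_t2_trials(trials, require_t1_correct,
                                     exclude_order_errors)
  if (!nrow(conditioned)) abort("No trials survive the conditioning filters.")

  split_table <- NULL
  if (identical(split_point, "auto")) {
    vis_cs <- constraint_set(
      constraints[constraints$axis == "visibility_high", , drop = FALSE])
    if (!nrow(vis_cs)) {
      abort("`split_point = \"auto\"` needs visibility constraints to score.")
    }
    sel <- select_visibility_split(conditioned, vis_cs, mc)
    split_point <- sel$split_point
    split_table <- sel$by_split
  }

  cells <- to_cells(conditioned, split_point = split_point)
  cells <- drop_lags(cells, lags_to_drop)
  if (any(cells$trials == 0)) {
    warn("Some (participant, lag) cells have zero retained trials.")
  }

  validity <- NULL
  if (nrow(constraints)) {
    validity <- grouped_bf(bf_by_participant(cells, "validity", constraints, mc))
  }
  mono_cs <- if (nrow(constraints)) constraints else NULL
  monotonicity <- grouped_bf(
    bf_by_participant(cells, "monotonicity", mono_cs, mc))

  structure(
    list(
      validity = validity,
      monotonicity = monotonicity,
      cells = cells,
      split_point = split_point,
      split_table = split_table,
      constraints = constraints,
      provenance = list(require_t1_correct = require_t1_correct,
                        exclude_order_errors = exclude_order_errors,
                        lags_to_drop = lags_to_drop,
                        mc = unclass(mc))
    ),
    class = "statetrace_analysis"
  )
}

#' @export
print.statetrace_analysis <- function(x, ...) {
  cat("<statetrace_analysis> split_point =", x$split_point, "\n")
  if (!is.null(x$validity)) {
    cat(sprintf("  validity    : grouped BF_D/N(D)  = %.4g (log10 %.2f)\n",
                x$validity$gbf, x$validity$log10_gbf))
  }
  cat(sprintf("  monotonicity: grouped BF_M/NM%s = %.4g (log10 %.2f)\n",
              if (nrow(x$constraints)) "|D" else "  ",
              x$monotonicity$gbf, x$monotonicity$log10_gbf))
  invisible(x)
}

#' Write a state-trace analysis as JSON reports
#'
#' Emits `per_participant.json` (one record per participant and contrast:
#' Bayes factor, log10 value, Monte Carlo error, hit counts, bounded flag)
#' and `group.json` (grouped Bayes factors, homogeneity bands, provenance).
#'
#' @param x A `statetrace_analysis`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_statetrace_report <- function(x, dir) {
  stopifnot(inherits(x, "statetrace_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  per <- list()
  grp <- list(split_point = x$split_point, provenance = x$provenance)
  add <- function(per, g, contrast) {
    tab <- tidy(g)
    tab$contrast <- contrast
    c(per, list(tab))
  }
  if (!is.null(x$validity)) {
    per <- add(per, x$validity, "validity")
    grp$validity <- glance(x$validity)
    grp$validity_bands <- x$validity$bands
  }
  per <- add(per, x$monotonicity, "monotonicity")
  grp$monotonicity <- glance(x$monotonicity)
  grp$monotonicity_bands <- x$monotonicity$bands
  p1 <- file.path(dir, "per_participant.json")
  p2 <- file.path(dir, "group.json")
  jsonlite::write_json(list_rbind(per), p1, dataframe = "rows", digits = NA)
  jsonlite::write_json(grp, p2, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(p1, p2))
}
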