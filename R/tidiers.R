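#' Tidy a Bayes-factor result
#'
#' @param x An `st_bf` object.
#' @param ... Unused.
#' @return A one-row tibble with the point estimate, log10 value, region
#'   probabilities, Monte Carlo error and hit counts.
#' @export
tidy.st_bf <- function(x, ...) {
  tibble(
    participant = x$participant,
    contrast = x$contrast,
    bf = x$bf,
    log10_bf = x$log10_bf,
    prior_region_prob = x$prior_region_prob,
    posterior_region_prob = x$posterior_region_prob,
    mc_se_log10 = x$mc_se_log10,
    n_prior_hits = x$n_prior_hits,
    n_posterior_hits = x$n_posterior_hits,
    bounded = x$bounded
  )
}

#' @rdname tidy.st_bf
#' @export
glance.st_bf <- function(x, ...) {
  tibble(bf = x$bf, log10_bf = x$log10_bf, mc_se_log10 = x$mc_se_log10,
         bounded = x$bounded)
}

#' Tidy a grouped Bayes factor
#'
#' `tidy()` returns the per-participant table; `glance()` the one-row group
#' summary.
#'
#' @param x An `st_gbf` object from [grouped_bf()].
#' @param ... Unused.
#' @export
tidy.st_gbf <- function(x, ...) {
  x$per_participant
}

#' @rdname tidy.st_gbf
#' @export
glance.st_gbf <- function(x, ...) {
  tibble(
    gbf = x$gbf,
    log10_gbf = x$log10_gbf,
    mc_se_log10 = x$mc_se_log10,
    n_participants = x$n_participants,
    bounded = x$bounded,
    single_driver = x$single_driver
  )
}
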