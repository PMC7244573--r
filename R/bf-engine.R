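#' Monte Carlo settings for the region-probability estimator
#'
#' The engine estimates prior and posterior probabilities of ordering regions
#' by sampling latent proportions and counting hits. Sampling proceeds in
#' batches of `n_samples` draws and keeps doubling the total until every
#' region of interest has at least `min_region_hits` hits or `max_total_samples`
#' draws have been spent; below the floor a rule-of-three bound is reported
#' instead of a spurious finite Bayes factor.
#'
#' @param n_samples Draws per batch (and minimum total).
#' @param seed Integer seed; every estimator call with the same settings and
#'   data reproduces exactly.
#' @param min_region_hits Smallest hit count accepted for a finite estimate.
#' @param max_total_samples Cap on total draws.
#' @return An `mc_settings` list.
#' @export
mc_settings <- function(n_samples = 1e6, seed = 1L, min_region_hits = 50,
                        max_total_samples = 1e8) {
  if (min_region_hits < 10) abort("`min_region_hits` must be >= 10.")
  if (max_total_samples < n_samples) {
    abort("`max_total_samples` must be >= `n_samples`.")
  }
  structure(
    list(n_samples = as.double(n_samples), seed = as.integer(seed),
         min_region_hits = as.integer(min_region_hits),
         max_total_samples = as.double(max_total_samples)),
    class = "mc_settings"
  )
}

# Draw n theta configurations for one participant's cells.
# Returns a named list (one element per measure) of n x n_lags matrices with
# lag values as column names. Prior: Beta(1, 1) per cell; posterior: conjugate
# Beta(1 + successes, 1 + failures).
draw_theta_samples <- function(cells, n, posterior = TRUE,
                               allow_empty_cells = FALSE) {
  check_cells(cells)
  if (posterior && !allow_empty_cells && any(cells$trials == 0)) {
    abort(paste0(
      "Posterior sampling with zero-trial cells is only permitted with ",
      "`allow_empty_cells = TRUE` (their posterior equals the prior)."
    ))
  }
  measures <- sort(unique(cells$measure))
  lags <- sort(unique(cells$lag))
  out <- lapply(measures, function(m) {
    sub <- cells[cells$measure == m, ]
    sub <- sub[match(lags, sub$lag), ]
    if (anyNA(sub$lag)) abort("Both measures must share the same lag set.")
    mat <- matrix(NA_real_, nrow = n, ncol = length(lags),
                  dimnames = list(NULL, lags))
    for (j in seq_along(lags)) {
      a <- if (posterior) 1 + sub$successes[j] else 1
      b <- if (posterior) 1 + sub$trials[j] - sub$successes[j] else 1
      mat[, j] <- rbeta(n, a, b)
    }
    mat
  })
  names(out) <- measures
  out
}

#' Region predicates over sampled configurations
#'
#' `monotone_predicate()` tests the monotone region of a two-axis state-trace
#' plot: a draw is monotone when every pair of lags is ordered concordantly on
#' the two axes, or every pair discordantly. `constraint_predicate(cs)` tests
#' membership of the constraint region D of a [constraint_set()].
#' `always_true_predicate()` is the trivial full region. Each returns a
#' vectorized function mapping a list of per-measure sample matrices to a
#' logical vector.
#'
#' @param cs A [constraint_set()].
#' @return A function `f(thetas) -> logical`.
#' @export
monotone_predicate <- function() {
  function(thetas) {
    if (length(thetas) != 2) {
      abort("Monotonicity is defined for exactly two measures.")
    }
    a <- thetas[[1]]
    b <- thetas[[2]]
    k <- ncol(a)
    if (k < 2) abort("Need at least 2 lags.")
    all_conc <- rep(TRUE, nrow(a))
    all_disc <- rep(TRUE, nrow(a))
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        conc <- (a[, i] < a[, j]) == (b[, i] < b[, j])
        all_conc <- all_conc & conc
        all_disc <- all_disc & !conc
      }
    }
    all_conc | all_disc
  }
}

#' @rdname monotone_predicate
#' @export
constraint_predicate <- function(cs) {
  stopifnot(inherits(cs, "constraint_set"))
  force(cs)
  function(thetas) {
    n <- nrow(thetas[[1]])
    ok <- rep(TRUE, n)
    for (i in seq_len(nrow(cs))) {
      m <- thetas[[cs$axis[i]]]
      if (is.null(m)) {
        abort(paste0("No sampled measure named '", cs$axis[i], "'."))
      }
      g <- as.character(cs$greater_lag[i])
      l <- as.character(cs$lesser_lag[i])
      if (!all(c(g, l) %in% colnames(m))) {
        abort("Constraint references a lag absent from the cells.")
      }
      ok <- ok & (m[, g] > m[, l])
    }
    ok
  }
}

#' @rdname monotone_predicate
#' @export
always_true_predicate <- function() {
  function(thetas) rep(TRUE, nrow(thetas[[1]]))
}

#' Monte Carlo probability of an ordering region
#'
#' Estimates P(region) under the independent Beta prior per cell (the
#' encompassing prior inducing a uniform distribution over joint lag
#' orderings) or under the conjugate Beta posterior given the observed
#' successes/trials.
#'
#' @param cells One participant's cells tibble.
#' @param predicate A region test, e.g. [monotone_predicate()].
#' @param mc [mc_settings()].
#' @param posterior Estimate the posterior (default) or prior probability.
#' @param allow_empty_cells Permit zero-trial cells in a posterior estimate
#'   (they contribute their Beta(1,1) prior).
#' @return A list: `estimate`, `se` (binomial), `hits`, `n`.
#' @export
region_probability <- function(cells, predicate, mc = mc_settings(),
                               posterior = TRUE, allow_empty_cells = FALSE) {
  n <- mc$n_samples
  hits <- withr::with_seed(mc$seed, {
    sum(predicate(draw_theta_samples(cells, n, posterior, allow_empty_cells)))
  })
  p <- hits / n
  list(estimate = p, se = sqrt(p * (1 - p) / n), hits = hits, n = n)
}

# Batch sampler: draw() returns a logical vector (or a multi-column logical
# matrix); sample-size doubling until `enough(hits, n)` or the sampling cap.
# Individual draws are chunked at 2e6 rows to bound memory.
accumulate_hits <- function(draw, mc, enough = NULL) {
  if (is.null(enough)) {
    enough <- function(hits, n) min(hits, n - hits) >= mc$min_region_hits
  }
  hits <- NULL
  n <- 0
  target <- mc$n_samples
  repeat {
    while (n < target) {
      batch <- min(2e6, target - n)
      x <- draw(batch)
      if (is.null(dim(x))) x <- matrix(x, ncol = 1)
      cnt <- colSums(x)
      hits <- if (is.null(hits)) cnt else hits + cnt
      n <- n + batch
    }
    if (enough(hits, n) || n >= mc$max_total_samples) break
    target <- min(2 * target, mc$max_total_samples)
  }
  list(hits = unname(hits), n = n)
}

new_bf_result <- function(contrast, participant, prior, posterior, mc,
                          constraints = NULL) {
  # prior/posterior: list(region_hits, total) where total is the number of
  # draws in the conditioning set (all draws when unconditioned).
  floor_ok <- function(x) min(x$region_hits, x$total - x$region_hits) >=
    mc$min_region_hits
  bounded <- !(floor_ok(prior) && floor_ok(posterior))
  # Rule-of-three effective count for regions below the floor: with h < floor
  # observed among n draws, p is bounded by about 3/n at 95%, so 3 stands in
  # for the deficient count and the BF is flagged as a bound.
  eff <- function(h) pmax(h, 3)
  odds <- function(x) {
    h <- x$region_hits
    m <- x$total - x$region_hits
    eff(h) / eff(m)
  }
  bf <- odds(posterior) / odds(prior)
  se_terms <- c(prior$region_hits, prior$total - prior$region_hits,
                posterior$region_hits, posterior$total - posterior$region_hits)
  mc_se_log10 <- sqrt(sum(1 / eff(se_terms))) / log(10)
  structure(
    list(
      contrast = contrast,
      participant = participant,
      bf = bf,
      log10_bf = log10(bf),
      prior_region_prob = prior$region_hits / prior$total,
      posterior_region_prob = posterior$region_hits / posterior$total,
      mc_se_log10 = mc_se_log10,
      n_prior_hits = prior$region_hits,
      n_posterior_hits = posterior$region_hits,
      n_prior_samples = prior$total,
      n_posterior_samples = posterior$total,
      bounded = bounded,
      constraints = constraints
    ),
    class = "st_bf"
  )
}

#' @export
print.st_bf <- function(x, ...) {
  cat(sprintf(
    "<st_bf> %s%s: BF = %.4g (log10 = %.3f, MC se %.3f)%s\n",
    x$contrast,
    if (is.na(x$participant)) "" else paste0(" [", x$participant, "]"),
    x$bf, x$log10_bf, x$mc_se_log10,
    if (x$bounded) " [bound]" else ""
  ))
  invisible(x)
}

single_participant_cells <- function(cells) {
  ids <- unique(cells$participant)
  if (length(ids) != 1) {
    abort("Expected cells for exactly one participant; see bf_by_participant().")
  }
  ids
}

#' Bayes factor for monotonic versus non-monotonic state-trace structure
#'
#' Computes BF_M/NM = (post M / post NM) / (prior M / prior NM) for one
#' participant's two-measure cells under the encompassing Beta prior, by
#' Monte Carlo. When a [constraint_set()] is supplied, both prior and
#' posterior draws are conditioned (by rejection) on lying in the constraint
#' region D before monotonicity is evaluated, giving BF_(M/NM)|D.
#'
#' At least 3 lags are required: with 2 lags every configuration is monotone
#' and the non-monotonic model has zero prior mass. If either the monotone or
#' the non-monotone region collects fewer than `min_region_hits` hits at the
#' sampling cap, the result is a rule-of-three bound with `bounded = TRUE`.
#'
#' @param cells One participant's cells tibble (two measures, shared lags).
#' @param constraints Optional [constraint_set()] defining region D.
#' @param mc [mc_settings()].
#' @param allow_empty_cells Permit zero-trial cells (posterior = prior for
#'   those cells).
#' @return An `st_bf` object; see [tidy.st_bf()].
#' @export
bf_monotonic <- function(cells, constraints = NULL, mc = mc_settings(),
                         allow_empty_cells = FALSE) {
  check_cells(cells)
  pid <- single_participant_cells(cells)
  n_lags <- length(unique(cells$lag))
  if (n_lags < 3) {
    abort("Need >= 3 lags: with 2 lags the non-monotone region has zero mass.")
  }
  if (length(unique(cells$measure)) != 2) {
    abort("Monotonicity needs exactly two measures.")
  }
  mono <- monotone_predicate()
  cond <- if (!is.null(constraints) && nrow(constraints)) {
    constraint_predicate(constraints)
  } else {
    always_true_predicate()
  }

  run_side <- function(posterior, seed) {
    counts <- withr::with_seed(seed, {
      accumulate_hits(function(n) {
        th <- draw_theta_samples(cells, n, posterior, allow_empty_cells)
        in_d <- cond(th)
        cbind(in_d & mono(th), in_d)
      }, mc, enough = function(hits, n) {
        min(hits[1], hits[2] - hits[1]) >= mc$min_region_hits
      })
    })
    if (counts$hits[2] == 0) {
      abort("Constraint region has zero sampled mass: unsatisfiable set?")
    }
    list(region_hits = counts$hits[1], total = counts$hits[2])
  }

  prior <- run_side(posterior = FALSE, seed = mc$seed)
  posterior <- run_side(posterior = TRUE, seed = mc$seed + 1L)
  new_bf_result("monotonicity", pid, prior, posterior, mc, constraints)
}

#' Validity Bayes factor of a constraint region
#'
#' BF_D/N(D): the odds-ratio Bayes factor of the constraint region D against
#' its complement, \[P(D|y) / (1 - P(D|y))\] / \[P(D) / (1 - P(D))\]. This is
#' the evidence that the ordering constraints fit one participant's data,
#' evaluated on a single axis and therefore orthogonal to the cross-axis
#' monotonicity contrast.
#'
#' @inheritParams bf_monotonic
#' @param constraints A non-empty [constraint_set()].
#' @return An `st_bf` object.
#' @export
bf_validity <- function(cells, constraints, mc = mc_settings(),
                        allow_empty_cells = FALSE) {
  check_cells(cells)
  pid <- single_participant_cells(cells)
  if (!inherits(constraints, "constraint_set") || !nrow(constraints)) {
    abort("`constraints` must be a non-empty constraint_set.")
  }
  used <- cells[cells$measure %in% constraints$axis, ]
  if (!nrow(used)) abort("No cells on the constrained axis.")
  pred <- constraint_predicate(constraints)

  run_side <- function(posterior, seed) {
    counts <- withr::with_seed(seed, {
      accumulate_hits(function(n) {
        pred(draw_theta_samples(used, n, posterior, allow_empty_cells))
      }, mc)
    })
    list(region_hits = counts$hits, total = counts$n)
  }
  prior <- run_side(FALSE, mc$seed)
  posterior <- run_side(TRUE, mc$seed + 1L)
  if (prior$region_hits == 0 || prior$region_hits == prior$total) {
    abort("Region or complement has zero sampled prior mass.")
  }
  new_bf_result("validity", pid, prior, posterior, mc, constraints)
}

#' Per-participant Bayes factors over a multi-participant dataset
#'
#' Maps [bf_monotonic()] or [bf_validity()] over every participant in a cells
#' table, with a deterministic per-participant seed derived from `mc$seed`.
#'
#' @param cells A cells tibble with any number of participants.
#' @param contrast `"monotonicity"` or `"validity"`.
#' @param constraints A [constraint_set()] (optional for monotonicity,
#'   required for validity).
#' @param mc [mc_settings()].
#' @param allow_empty_cells Passed through.
#' @return A tibble of tidied results, one row per participant, with the
#'   `st_bf` objects in a `result` list-column.
#' @export
bf_by_participant <- function(cells, contrast = c("monotonicity", "validity"),
                              constraints = NULL, mc = mc_settings(),
                              allow_empty_cells = FALSE) {
  contrast <- match.arg(contrast)
  check_cells(cells)
  ids <- sort(unique(cells$participant))
  results <- lapply(seq_along(ids), function(i) {
    sub <- cells[cells$participant == ids[i], ]
    mc_i <- mc
    mc_i$seed <- as.integer((mc$seed + 7919 * i) %% .Machine$integer.max)
    if (contrast == "monotonicity") {
      bf_monotonic(sub, constraints, mc_i, allow_empty_cells)
    } else {
      bf_validity(sub, constraints, mc_i, allow_empty_cells)
    }
  })
  out <- list_rbind(map(results, tidy))
  out$result <- results
  out
}

#' Grouped Bayes factor across independent participants
#'
#' Treats participants as independent and multiplies their individual Bayes
#' factors: GBF = prod(BF_i), computed as a sum of log10 values. Alongside
#' the product the result carries a homogeneity summary: counts of
#' participants falling in the evidence bands delimited by 1/1000, 1/100,
#' 1/20, 1/3, 3, 20, 100 and 1000, and a flag raised when removing a single
#' participant would flip the direction of the group result (the situation
#' in which a grouped Bayes factor can mislead).
#'
#' @param results A tibble from [bf_by_participant()], a list of `st_bf`
#'   objects, or a bare numeric vector of Bayes factors.
#' @return An `st_gbf` object; see [tidy.st_gbf()] / [glance.st_gbf()].
#' @examples
#' grouped_bf(c(100, 1000))$log10_gbf  # 5
#' @export
grouped_bf <- function(results) {
  if (is.numeric(results)) {
    tab <- tibble(participant = paste0("p", seq_along(results)),
                  bf = as.double(results),
                  log10_bf = log10(as.double(results)),
                  mc_se_log10 = NA_real_,
                  bounded = FALSE)
  } else if (is.data.frame(results)) {
    tab <- as_tibble(results)
    if (!"mc_se_log10" %in% names(tab)) tab$mc_se_log10 <- NA_real_
    tab <- tab[c("participant", "bf", "log10_bf", "mc_se_log10", "bounded")]
  } else if (is.list(results)) {
    tab <- list_rbind(map(results, tidy))[
      c("participant", "bf", "log10_bf", "mc_se_log10", "bounded")]
  } else {
    abort("Unsupported input to grouped_bf().")
  }
  if (!nrow(tab)) abort("Cannot group an empty set of results.")
  if (any(!is.finite(tab$log10_bf))) abort("Non-finite Bayes factor supplied.")
  log10_gbf <- sum(tab$log10_bf)
  mc_se_log10 <- if (all(is.finite(tab$mc_se_log10))) {
    sqrt(sum(tab$mc_se_log10^2))
  } else {
    NA_real_
  }

  cuts <- log10(c(1 / 1000, 1 / 100, 1 / 20, 1 / 3, 3, 20, 100, 1000))
  labels <- c("<1/1000", "1/1000-1/100", "1/100-1/20", "1/20-1/3", "1/3-3",
              "3-20", "20-100", "100-1000", ">1000")
  assigned <- cut(tab$log10_bf, breaks = c(-Inf, cuts, Inf), labels = labels)
  counts <- as.integer(table(factor(assigned, levels = labels)))
  bands <- tibble(band = labels, n = counts)

  # Leave-one-out direction check: does dropping any single participant flip
  # (or zero) the sign of the group log10 BF?
  drop_one <- log10_gbf - tab$log10_bf
  single_driver <- nrow(tab) > 1 && log10_gbf != 0 &&
    any(sign(drop_one) != sign(log10_gbf))
  structure(
    list(
      gbf = 10^log10_gbf,
      log10_gbf = log10_gbf,
      mc_se_log10 = mc_se_log10,
      n_participants = nrow(tab),
      per_participant = tab,
      bands = bands,
      bounded = any(tab$bounded),
      single_driver = single_driver
    ),
    class = "st_gbf"
  )
}

#' @export
print.st_gbf <- function(x, ...) {
  cat(sprintf(
    "<st_gbf> %d participants: GBF = %.4g (log10 = %.3f)%s%s\n",
    x$n_participants, x$gbf, x$log10_gbf,
    if (x$bounded) " [contains bounded BFs]" else "",
    if (x$single_driver) " [direction carried by a single participant]" else ""
  ))
  invisible(x)
}
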