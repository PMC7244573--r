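#' Build a set of strict order constraints on latent proportions
#'
#' A constraint set is the prior region D of the order-constrained analysis:
#' a collection of strict inequalities "at lag `a` the latent proportion on
#' axis `m` is larger than at lag `b`". Constraints are strict because under
#' continuous priors ties have measure zero. Duplicates and directly
#' contradictory pairs (a > b and b > a on the same axis) are rejected at
#' construction.
#'
#' @param constraints A data frame with columns `axis`, `greater_lag`,
#'   `lesser_lag` (may have zero rows), or a character vector of
#'   `"axis: a > b"` strings as produced by [format_constraints()].
#' @param name Optional label for the set.
#' @return A `constraint_set`: a tibble with class attached.
#' @examples
#' constraint_set(data.frame(axis = "accuracy", greater_lag = 1, lesser_lag = 2))
#' constraint_set("accuracy: 1 > 2")
#' @export
constraint_set <- function(constraints = NULL, name = NULL) {
  if (is.null(constraints)) {
    cs <- tibble(axis = character(), greater_lag = integer(),
                 lesser_lag = integer())
  } else if (is.character(constraints)) {
    cs <- parse_constraints(constraints)
  } else {
    cs <- as_tibble(constraints)[c("axis", "greater_lag", "lesser_lag")]
    cs$greater_lag <- as.integer(cs$greater_lag)
    cs$lesser_lag <- as.integer(cs$lesser_lag)
  }
  if (any(cs$greater_lag == cs$lesser_lag)) {
    abort("A constraint cannot compare a lag with itself.")
  }
  if (anyDuplicated(cs)) abort("Duplicate constraints in set.")
  key <- paste(cs$axis, cs$greater_lag, cs$lesser_lag)
  rev_key <- paste(cs$axis, cs$lesser_lag, cs$greater_lag)
  if (any(key %in% rev_key)) {
    abort("Contradictory constraint pair (a > b and b > a on the same axis).")
  }
  structure(cs, class = c("constraint_set", class(cs)),
            name = name %||% "custom")
}

parse_constraints <- function(x) {
  m <- regmatches(x, regexec("^\\s*([^:]+?)\\s*:\\s*(\\d+)\\s*>\\s*(\\d+)\\s*$", x))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) {
    abort(paste0("Cannot parse constraint string(s): ",
                 paste(x[bad], collapse = "; ")))
  }
  tibble(
    axis = vapply(m, `[`, character(1), 2),
    greater_lag = as.integer(vapply(m, `[`, character(1), 3)),
    lesser_lag = as.integer(vapply(m, `[`, character(1), 4))
  )
}

#' Serialize a constraint set to "axis: a > b" strings
#'
#' @param cs A [constraint_set()].
#' @return A character vector, one string per constraint.
#' @export
format_constraints <- function(cs) {
  stopifnot(inherits(cs, "constraint_set"))
  sprintf("%s: %d > %d", cs$axis, cs$greater_lag, cs$lesser_lag)
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set>", attr(x, "name"), "-", nrow(x), "constraint(s)\n")
  if (nrow(x)) cat(paste0("  ", format_constraints(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Literature and empirically reduced constraint presets
#'
#' The published constraint sets for the two attentional-blink experiments.
#' For the colour-marked experiment, report accuracy is constrained so that
#' lags 1, 4 and 6 exceed lags 2 and 3, with lag 1 additionally exceeding
#' lag 4; the empirical reduction drops the two lag-4 constraints (4 > 2,
#' 4 > 3) and nothing else. Subjective visibility is constrained
#' 6 > 4 > 3 > 2 at both stages. The replication (letters-in-digits)
#' experiment reuses the literature sets with lag 5 substituted for lag 4 and
#' lag 7 for lag 6; it never derived empirical constraints, and its T1 axis
#' is left unconstrained.
#'
#' @param experiment `"colour_marked"` or `"replication"`.
#' @param stage `"literature"` or `"empirical"`.
#' @param axis `"accuracy"`, `"visibility"` or `"t1"`. Visibility constraints
#'   are emitted with axis label `"visibility_high"`, matching the measure
#'   label of [to_cells()].
#' @return A [constraint_set()].
#' @examples
#' ab_constraints("colour_marked", "literature", "accuracy")
#' ab_constraints("replication", "literature", "t1")
#' @export
ab_constraints <- function(experiment = c("colour_marked", "replication"),
                           stage = c("literature", "empirical"),
                           axis = c("accuracy", "visibility", "t1")) {
  experiment <- match.arg(experiment)
  stage <- match.arg(stage)
  axis <- match.arg(axis)

  if (experiment == "replication" && stage == "empirical") {
    abort("The replication analysis did not derive empirical constraints.")
  }
  if (experiment == "colour_marked" && axis == "t1") {
    abort("T1 visibility was not collected in the colour-marked experiment.")
  }
  if (axis == "t1") {
    return(constraint_set(name = "replication/t1 (unconstrained)"))
  }

  pairs <- if (axis == "accuracy") {
    acc <- list(c(1, 2), c(1, 3), c(4, 2), c(4, 3), c(6, 2), c(6, 3), c(1, 4))
    if (stage == "empirical") acc <- acc[-c(3, 4)]  # lag-4 constraints dropped
    acc
  } else {
    list(c(6, 4), c(4, 3), c(3, 2))
  }
  tab <- do.call(rbind, pairs)
  if (experiment == "replication") {
    tab[tab == 4] <- 5L
    tab[tab == 6] <- 7L
  }
  axis_label <- if (axis == "accuracy") "accuracy" else "visibility_high"
  constraint_set(
    tibble(axis = axis_label, greater_lag = tab[, 1], lesser_lag = tab[, 2]),
    name = paste(experiment, stage, axis, sep = "/")
  )
}

#' Does a latent configuration satisfy a constraint set?
#'
#' @param theta A data frame with columns `measure` (or `axis`), `lag` and
#'   `value`: one latent proportion per (axis, lag).
#' @param cs A [constraint_set()].
#' @return `TRUE` iff every constraint holds strictly (vacuously `TRUE` for an
#'   empty set).
#' @export
satisfies <- function(theta, cs) {
  stopifnot(inherits(cs, "constraint_set"))
  theta <- as_tibble(theta)
  if ("axis" %in% names(theta) && !"measure" %in% names(theta)) {
    theta <- rename(theta, measure = "axis")
  }
  if (!nrow(cs)) return(TRUE)
  lookup <- function(axis, lag) {
    v <- theta$value[theta$measure == axis & theta$lag == lag]
    if (length(v) != 1) {
      abort(sprintf("theta has no unique value for axis '%s' at lag %d.", axis, lag))
    }
    v
  }
  all(vapply(seq_len(nrow(cs)), function(i) {
    lookup(cs$axis[i], cs$greater_lag[i]) > lookup(cs$axis[i], cs$lesser_lag[i])
  }, logical(1)))
}

#' Test monotonicity of a two-axis state-trace configuration
#'
#' The configuration is monotone when the rank order of the lags on one axis
#' is either identical to, or the exact reverse of, their rank order on the
#' other axis — precisely when a single monotone curve can pass through all
#' points of the state-trace plot. Within-axis ties are rejected: they have
#' probability zero under continuous sampling, so a tie signals a degenerate
#' user-supplied configuration rather than something to break arbitrarily.
#'
#' @param theta_axis1,theta_axis2 Numeric vectors of latent proportions, one
#'   per lag, in the same lag order.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_monotone(c(0.2, 0.5, 0.8), c(0.8, 0.5, 0.2))  # reversed: monotone
#' is_monotone(c(0.2, 0.5, 0.8), c(0.5, 0.2, 0.8))  # neither: non-monotone
#' @export
is_monotone <- function(theta_axis1, theta_axis2) {
  if (length(theta_axis1) != length(theta_axis2)) {
    abort("Axes must have the same number of lags.")
  }
  if (length(theta_axis1) < 2) abort("Need at least 2 lags.")
  if (anyDuplicated(theta_axis1) || anyDuplicated(theta_axis2)) {
    abort("Tie encountered: within-axis ties are not permitted.")
  }
  o1 <- order(theta_axis1)
  o2 <- order(theta_axis2)
  identical(o1, o2) || identical(o1, rev(o2))
}

#' Prior probability of the monotone region under the uniform ordering prior
#'
#' With n lags there are n! orderings per axis and (n!)^2 joint orderings,
#' all equally likely under the completely uniform encompassing prior. The
#' monotone region pairs each axis-1 ordering with itself or its reverse, so
#' its prior mass is 2 * n! / (n!)^2 = 2 / n!.
#'
#' @param n_lags Number of dimension-factor levels (>= 2).
#' @return The prior probability 2 / n_lags!.
#' @examples
#' monotone_prior_probability(3)  # 1/3
#' monotone_prior_probability(5)  # 1/60
#' @export
monotone_prior_probability <- function(n_lags) {
  if (length(n_lags) != 1 || n_lags < 2 || n_lags != round(n_lags)) {
    abort("`n_lags` must be a single integer >= 2.")
  }
  2 / factorial(n_lags)
}
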