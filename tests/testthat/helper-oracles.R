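# Independent oracles used to cross-check the package's estimators. These
# deliberately share no code with the implementation paths they verify.

# Brute-force per-time-step occupancy automaton for the serial-experience
# rule: one occupant at a time; an item claims experience when supra-
# threshold and the slot is free, with priority to the item whose current
# supra-threshold run started earliest (ties by column order); the occupant
# releases the step its trace drops below threshold.
oracle_serial_experience <- function(traces, phi, time) {
  dt <- if (length(time) > 1) time[2] - time[1] else 1
  k <- ncol(traces)
  run_start <- rep(NA_real_, k)
  occupant <- 0L
  ep_start <- NA_real_
  episodes <- list()
  for (s in seq_along(time)) {
    supra <- traces[s, ] >= phi
    for (j in seq_len(k)) {
      if (supra[j] && is.na(run_start[j])) run_start[j] <- time[s]
      if (!supra[j]) run_start[j] <- NA_real_
    }
    if (occupant > 0L && !supra[occupant]) {
      episodes[[length(episodes) + 1]] <-
        list(item = occupant, start = ep_start, end = time[s])
      occupant <- 0L
    }
    if (occupant == 0L && any(supra)) {
      cand <- which(supra)
      occupant <- cand[order(run_start[cand], cand)][1]
      ep_start <- time[s]
    }
  }
  if (occupant > 0L) {
    episodes[[length(episodes) + 1]] <-
      list(item = occupant, start = ep_start, end = time[length(time)] + dt)
  }
  if (!length(episodes)) {
    return(tibble::tibble(item_idx = integer(), start = numeric(),
                          end = numeric()))
  }
  tibble::tibble(
    item_idx = vapply(episodes, function(e) e$item, integer(1)),
    start = vapply(episodes, function(e) e$start, numeric(1)),
    end = vapply(episodes, function(e) e$end, numeric(1))
  )
}

# Random piecewise-linear trace sets on a fixed grid.
random_traces <- function(n_items = 3, n_time = 240, n_knots = 6) {
  time <- seq(0, n_time - 1)
  tr <- vapply(seq_len(n_items), function(j) {
    knots <- sort(sample(seq_along(time), n_knots))
    vals <- runif(n_knots, 0, 2)
    stats::approx(time[knots], vals, xout = time, rule = 2)$y
  }, numeric(length(time)))
  colnames(tr) <- paste0("item", seq_len(n_items))
  list(traces = tr, time = time)
}

# Permutation ids (and the ids of the reversed permutations) of each row of
# a samples matrix, encoded from pairwise-comparison ranks.
perm_ids <- function(m) {
  L <- ncol(m)
  n <- nrow(m)
  R <- matrix(0, n, L)
  for (a in seq_len(L)) {
    for (b in seq_len(L)) {
      if (a != b) R[, a] <- R[, a] + (m[, b] < m[, a])
    }
  }
  base <- L^(seq_len(L) - 1)
  list(id = as.vector(R %*% base), rev = as.vector((L - 1 - R) %*% base))
}

# Axis-factorized monotone probability: because the two axes are independent
# given the data, P(monotone) = sum over axis-1 orderings pi of
# P1(pi) * (P2(pi) + P2(reverse pi)). Axes are sampled separately, each from
# its own Beta cells, so this estimator is independent of the joint draw.
oracle_factorized_monotone <- function(cells, n, posterior = TRUE,
                                       seed = 1) {
  measures <- sort(unique(cells$measure))
  lags <- sort(unique(cells$lag))
  draw_axis <- function(measure, seed_offset) {
    sub <- cells[cells$measure == measure, ]
    sub <- sub[match(lags, sub$lag), ]
    withr::with_seed(seed + seed_offset, {
      vapply(seq_along(lags), function(j) {
        a <- if (posterior) 1 + sub$successes[j] else 1
        b <- if (posterior) 1 + sub$trials[j] - sub$successes[j] else 1
        stats::rbeta(n, a, b)
      }, numeric(n))
    })
  }
  L <- length(lags)
  ids1 <- perm_ids(draw_axis(measures[1], 101))$id
  ids2 <- perm_ids(draw_axis(measures[2], 202))$id
  f1 <- table(ids1) / n
  f2 <- table(ids2) / n
  # With id = sum_j r_j L^(j-1), the reversed ordering (ranks L-1-r_j) has
  # id (L-1) * sum_j L^(j-1) - id.
  rev_id <- function(id) (L - 1) * sum(L^(seq_len(L) - 1)) - id
  lookup <- function(tab, key) {
    key <- as.character(key)
    if (key %in% names(tab)) as.numeric(tab[[key]]) else 0
  }
  p <- 0
  var_terms <- 0
  for (pi in names(f1)) {
    q <- lookup(f2, pi) + lookup(f2, rev_id(as.numeric(pi)))
    p1 <- as.numeric(f1[[pi]])
    p <- p + p1 * q
    var_terms <- var_terms + q^2 * p1 * (1 - p1) / n +
      p1^2 * q * (1 - q) / n
  }
  list(estimate = p, se = sqrt(var_terms))
}

# Exhaustive enumeration of all (n!)^2 joint orderings; counts the monotone
# pairs (identical or exactly reversed orderings).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

enumerate_monotone_fraction <- function(n) {
  perms <- all_perms(n)
  hits <- 0
  for (p1 in perms) {
    for (p2 in perms) {
      if (identical(p1, p2) || identical(p1, rev(p2))) hits <- hits + 1
    }
  }
  hits / length(perms)^2
}
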