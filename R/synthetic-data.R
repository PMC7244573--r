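#' Latent designs for synthetic RSVP data
#'
#' A latent design fixes the population-level behaviour of a simulated
#' attentional-blink experiment: per-lag T1 accuracy, per-lag T2|T1 accuracy,
#' a per-lag distribution over the 6-point visibility scale, an order-error
#' rate, and the sampling frame (participants, trials per lag, between-
#' participant jitter). [simulate_trials()] turns a design into a tidy trial
#' table.
#'
#' Three presets are provided:
#' \describe{
#'   \item{`flat`}{identical accuracy and visibility at every lag — a null
#'     design with no lag structure at all.}
#'   \item{`monotone`}{a blink-shaped dip in both measures with concordant
#'     rank orders across lags, so accuracy and high-visibility probability
#'     admit a single monotone state-trace curve.}
#'   \item{`nonmonotone_lag1`}{accuracy is maximal at lag 1 (lag-1 sparing)
#'     while the probability of a high visibility rating at lag 1 sits below
#'     its value at the longest lag — the dissociated pattern in which no
#'     monotone curve can join the lags.}
#' }
#'
#' @param preset One of `"flat"`, `"monotone"`, `"nonmonotone_lag1"`.
#' @param ... Named overrides for any design field (`lags`, `theta_t1`,
#'   `theta_acc`, `vis_probs`, `order_error_rate`, `n_trials_per_lag`,
#'   `n_participants`, `participant_jitter_sd`, `seed`). Per-lag fields may be
#'   a scalar (recycled) or one value per lag; `vis_probs` is a
#'   `length(lags)` x 6 matrix of visibility-rating probabilities.
#' @return A `latent_design` object (a validated list).
#' @examples
#' d <- make_design("nonmonotone_lag1", n_participants = 4)
#' d$theta_acc
#' @export
make_design <- function(preset = c("flat", "monotone", "nonmonotone_lag1"), ...) {
  preset <- match.arg(preset)
  lags <- c(1L, 2L, 3L, 4L, 6L)

  # Blink-shaped per-lag values; within each axis adjacent sorted values are
  # 0.15 apart so individual-participant Bayes factors are well powered at
  # a couple of hundred trials per cell.
  p_high <- switch(preset,
    flat             = rep(0.50, 5),
    monotone         = c(0.78, 0.33, 0.48, 0.63, 0.93),
    nonmonotone_lag1 = c(0.35, 0.20, 0.50, 0.65, 0.80)
  )
  theta_acc <- switch(preset,
    flat             = rep(0.60, 5),
    monotone         = c(0.80, 0.35, 0.50, 0.65, 0.95),
    nonmonotone_lag1 = c(0.95, 0.35, 0.50, 0.65, 0.80)
  )

  design <- list(
    lags = lags,
    theta_t1 = rep(0.9, length(lags)),
    theta_acc = theta_acc,
    vis_probs = vis_probs_from_high(p_high),
    order_error_rate = rep(0.1, length(lags)),
    n_trials_per_lag = 200L,
    n_participants = 18L,
    participant_jitter_sd = 0.3,
    seed = 1L,
    preset = preset
  )

  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(design))
  if (length(unknown)) {
    abort(paste0("Unknown design field(s): ", paste(unknown, collapse = ", ")))
  }
  if ("lags" %in% names(overrides)) {
    new_lags <- as.integer(overrides$lags)
    k <- length(new_lags)
    recycle <- function(x) if (length(x) == 1) rep(x, k) else x
    design$lags <- new_lags
    for (f in c("theta_t1", "theta_acc", "order_error_rate")) {
      if (!f %in% names(overrides)) design[[f]] <- recycle(design[[f]][1])
    }
    if (!"vis_probs" %in% names(overrides)) {
      design$vis_probs <- vis_probs_from_high(rep(p_high[1], k))
    }
  }
  for (f in setdiff(names(overrides), "lags")) design[[f]] <- overrides[[f]]
  design$lags <- as.integer(design$lags)
  for (f in c("theta_t1", "theta_acc", "order_error_rate")) {
    if (length(design[[f]]) == 1) design[[f]] <- rep(design[[f]], length(design$lags))
  }
  if (is.vector(design$vis_probs) && length(design$vis_probs) == 6) {
    design$vis_probs <- matrix(rep(design$vis_probs, length(design$lags)),
                               ncol = 6, byrow = TRUE)
  }

  validate_design(design)
}

# Split a high-visibility probability p into a full 6-point distribution:
# mass p over ratings 4:6 and 1 - p over ratings 1:3, each with a fixed
# within-bin shape.
vis_probs_from_high <- function(p_high) {
  low_shape <- c(0.5, 0.3, 0.2)
  high_shape <- c(0.2, 0.3, 0.5)
  t(vapply(
    p_high,
    function(p) c((1 - p) * low_shape, p * high_shape),
    numeric(6)
  ))
}

validate_design <- function(design) {
  k <- length(design$lags)
  if (k < 1 || any(diff(design$lags) <= 0)) {
    abort("`lags` must be strictly increasing.")
  }
  for (f in c("theta_t1", "theta_acc", "order_error_rate")) {
    v <- design[[f]]
    if (length(v) != k || any(!is.finite(v)) || any(v < 0 | v > 1)) {
      abort(paste0("`", f, "` must be ", k, " probabilities in [0, 1]."))
    }
  }
  vp <- design$vis_probs
  if (!is.matrix(vp) || nrow(vp) != k || ncol(vp) != 6 ||
      any(vp < 0 | vp > 1) || any(abs(rowSums(vp) - 1) > 1e-9)) {
    abort("`vis_probs` must be a lags x 6 matrix of rows summing to 1.")
  }
  if (design$n_trials_per_lag < 1 || design$n_participants < 1) {
    abort("`n_trials_per_lag` and `n_participants` must be >= 1.")
  }
  if (design$participant_jitter_sd < 0) {
    abort("`participant_jitter_sd` must be >= 0.")
  }
  structure(design, class = "latent_design")
}

#' @export
print.latent_design <- function(x, ...) {
  cat("<latent_design> preset:", x$preset %||% "custom", "\n")
  cat("  lags:", paste(x$lags, collapse = ", "),
      "|", x$n_participants, "participants x",
      x$n_trials_per_lag, "trials/lag\n")
  cat("  theta_acc:", paste(format(x$theta_acc, digits = 2), collapse = ", "), "\n")
  cat("  P(vis >= 4):",
      paste(format(rowSums(x$vis_probs[, 4:6, drop = FALSE]), digits = 2),
            collapse = ", "), "\n")
  invisible(x)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Participant-level perturbation: a single logit-scale offset per participant
# and field, shared across lags so within-participant rank orders (and hence
# the monotone / non-monotone structure of the design) are preserved.
jitter_probs <- function(p, offset) inv_logit(logit(pmin(pmax(p, 1e-8), 1 - 1e-8)) + offset)

jitter_vis_probs <- function(vis_probs, offset) {
  cum <- t(apply(vis_probs, 1, cumsum))[, 1:5, drop = FALSE]
  cum <- jitter_probs(cum, offset)
  cum <- matrix(apply(cum, 1, cummax),  # keep cut points ordered after jitter
                ncol = 5, byrow = TRUE)
  probs <- cbind(cum, 1)
  probs <- cbind(probs[, 1, drop = FALSE],
                 probs[, 2:6, drop = FALSE] - probs[, 1:5, drop = FALSE])
  pmax(probs, 0)
}

#' Simulate RSVP trial tables from a latent design
#'
#' Draws one row per (participant, lag, trial). Per participant the design
#' probabilities are perturbed by a single logit-normal offset (per field), so
#' each participant's cells stay binomial and the design's rank orders across
#' lags are preserved. T1 report, T2 report and the visibility rating are
#' drawn independently given the participant-level probabilities; the
#' order-error flag is drawn only on trials where both targets are correct
#' (a swapped-order report requires both identities).
#'
#' @param design A [make_design()] object.
#' @param seed Integer seed; defaults to the design's own seed. Identical
#'   seeds give identical tables.
#' @return A tibble with columns `participant`, `lag`, `t1_correct`,
#'   `t2_correct`, `visibility`, `order_error`.
#' @examples
#' trials <- simulate_trials(make_design("flat", n_participants = 2,
#'                                       n_trials_per_lag = 20))
#' dplyr::count(trials, lag)
#' @export
simulate_trials <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "latent_design"))
  withr::with_seed(seed, {
    k <- length(design$lags)
    n <- design$n_trials_per_lag
    out <- vector("list", design$n_participants)
    for (p in seq_len(design$n_participants)) {
      off <- rnorm(3, 0, design$participant_jitter_sd)
      th_t1 <- jitter_probs(design$theta_t1, off[1])
      th_acc <- jitter_probs(design$theta_acc, off[2])
      vp <- jitter_vis_probs(design$vis_probs, off[3])
      rows <- vector("list", k)
      for (i in seq_len(k)) {
        t1 <- rbinom(n, 1, th_t1[i]) == 1
        t2 <- rbinom(n, 1, th_acc[i]) == 1
        vis <- sample.int(6, n, replace = TRUE, prob = vp[i, ])
        oe <- (t1 & t2) & (runif(n) < design$order_error_rate[i])
        rows[[i]] <- tibble(
          participant = sprintf("p%02d", p),
          lag = design$lags[i],
          t1_correct = t1,
          t2_correct = t2,
          visibility = as.integer(vis),
          order_error = oe
        )
      }
      out[[p]] <- bind_rows(rows)
    }
    bind_rows(out)
  })
}
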