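---
title: "Order-constrained state-trace analysis and the serial-experience model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order-constrained state-trace analysis and the serial-experience model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinktrace)
```

## The scientific question

In rapid serial visual presentation (RSVP), a second target (T2) presented
100–500 ms after a correctly encoded first target (T1) is often missed — the
attentional blink. When participants also rate T2's subjective visibility on
a 1–6 scale, the visibility curve across lags has a different shape from the
report-accuracy curve: most strikingly, accuracy shows lag-1 sparing while
visibility can show little or none. If report accuracy and subjective
visibility were both monotone readouts of one latent process, then across
lags the two measures would have to be ordered concordantly (or exactly
anti-concordantly). A state-trace plot — accuracy on one axis, the
probability of a high visibility rating on the other, one point per lag —
makes this testable: a single monotone curve through all points is possible
exactly when the two rank orders are identical or reversed.

`blinktrace` quantifies that question with order-constrained Bayesian model
comparison, and complements it with a process model (an STST-lite simulator
with a serial-experience readout) that produces the dissociated pattern from
an explicit mechanism.

## The Bayesian machinery

### Encompassing prior and region probabilities

Each (participant, measure, lag) cell is a binomial count. Under the
encompassing prior every cell's latent proportion is independently
Beta(1, 1), which makes all $(n!)^2$ joint orderings of $n$ lags across the
two axes equally likely; the posterior is conjugate,
Beta$(1 + \text{successes}, 1 + \text{failures})$. Any ordering hypothesis
is then a *region* of this space, and its Bayes factor against the
complement reduces to a ratio of posterior to prior region odds:

$$BF_{M/NM} \;=\; \frac{\pi_M^{(y)} / \pi_{NM}^{(y)}}{\pi_M / \pi_{NM}},$$

where $M$ is the monotone region (axis-2 ordering equal to axis-1's or its
reverse) and $NM$ its complement. The prior mass of $M$ has the closed form
$2\,n!/(n!)^2 = 2/n!$, which the test suite uses as an oracle. Region
probabilities are estimated by Monte Carlo: draw proportions per cell,
evaluate the region predicate, count hits. A draw is monotone iff all lag
pairs are ordered concordantly on both axes, or all discordantly.

Prior knowledge about the blink enters as strict order constraints on single
axes (for example "accuracy at lag 1 exceeds accuracy at lag 2"), forming a
region $D$. Conditioning on $D$ is by rejection, applied identically to
prior and posterior draws, giving $BF_{(M/NM)|D}$. The evidence that $D$
itself fits a participant's data is the validity Bayes factor
$BF_{D/N(D)} = [P(D|y)/(1-P(D|y))]\,/\,[P(D)/(1-P(D))]$.

Constraints are strict inequalities: under continuous priors ties have
measure zero, so observed ties in user-supplied configurations raise an
error rather than being broken arbitrarily.

### Monte Carlo control

`mc_settings()` governs the estimator: `n_samples` draws (default $10^6$),
doubling adaptively until every region of interest has at least
`min_region_hits` (default 50) hits, up to `max_total_samples` (default
$10^8$). When data are strongly informative one region may collect
essentially no posterior hits at any affordable sample size; the engine then
reports a one-sided bound built from the rule-of-three count (3 stands in
for the deficient hit count) and flags the result `bounded`, rather than
reporting a spuriously finite Bayes factor. The Monte Carlo error of
$\log_{10} BF$ is the delta-method binomial expression
$\sqrt{\sum 1/h_i}/\ln 10$ over the four hit/miss counts. Tests and the
acceptance script run at $5\times10^4$–$10^6$ draws with caps of
$2\times10^5$–$1.6\times10^6$; at those sizes the log10 MC error is below
0.01 in the regimes exercised, and strongly informative cells return bounds
quickly.

### Groups of participants

Averaging data across participants can manufacture or destroy
monotonicity, so the group-level summary is the grouped Bayes factor
$GBF = \prod_i BF_i$, computed as a sum of log10 values. Because a product
can be dominated by one extreme participant, `grouped_bf()` also reports a
homogeneity summary — counts of participants in the evidence bands
delimited by 1/1000, 1/100, 1/20, 1/3, 3, 20, 100, 1000 — and a
leave-one-out flag raised when removing any single participant would flip
the direction of the group result.

### Empirical reduction of the constraint set

A literature-derived constraint set may not fit a given dataset.
`constraint_validity_profile()` scores each candidate constraint *alone* on
its own axis: per participant, the validity Bayes factor of the singleton
region, then the grouped product. Scoring is single-axis and so orthogonal
to the cross-axis monotonicity contrast — the property that makes it
legitimate to select the prior from the same data. `reduce_constraints()`
retains candidates with grouped validity at or above a threshold of 1 (keep
unless the evidence is on balance against); both the per-constraint scoring
and the retention rule are deliberate design choices where a joint-subset
search would also have been defensible, and both are configurable. The same
machinery selects the visibility split: `select_visibility_split()` scores
all five binnings of the 1–6 scale by grouped constraint validity and
returns the maximizer, with ties resolved toward the central, equal-mass
3|4 boundary.

## The synthetic RSVP generator

`make_design()` + `simulate_trials()` produce tidy per-trial tables with
known latent structure, so every downstream stage is testable without any
external data. The defaults emulate a well-powered blink experiment: lags
1, 2, 3, 4, 6; 18 participants; 200 trials per lag (the trial count of the
higher-powered experiment that supports the minimal-visibility analysis);
T1 accuracy 0.9; an order-error rate of 0.1 on both-correct trials (the
reduced rate typical of a colour-marked T1); and a between-participant
logit-normal jitter of sd 0.3. Three presets fix the state-trace structure:
`flat` (no lag structure), `monotone` (blink-shaped but rank-concordant
across the two measures), and `nonmonotone_lag1` (accuracy maximal at lag 1
while high-visibility probability at lag 1 sits below the longest lag — the
dissociated pattern). In the structured presets adjacent sorted values
within an axis are 0.15 apart, which makes individual participants
decisively recoverable at 200 trials per cell.

Participant heterogeneity is a single logit-scale offset per participant
and field, shared across lags. That choice keeps each participant's cells
binomial (matching the analysis model) and — importantly — preserves the
design's rank orders within participant, so a `monotone` design stays
monotone for every simulated participant. Visibility jitter perturbs the
cumulative rating cut points by the same shared offset. T1-incorrect trials
still record a visibility draw (conditioning is the preprocessor's job),
and order errors are drawn only on both-correct trials, since a swapped
report requires both identities.

What the generator does *not* emulate: letter identities and response
confusions, serial-position effects within a stream, trial-order learning,
or any correlation between accuracy and visibility beyond their shared lag
structure. Passing recovery tests therefore show that the estimator
recovers known ordinal structure from binomial data of realistic size — not
that real RSVP data satisfy the binomial or independence assumptions.

## Preprocessing rules

`condition_t2_trials()` exposes both published conventions as independent
flags: require T1 correct and exclude order errors (the colour-marked
convention), or analyse everything (the replication convention). Visibility
is binned at a configurable split (default 3) on the same retained trial
set as accuracy. `drop_lags()` implements serial-position outlier
exclusion, such as removing lag 8 when it is the stream's outlying last
position. Cells with zero retained trials are carried explicitly as (0, 0)
and rejected by the Bayes-factor engine unless `allow_empty_cells = TRUE`
deliberately treats their posterior as the prior — explicit failure beats
silent imputation.

## The constraint presets

`ab_constraints()` returns the published sets: for the colour-marked
experiment's accuracy axis, lags 1, 4, 6 above lags 2, 3 with lag 1 also
above lag 4 (literature), reduced empirically to drop the two lag-4
constraints; visibility ordered 6 > 4 > 3 > 2 at both stages; for the
replication, the same sets with lag 5 for lag 4 and lag 7 for lag 6; and an
unconstrained T1 axis. The replication never derived empirical constraints
and the colour-marked experiment never collected T1 visibility, so those
combinations error rather than guessing.

## The minimal-visibility ("sight-blind recall") analysis

Restricting T2|T1 accuracy to trials rated 1 ("not seen") asks whether
identity report survives the absence of reported experience. Accuracy per
participant is compared against the guessing chance of 1/21 (4.76%, one of
21 candidate letters) with a one-sample t-test, one-sided by default
because the hypothesis is directional; Cohen's d is (mean − chance)/sd. The
lag-1 versus lag-3 contrast is a paired t-test on differences with listwise
deletion of participants missing either lag. Zero-variance samples are
flagged degenerate: constant-at-chance returns the natural limit t = 0,
d = 0, and constant non-zero differences (infinite t) return no finite
statistic.

## STST-lite and the serial-experience readout

The simulator is a deliberately small stand-in for the neural STST
architecture, built from the architecture's narrative rather than its
original equations (which are not reproduced here): its parameters live in
one documented block (`sese_params()`) and were calibrated once to the
qualitative pattern below, not fitted to any published curve.

Per item: an input pulse (110 ms, outlasting the 90 ms SOA so successive
items overlap); masked drive = pulse − 0.5 × next item's pulse − 0.2 ×
other concurrent pulses (backward masking stronger than lateral); a leaky
item stage with self-excitation close to the leak (net leak 0.002/ms, so a
represented item persists for hundreds of ms); and a task filter that
passes targets at gain 1 and distractors at 0.15. The filtered activation
is the item's *trace* — the aggregate that stands in for the summed
post-synaptic activity the full model distributes over layers.

The blaster fires when a target's trace makes a fresh upward crossing of
the detection threshold (0.55), multiplying all stimulus drive by 2.5 for
150 ms. Tokenisation starts when a trace crosses the encoding threshold
(1.6) and either no binding is in progress or the blaster window is still
open — the latter is the lag-1 joint-encoding route, capped at two
concurrent tokens. Binding progress integrates at a rate that grows with
instantaneous trace strength (base 450 ms at threshold, floored at 250 ms),
aborts if the trace decays below the encoding threshold, and its completion
is what "encoded", and hence correct report, means. While any binding is in
progress the blaster is inhibited, and detections arriving in that window
are lost — that loss *is* the blink: a lag-2/3 T2 crosses detection during
T1's binding, never gets the blaster, and its unboosted trace cannot
sustain a binding of its own, while a lag-4+ T2 crosses after release and
recovers.

Subjective visibility is a separate, serial readout. An item is
experienced while its trace exceeds the subjectivity threshold (1.3) *and*
no other item occupies experience; a supra-threshold item waits, begins an
episode at the release instant only if still supra-threshold
(half-open `[start, end)` bookkeeping), and any time spent waiting is lost.
Experienced duration maps to the 1–6 rating scale through five duration
cuts (50, 120, 200, 300, 420 ms; closed from below). The virtual P3 is
gated the same way: during an episode only the occupant's trace contributes
to the grand trace; outside episodes the grand trace is the plain sum.

At the default parameters a noise-free run encodes a lone target, encodes
both targets at lag 1 (with T2's experience cut to ~150 ms by T1's
occupancy), blinks T2 at lags 2–3, and recovers by lag 6 — high lag-1
accuracy with low lag-1 visibility, which is exactly the non-monotone
signature. Trial noise is a multiplicative Gaussian perturbation (sd 0.25)
of input strength, the simplest mechanism that grades these all-or-none
outcomes into realistic curves. Deliberately out of scope: order errors and
token conjunction mechanics, eSTST extensions, distractor-driven steady
state responses, and any quantitative fit to human ERPs.

Two readout conventions are open in principle: whether distractors may
claim experience episodes (default yes — their suppressed traces almost
never reach the threshold, and excluding them would need a principled
reason the architecture does not supply), and how durations map to the
rating scale (the cuts above, chosen so a lone target's ~550 ms experience
rates near the scale top and a blinked target's 0 ms rates 1).

## Numerical and testing choices

Determinism: every stochastic entry point takes an explicit seed;
per-participant and per-trial seeds are derived arithmetically from it.
Episode and interval logic uses half-open intervals throughout; the
simulator's grid is 1 ms. The serial-experience implementation is
event-driven over supra-threshold intervals and is verified in the tests
against an independent per-time-step occupancy automaton on a thousand
random piecewise-linear trace sets; the monotone-region estimator is
verified against the 2/n! closed form and against an axis-factorized
computation $P(\text{mono}) = \sum_\pi P_1(\pi)[P_2(\pi) + P_2(\pi^R)]$
that samples each axis separately. Test problem sizes (50 simulated
participants at 200 trials per lag for recovery; 500 trials per lag for the
simulator's behavioural pattern; $10^5$–$10^6$ Monte Carlo draws) were
chosen so that every tolerance is a small multiple of the corresponding
Monte Carlo or sampling error.

## Known limitations

The engine treats cells as independent binomials; overdispersion or
within-session drift in real data would make individual Bayes factors
overconfident. The grouped Bayes factor assumes independent participants
and is reported with, not protected by, its homogeneity summary. The
empirical-reduction rule scores constraints singly; a strongly correlated
pair of constraints could survive or fall together where a joint search
would behave differently. STST-lite is a caricature tuned for the
qualitative dissociation; its parameter values have no committed
physiological interpretation, and regimes such as lag-1 visibility sparing
(observed in some tasks) are outside its default parameter neighbourhood.
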