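#' Parameters of the STST-lite / serial-experience simulator
#'
#' STST-lite is a deliberately small discrete-time stand-in for the
#' neural-STST architecture: one aggregate activation trace per stream item,
#' produced by an input pulse, backward-dominant masking, a leaky
#' self-excited item stage and a task-salience filter; a transient attention
#' "blaster" that multiplies the stimulus drive when a target is detected and
#' is suppressed while any tokenisation is in progress; and a serial
#' tokenisation stage whose completion defines working-memory encoding
#' (report accuracy). Subjective visibility is read out separately by the
#' serial-experience rule ([serial_experience()]): experienced time is time
#' above the subjectivity threshold while no other item occupies experience.
#'
#' All amplitudes are in arbitrary trace units; times in ms. The defaults are
#' calibrated so that, noise-free: a lone target is encoded and experienced;
#' two targets at lag 3 show the blink (T2 not encoded, the blaster being
#' suppressed during T1's tokenisation); and two targets at lag 1 show
#' sparing through joint encoding within the blaster window — while T2's
#' experienced duration at lag 1 stays short because T1 occupies experience
#' first.
#'
#' @param dt Time step (ms).
#' @param soa Stimulus onset asynchrony (ms); 90 in the colour-marked task,
#'   83 in the replication.
#' @param pulse_duration Duration of an item's input pulse (ms); longer than
#'   the SOA so successive items overlap and mask one another.
#' @param mask_forward_inhibition,mask_lateral_inhibition Gains of backward
#'   masking by the next item and of weaker lateral masking among other
#'   concurrent items (lateral must be below forward).
#' @param item_decay,item_self_excitation Leak and self-excitation rates of
#'   the item stage (per ms); their difference is the effective leak.
#' @param input_gain Drive-to-activation scale.
#' @param target_salience_gain,distractor_suppression Task-filter gains for
#'   targets and distractors.
#' @param detection_threshold Trace level at which a target is "detected" and
#'   the blaster may fire.
#' @param blaster_gain Multiplicative enhancement of stimulus drive while the
#'   blaster is active.
#' @param blaster_duration Blaster window (ms).
#' @param encoding_threshold Trace level required to start (and sustain)
#'   tokenisation.
#' @param token_base_duration Tokenisation time (ms, several hundred) at a
#'   trace sitting exactly at the encoding threshold; binding progress
#'   accrues faster for stronger traces.
#' @param token_speedup Gain on the binding rate per unit of relative trace
#'   strength above the encoding threshold (more active items bind faster).
#' @param token_min_duration Floor on tokenisation time (ms); caps the
#'   speed-up.
#' @param max_tokens Concurrent tokenisation limit; 2 permits the lag-1
#'   joint encoding.
#' @param subjectivity_threshold Trace level above which an item can be
#'   consciously experienced.
#' @param visibility_duration_cuts Five increasing experienced-duration cut
#'   points (ms) mapping experience to the 1-6 rating scale.
#' @param input_strength_mean,input_strength_sd Mean and multiplicative
#'   Gaussian noise sd of per-item input strength on noisy trials.
#' @param distractors_experienced Can distractor traces claim an experience
#'   episode? (They rarely exceed the threshold either way.)
#' @param trial_tail Simulated time after the last stream onset (ms).
#' @return A validated `sese_params` list.
#' @export
sese_params <- function(dt = 1,
                        soa = 90,
                        pulse_duration = 110,
                        mask_forward_inhibition = 0.5,
                        mask_lateral_inhibition = 0.2,
                        item_decay = 0.010,
                        item_self_excitation = 0.008,
                        input_gain = 0.02,
                        target_salience_gain = 1,
                        distractor_suppression = 0.15,
                        detection_threshold = 0.55,
                        blaster_gain = 2.5,
                        blaster_duration = 150,
                        encoding_threshold = 1.6,
                        token_base_duration = 450,
                        token_speedup = 2,
                        token_min_duration = 250,
                        max_tokens = 2,
                        subjectivity_threshold = 1.3,
                        visibility_duration_cuts = c(50, 120, 200, 300, 420),
                        input_strength_mean = 1,
                        input_strength_sd = 0.25,
                        distractors_experienced = TRUE,
                        trial_tail = 800) {
  p <- as.list(environment())
  if (p$dt <= 0) abort("`dt` must be positive.")
  if (p$subjectivity_threshold <= 0) {
    abort("`subjectivity_threshold` must be positive.")
  }
  if (p$mask_lateral_inhibition >= p$mask_forward_inhibition) {
    abort("Lateral masking must be weaker than forward masking.")
  }
  if (p$item_decay <= p$item_self_excitation) {
    abort("`item_decay` must exceed `item_self_excitation` (net leak > 0).")
  }
  if (p$token_base_duration < 200) {
    abort("`token_base_duration` must be at least 200 ms.")
  }
  cuts <- p$visibility_duration_cuts
  if (length(cuts) != 5 || any(diff(cuts) <= 0)) {
    abort("`visibility_duration_cuts` must be five strictly increasing values.")
  }
  structure(p, class = "sese_params")
}

#' @export
print.sese_params <- function(x, ...) {
  cat("<sese_params> soa", x$soa, "ms, dt", x$dt, "ms\n")
  cat("  thresholds: detect", x$detection_threshold,
      "| encode", x$encoding_threshold,
      "| subjectivity", x$subjectivity_threshold, "\n")
  cat("  blaster: gain", x$blaster_gain, "for", x$blaster_duration, "ms;",
      "token", x$token_base_duration, "ms base\n")
  invisible(x)
}
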