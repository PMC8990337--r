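#' Configuration for the synthetic delayed-response dataset
#'
#' Bundles every knob of the trial simulator into a validated list. The
#' defaults describe a small but realistic anterior-lateral-motor-cortex-like
#' population: a sample epoch (1.4 s) in which the instruction is presented,
#' a delay epoch (1.2 s) during which selective preparatory activity ramps
#' up, and a response epoch (1.5 s) initiated by an auditory go cue. Units
#' combine a baseline rate, a non-selective ramp, a lick-direction-selective
#' ramp, and a transient go-cue response modelled as a causal alpha-function
#' kernel with a planted latency. A single multiplicative gain, shared by all
#' units within a trial, couples delay-epoch and response-epoch amplitudes
#' trial by trial.
#'
#' @param n_animals,sessions_per_animal,neurons_per_session,n_trials_per_type
#'   Counts defining the animal -> session -> trial hierarchy. `n_trials_per_type`
#'   is the number of trials per lick direction and session.
#' @param epoch_durations Named numeric vector with elements `sample`, `delay`,
#'   `response`, in seconds.
#' @param pre_trial_s Seconds of simulated baseline before the sample onset
#'   (must cover the 0.6 s pre-trial window used by the ramping direction).
#' @param baseline_rate_range Range (spikes/s) of per-unit baseline rates.
#' @param ramp_amplitude_range Range (spikes/s) of the non-selective,
#'   condition-invariant delay ramp amplitude.
#' @param sel_amplitude_range Range (spikes/s) of the selective ramp amplitude
#'   for delay-selective units.
#' @param selectivity_fraction Probability that a unit is delay-selective.
#' @param go_amp_range Range (spikes/s) of go-cue response amplitudes for
#'   cue-responsive units.
#' @param go_down_fraction Probability that a cue-responsive unit decreases
#'   its rate after the cue (go-down cell).
#' @param condition_invariant_fraction Fraction of units carrying a go-cue
#'   response (the condition-invariant post-cue component).
#' @param resp_sel_fraction Fraction of units with sustained, lick-direction
#'   selective response-epoch activity; drawn independently of delay
#'   selectivity, this plants a response-selectivity pattern linearly
#'   independent of the delay pattern (rank-2 selectivity structure).
#' @param resp_sel_amp_range Range (spikes/s) of the sustained
#'   response-epoch selective amplitude.
#' @param resp_sel_mod_range Range of the dimensionless direction modulation
#'   of the cue transient itself (small: the cue response is near
#'   condition-invariant; sign drawn at random per unit).
#' @param resp_decay_tau,resp_rise_tau Decay and rise time constants (s) of
#'   the sustained response-epoch profile.
#' @param latency_mean_ms,latency_sd_ms Mean and s.d. (ms) of planted go-cue
#'   latencies; per-area offsets can be passed via `latency_mean_ms` when
#'   simulating several areas.
#' @param go_kernel_tau Time constant (s) of the alpha-function cue kernel.
#' @param ramp_decay_tau Time constant (s) of the post-cue decay of the delay
#'   ramp (preparatory activity collapses after the cue).
#' @param gain_sd Dispersion of the trial gain `g ~ lognormal(0, gain_sd)`,
#'   shared across units within a trial. Zero disables trial-gain coupling.
#' @param p_no_response,p_incorrect,p_early_lick Outcome probabilities.
#' @param no_response_gain Multiplier applied to the trial gain in
#'   no-response trials (attenuated preparatory and response activity).
#' @param p_stim,p_go_omitted Fractions of trials carrying an optogenetic
#'   stimulation, or with the go cue omitted (no cue kernel).
#' @param perturbation_scale Multiplier on the cue-response amplitude in
#'   stimulation trials.
#' @param quality_fail_fraction Fraction of units whose (simulated) sorting
#'   quality metrics are planted to fail exactly one quality criterion.
#' @param area Area label stamped on every unit.
#' @param kinematic_noise_sd Sample-to-sample noise s.d. of kinematic traces
#'   (trace units; movement amplitude is 1).
#' @param kinematic_onset_ms Planted movement onset (ms after the go cue).
#' @param tongue_jitter_ms Mean of the exponential jitter added to the tongue
#'   detection time on lick trials.
#' @param seed Master seed; fixes the whole dataset bit-for-bit.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 2,
                       sessions_per_animal = 2,
                       neurons_per_session = 50,
                       n_trials_per_type = 50,
                       epoch_durations = c(sample = 1.4, delay = 1.2, response = 1.5),
                       pre_trial_s = 0.8,
                       baseline_rate_range = c(2, 10),
                       ramp_amplitude_range = c(0, 6),
                       sel_amplitude_range = c(4, 12),
                       selectivity_fraction = 0.5,
                       go_amp_range = c(5, 25),
                       go_down_fraction = 0.25,
                       condition_invariant_fraction = 0.6,
                       resp_sel_fraction = 0.5,
                       resp_sel_amp_range = c(4, 12),
                       resp_sel_mod_range = c(0.05, 0.2),
                       resp_rise_tau = 0.05,
                       resp_decay_tau = 0.6,
                       latency_mean_ms = 20,
                       latency_sd_ms = 6,
                       go_kernel_tau = 0.015,
                       ramp_decay_tau = 0.15,
                       gain_sd = 0.2,
                       p_no_response = 0.1,
                       p_incorrect = 0.1,
                       p_early_lick = 0.05,
                       no_response_gain = 0.4,
                       p_stim = 0,
                       p_go_omitted = 0,
                       perturbation_scale = 1,
                       quality_fail_fraction = 0,
                       area = "ALM",
                       kinematic_noise_sd = 0.15,
                       kinematic_onset_ms = 64,
                       tongue_jitter_ms = 30,
                       seed = 1L) {
  cfg <- list(
    n_animals = check_count(n_animals, "n_animals"),
    sessions_per_animal = check_count(sessions_per_animal, "sessions_per_animal"),
    neurons_per_session = check_count(neurons_per_session, "neurons_per_session"),
    n_trials_per_type = check_count(n_trials_per_type, "n_trials_per_type"),
    epoch_durations = epoch_durations,
    pre_trial_s = pre_trial_s,
    baseline_rate_range = baseline_rate_range,
    ramp_amplitude_range = ramp_amplitude_range,
    sel_amplitude_range = sel_amplitude_range,
    selectivity_fraction = check_prob(selectivity_fraction, "selectivity_fraction"),
    go_amp_range = go_amp_range,
    go_down_fraction = check_prob(go_down_fraction, "go_down_fraction"),
    condition_invariant_fraction =
      check_prob(condition_invariant_fraction, "condition_invariant_fraction"),
    resp_sel_fraction = check_prob(resp_sel_fraction, "resp_sel_fraction"),
    resp_sel_amp_range = resp_sel_amp_range,
    resp_sel_mod_range = resp_sel_mod_range,
    resp_rise_tau = resp_rise_tau,
    resp_decay_tau = resp_decay_tau,
    latency_mean_ms = latency_mean_ms,
    latency_sd_ms = latency_sd_ms,
    go_kernel_tau = go_kernel_tau,
    ramp_decay_tau = ramp_decay_tau,
    gain_sd = gain_sd,
    p_no_response = check_prob(p_no_response, "p_no_response"),
    p_incorrect = check_prob(p_incorrect, "p_incorrect"),
    p_early_lick = check_prob(p_early_lick, "p_early_lick"),
    no_response_gain = no_response_gain,
    p_stim = check_prob(p_stim, "p_stim"),
    p_go_omitted = check_prob(p_go_omitted, "p_go_omitted"),
    perturbation_scale = perturbation_scale,
    quality_fail_fraction = check_prob(quality_fail_fraction, "quality_fail_fraction"),
    area = area,
    kinematic_noise_sd = kinematic_noise_sd,
    kinematic_onset_ms = kinematic_onset_ms,
    tongue_jitter_ms = tongue_jitter_ms,
    seed = check_seed(seed)
  )
  if (!all(c("sample", "delay", "response") %in% names(cfg$epoch_durations)) ||
      any(cfg$epoch_durations <= 0)) {
    abort("`epoch_durations` must name positive sample/delay/response durations",
          class = "popmodes_error")
  }
  if (cfg$pre_trial_s < 0.6) {
    abort("`pre_trial_s` must be >= 0.6 s (pre-trial baseline window)",
          class = "popmodes_error")
  }
  if (cfg$latency_mean_ms < 0) {
    abort("`latency_mean_ms` must be >= 0", class = "popmodes_error")
  }
  for (rng in c("baseline_rate_range", "ramp_amplitude_range", "sel_amplitude_range",
                "go_amp_range", "resp_sel_amp_range", "resp_sel_mod_range")) {
    r <- cfg[[rng]]
    if (!is.numeric(r) || length(r) != 2 || r[2] < r[1] || r[1] < 0) {
      abort(sprintf("`%s` must be a nonnegative, nondecreasing pair", rng),
            class = "popmodes_error")
    }
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_animals, " animal(s) x ", x$sessions_per_animal,
      " session(s), ", x$neurons_per_session, " units, ",
      2L * x$n_trials_per_type, " trials; seed ", x$seed, "\n", sep = "")
  invisible(x)
}
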