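#' Deterministic firing-rate model of a simulated unit
#'
#' Computes the instantaneous rate (spikes/s) of one simulated unit at times
#' `t` (seconds, relative to the go cue) in one trial:
#'
#' \deqn{r(t) = \max\{0,\; b + g\,(\rho + s d)\,\mathrm{ramp}(t) +
#'   g\,a\,P\,K(t - L)\,(1 + c d) + g\,u\,d\,S(t)\}}
#'
#' where `b` is the baseline, `g` the trial gain, `rho` the non-selective ramp
#' amplitude, `s` the signed selective ramp amplitude, `d = +1/-1` the lick
#' direction, `a` the signed cue-response amplitude, `c` its (small)
#' direction modulation, `u` the signed sustained response-epoch selective
#' amplitude, `L` the planted cue latency and `P` a perturbation multiplier.
#' `ramp(t)` is 0 before delay onset, rises linearly to 1 at the go cue, and
#' decays exponentially afterwards (preparatory activity collapses once the
#' movement is initiated). `K(x) = (x/\tau) e^{1 - x/\tau}` for `x >= 0` (else
#' 0) is a causal alpha-function kernel with unit peak at `x = \tau`.
#' `S(t) = (1 - e^{-t/\tau_r}) e^{-t/\tau_d}` for `t >= 0` is the sustained
#' response-epoch profile, carrying the direction-selective activity during
#' licking; it is absent (like `K`) in go-cue-omitted trials.
#'
#' @param unit One row of the per-unit ground-truth table (list or one-row
#'   data frame) with fields `baseline_rate`, `ramp_amp`, `sel_amp`,
#'   `go_amp`, `go_latency_ms`, `resp_sel_mod`, `resp_sel_amp`.
#' @param trial One row of the per-trial ground-truth table with fields
#'   `direction` (+1/-1), `gain`, `perturbation`, `delay_on_rel` (delay onset
#'   in seconds relative to the go cue, negative).
#' @param t Numeric vector of times (s, relative to the go cue).
#' @param go_kernel_tau,ramp_decay_tau Kernel and post-cue decay time
#'   constants (s).
#' @param resp_rise_tau,resp_decay_tau Time constants (s) of the sustained
#'   response-epoch profile.
#' @param perturbation_scale Multiplier on the cue response in stimulation
#'   trials.
#'
#' @return Numeric vector of rates (spikes/s), same length as `t`.
#' @export
rate_function <- function(unit, trial, t,
                          go_kernel_tau = 0.015,
                          ramp_decay_tau = 0.15,
                          resp_rise_tau = 0.05,
                          resp_decay_tau = 0.6,
                          perturbation_scale = 1) {
  delay_on <- trial$delay_on_rel %||% -1.2
  ramp <- ramp_profile(t, delay_on, ramp_decay_tau)
  kern <- cue_kernel(t, unit$go_latency_ms, go_kernel_tau)
  resp <- resp_profile(t, resp_rise_tau, resp_decay_tau)
  pert <- switch(as.character(trial$perturbation %||% "none"),
                 go_omitted = 0,
                 stimulation = perturbation_scale,
                 1)
  omitted <- identical(as.character(trial$perturbation %||% "none"), "go_omitted")
  d <- trial$direction
  g <- trial$gain
  a <- if (is.na(unit$go_amp)) 0 else unit$go_amp
  u <- unit$resp_sel_amp %||% 0
  drive <- unit$baseline_rate +
    g * (unit$ramp_amp + unit$sel_amp * d) * ramp +
    g * a * pert * kern * (1 + unit$resp_sel_mod * d) +
    g * u * d * (if (omitted) 0 else 1) * resp
  pmax(0, drive)
}

resp_profile <- function(t, rise_tau, decay_tau) {
  out <- numeric(length(t))
  post <- t >= 0
  out[post] <- (1 - exp(-t[post] / rise_tau)) * exp(-t[post] / decay_tau)
  out
}

ramp_profile <- function(t, delay_on, decay_tau) {
  out <- numeric(length(t))
  rising <- t >= delay_on & t < 0
  out[rising] <- (t[rising] - delay_on) / (-delay_on)
  post <- t >= 0
  out[post] <- exp(-t[post] / decay_tau)
  out
}

cue_kernel <- function(t, latency_ms, tau) {
  if (is.null(latency_ms) || is.na(latency_ms)) return(numeric(length(t)))
  x <- t - latency_ms / 1000
  out <- numeric(length(t))
  pos <- x >= 0
  out[pos] <- (x[pos] / tau) * exp(1 - x[pos] / tau)
  out
}

sample_unit_truth <- function(cfg, n) {
  ru <- function(rng, n) runif(n, rng[1], rng[2])
  selective <- runif(n) < cfg$selectivity_fraction
  sel_sign <- ifelse(selective, sample(c(-1, 1), n, replace = TRUE), 0)
  sel_amp <- ifelse(selective, ru(cfg$sel_amplitude_range, n) * sel_sign, 0)
  cue <- runif(n) < cfg$condition_invariant_fraction
  go_sign <- ifelse(runif(n) < cfg$go_down_fraction, -1, 1)
  go_amp <- ifelse(cue, ru(cfg$go_amp_range, n) * go_sign, 0)
  go_lat <- ifelse(cue, pmax(0, rnorm(n, cfg$latency_mean_ms, cfg$latency_sd_ms)), NA_real_)
  resp_mod <- ifelse(cue,
                     ru(cfg$resp_sel_mod_range, n) * sample(c(-1, 1), n, replace = TRUE),
                     0)
  resp_sel <- runif(n) < cfg$resp_sel_fraction
  resp_amp <- ifelse(resp_sel,
                     ru(cfg$resp_sel_amp_range, n) * sample(c(-1, 1), n, replace = TRUE),
                     0)
  tibble::tibble(
    unit_id = sprintf("u%03d", seq_len(n)),
    baseline_rate = ru(cfg$baseline_rate_range, n),
    selectivity_sign = as.integer(sel_sign),
    sel_amp = sel_amp,
    ramp_amp = ru(cfg$ramp_amplitude_range, n),
    go_amp = go_amp,
    go_latency_ms = go_lat,
    resp_sel_mod = resp_mod,
    resp_sel_amp = resp_amp
  )
}

# Quality metrics are drawn independently of the firing model; a planted
# fraction of units fails exactly one criterion (cycling through all six) so
# the filter logic can be tested against known flags.
sample_unit_metadata <- function(cfg, n) {
  meta <- tibble::tibble(
    unit_id = sprintf("u%03d", seq_len(n)),
    area_label = cfg$area,
    depth_um = runif(n, 700, 1100),
    spike_width_ms = runif(n, 0.55, 1.1),
    amplitude_uv = runif(n, 120, 400),
    isi_violation = runif(n, 0, 0.3),
    amplitude_cutoff = runif(n, 0, 0.08),
    snr = runif(n, 3, 8),
    presence_ratio = runif(n, 0.96, 1),
    x_um = runif(n, 0, 1000),
    y_um = runif(n, 0, 1000)
  )
  n_fail <- round(cfg$quality_fail_fraction * n)
  planted_pass <- rep(TRUE, n)
  if (n_fail > 0) {
    fail_idx <- sample.int(n, n_fail)
    planted_pass[fail_idx] <- FALSE
    bad <- list(
      amplitude_uv = 80, isi_violation = 0.7, amplitude_cutoff = 0.2,
      snr = 1.5, spike_width_ms = 1.4, presence_ratio = 0.8
    )
    which_metric <- names(bad)[(seq_len(n_fail) - 1L) %% length(bad) + 1L]
    for (i in seq_len(n_fail)) {
      meta[[which_metric[i]]][fail_idx[i]] <- bad[[which_metric[i]]]
    }
  }
  list(meta = meta, planted_pass = planted_pass)
}

sample_trials <- function(cfg, n_trials = 2L * cfg$n_trials_per_type) {
  stopifnot(n_trials %% 2 == 0)
  type <- sample(rep(c("lick_right", "lick_left"), each = n_trials / 2))
  u <- runif(n_trials)
  outcome <- rep("correct", n_trials)
  p1 <- cfg$p_early_lick
  p2 <- p1 + (1 - p1) * cfg$p_no_response
  p3 <- p2 + (1 - p2) * cfg$p_incorrect
  outcome[u < p3] <- "incorrect"
  outcome[u < p2] <- "no_response"
  outcome[u < p1] <- "early_lick"
  v <- runif(n_trials)
  perturbation <- rep("none", n_trials)
  perturbation[v < cfg$p_stim] <- "stimulation"
  perturbation[v >= cfg$p_stim & v < cfg$p_stim + cfg$p_go_omitted] <- "go_omitted"
  gain <- if (cfg$gain_sd > 0) rlnorm(n_trials, 0, cfg$gain_sd) else rep(1, n_trials)
  gain[outcome == "no_response"] <- gain[outcome == "no_response"] * cfg$no_response_gain
  direction <- ifelse(type == "lick_right", 1, -1)
  direction[outcome == "incorrect"] <- -direction[outcome == "incorrect"]

  ep <- cfg$epoch_durations
  spacing <- cfg$pre_trial_s + sum(ep) + 0.5
  start <- (seq_len(n_trials) - 1) * spacing
  t_sample_on <- start + cfg$pre_trial_s
  t_delay_on <- t_sample_on + ep[["sample"]]
  t_go <- t_delay_on + ep[["delay"]]

  licked <- outcome %in% c("correct", "incorrect") & perturbation != "go_omitted"
  lick_lat <- (cfg$kinematic_onset_ms + rexp(n_trials, 1 / cfg$tongue_jitter_ms)) / 1000
  first_lick_time <- ifelse(licked, t_go + lick_lat, NA_real_)
  first_lick_time[outcome == "early_lick"] <-
    t_delay_on[outcome == "early_lick"] + runif(sum(outcome == "early_lick")) * ep[["delay"]]
  first_lick_direction <- ifelse(licked, ifelse(direction > 0, "right", "left"), NA_character_)

  tibble::tibble(
    trial_index = seq_len(n_trials), type, outcome, perturbation,
    t_sample_on, t_delay_on, t_go, first_lick_time, first_lick_direction,
    gain, direction
  )
}

#' Planted mode directions implied by the ground truth
#'
#' Evaluates the generator's noise-free rate model for both lick directions
#' (unit gain, no perturbation) and returns, per unit, the planted
#' delay-window and response-window selectivity patterns (right-minus-left
#' window means). These are the reference directions for mode-recovery
#' checks; `response_orth` is the response pattern Gram-Schmidt
#' orthogonalized to the delay pattern, matching the estimated
#' `CD_response` convention.
#'
#' @param truth_units Per-unit ground-truth tibble from [simulate_session()].
#' @param config The [sim_config()] used.
#' @param delay_window,response_window Averaging windows (s relative to cue).
#' @return Tibble: `unit_id`, `delay`, `response`, `response_orth`.
#' @export
planted_mode_patterns <- function(truth_units, config,
                                  delay_window = c(-0.6, 0),
                                  response_window = c(0, 0.4)) {
  grid_d <- seq(delay_window[1], delay_window[2] - 1e-4, by = 1e-3) + 5e-4
  grid_r <- seq(response_window[1], response_window[2] - 1e-4, by = 1e-3) + 5e-4
  delay_on <- -config$epoch_durations[["delay"]]
  one <- function(u, d, t) {
    rate_function(u, list(direction = d, gain = 1, perturbation = "none",
                          delay_on_rel = delay_on), t,
                  go_kernel_tau = config$go_kernel_tau,
                  ramp_decay_tau = config$ramp_decay_tau,
                  resp_rise_tau = config$resp_rise_tau,
                  resp_decay_tau = config$resp_decay_tau)
  }
  pat <- purrr::map_dfr(seq_len(nrow(truth_units)), function(i) {
    u <- truth_units[i, ]
    tibble::tibble(
      unit_id = u$unit_id,
      delay = mean(one(u, 1, grid_d) - one(u, -1, grid_d)),
      response = mean(one(u, 1, grid_r) - one(u, -1, grid_r))
    )
  })
  dnorm2 <- sum(pat$delay^2)
  if (dnorm2 > 0) {
    pd <- pat$delay / sqrt(dnorm2)
    pat$response_orth <- pat$response - sum(pat$response * pd) * pd
  } else {
    pat$response_orth <- pat$response
  }
  pat
}

#' Simulate one recording session
#'
#' Draws spikes from an inhomogeneous Poisson process (1 ms Bernoulli
#' thinning of [rate_function()]) for every unit and trial, together with
#' trial events, outcomes, perturbation labels and unit quality metadata.
#'
#' @param config A [sim_config()].
#' @param animal_id,session_id Identity labels.
#' @param seed Session seed (defaults to `config$seed`).
#'
#' @return A list with `session` (a `session_data` object) and
#'   `ground_truth` (list of per-unit and per-trial planted-parameter
#'   tibbles).
#' @export
simulate_session <- function(config, animal_id = "animal01",
                             session_id = "session01", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  seed <- check_seed(seed)
  withr::with_seed(seed, {
    n_units <- config$neurons_per_session
    n_trials <- 2L * config$n_trials_per_type
    truth_units <- sample_unit_truth(config, n_units)
    md <- sample_unit_metadata(config, n_units)
    trials_full <- sample_trials(config, n_trials)

    ep <- config$epoch_durations
    t0 <- -(config$pre_trial_s + ep[["sample"]] + ep[["delay"]])
    t1 <- ep[["response"]]
    bin <- 0.001
    grid <- seq(t0, t1 - bin, by = bin) # bin left edges
    n_bins <- length(grid)
    delay_on <- -ep[["delay"]]
    ramp <- ramp_profile(grid + bin / 2, delay_on, config$ramp_decay_tau)
    resp <- resp_profile(grid + bin / 2, config$resp_rise_tau, config$resp_decay_tau)

    pert_mult <- ifelse(trials_full$perturbation == "go_omitted", 0,
                        ifelse(trials_full$perturbation == "stimulation",
                               config$perturbation_scale, 1))
    spikes <- vector("list", n_units)
    for (i in seq_len(n_units)) {
      u <- truth_units[i, ]
      kern <- cue_kernel(grid + bin / 2, u$go_latency_ms, config$go_kernel_tau)
      ramp_amp_tr <- trials_full$gain * (u$ramp_amp + u$sel_amp * trials_full$direction)
      go_amp_tr <- trials_full$gain * ifelse(is.na(u$go_amp), 0, u$go_amp) *
        pert_mult * (1 + u$resp_sel_mod * trials_full$direction)
      resp_amp_tr <- trials_full$gain * u$resp_sel_amp * trials_full$direction *
        (trials_full$perturbation != "go_omitted")
      rate <- u$baseline_rate +
        outer(ramp, ramp_amp_tr) + outer(kern, go_amp_tr) + outer(resp, resp_amp_tr)
      rate[rate < 0] <- 0
      p <- rate * bin
      p[p > 1] <- 1
      hit <- matrix(runif(n_bins * n_trials), n_bins, n_trials) < p
      idx <- which(hit, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        rel <- grid[idx[, 1]] + runif(nrow(idx)) * bin
        abs_time <- trials_full$t_go[idx[, 2]] + rel
        spikes[[i]] <- tibble::tibble(unit_id = truth_units$unit_id[i],
                                      spike_time = sort(abs_time))
      }
    }
    spikes <- dplyr::bind_rows(spikes)
    if (nrow(spikes) == 0) {
      spikes <- tibble::tibble(unit_id = character(), spike_time = numeric())
    }

    trials <- dplyr::select(trials_full, -"gain", -"direction")
    session <- new_session_data(
      animal_id = animal_id, session_id = session_id,
      units = md$meta, spikes = spikes, trials = trials
    )
    truth_units$planted_quality_pass <- md$planted_pass
    truth_trials <- dplyr::select(
      trials_full, "trial_index", "type", "outcome", "perturbation",
      "gain", "direction"
    )
    truth_trials$delay_on_rel <- delay_on
    list(session = session,
         ground_truth = list(units = truth_units, trials = truth_trials))
  })
}

#' Simulate a hierarchical multi-session dataset
#'
#' Generates `n_animals x sessions_per_animal` sessions with per-session
#' seeds derived deterministically from the master seed, preserving the
#' animal -> session -> trial hierarchy needed by the hierarchical bootstrap.
#'
#' @param config A [sim_config()].
#' @return A list of class `dataset_bundle` with named elements `sessions`
#'   and `ground_truth` (both keyed `"<animal>/<session>"`) plus the config.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- config$n_animals * config$sessions_per_animal
  seeds <- derive_seeds(config$seed, n_total)
  sessions <- list()
  truth <- list()
  k <- 0L
  for (a in seq_len(config$n_animals)) {
    for (s in seq_len(config$sessions_per_animal)) {
      k <- k + 1L
      aid <- sprintf("animal%02d", a)
      sid <- sprintf("session%02d", s)
      sim <- simulate_session(config, aid, sid, seed = seeds[k])
      key <- paste(aid, sid, sep = "/")
      sessions[[key]] <- sim$session
      truth[[key]] <- sim$ground_truth
    }
  }
  structure(list(sessions = sessions, ground_truth = truth, config = config),
            class = "dataset_bundle")
}

#' Simulate kinematic traces and tongue detection times
#'
#' Jaw and nose traces are Gaussian noise plus a slow linear drift, with a
#' causal saturating ("sigmoidal") displacement starting at the planted onset
#' on movement trials, sampled at 400 Hz. The tongue detection time is the
#' planted onset plus exponential jitter on lick trials, absent otherwise.
#'
#' @param config A [sim_config()].
#' @param trials A trial table (as in a `session_data`) with `t_go`,
#'   `outcome` and `perturbation` columns.
#' @param seed RNG seed.
#' @param window Trace window (s, relative to the go cue).
#'
#' @return List with `traces` (tibble: trial_index, time, jaw, nose),
#'   `tongue` (tibble: trial_index, detect_time_ms; `NA` when undetected) and
#'   `onset_ms` (the planted onset).
#' @export
simulate_kinematics <- function(config, trials, seed = config$seed,
                                window = c(-0.7, 1.0)) {
  stopifnot(inherits(config, "sim_config"))
  seed <- check_seed(seed)
  withr::with_seed(seed, {
    fs <- 400
    time <- seq(window[1], window[2], by = 1 / fs)
    n_t <- length(time)
    onset <- config$kinematic_onset_ms / 1000
    moves <- trials$outcome %in% c("correct", "incorrect") &
      trials$perturbation != "go_omitted"
    rise <- function(t, amp) {
      out <- numeric(length(t))
      post <- t >= onset
      out[post] <- amp * (1 - exp(-(t[post] - onset) / 0.02))
      out
    }
    traces <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
      drift <- rnorm(1, 0, 0.05) * (time - time[1])
      jaw <- rnorm(n_t, 0, config$kinematic_noise_sd) + drift
      nose <- rnorm(n_t, 0, config$kinematic_noise_sd) + rnorm(1, 0, 0.05) * (time - time[1])
      if (moves[i]) {
        jaw <- jaw + rise(time, 1)
        nose <- nose + rise(time, 0.6)
      }
      tibble::tibble(trial_index = trials$trial_index[i], time = time,
                     jaw = jaw, nose = nose)
    })
    licked <- moves
    detect <- ifelse(licked,
                     config$kinematic_onset_ms + rexp(nrow(trials), 1 / config$tongue_jitter_ms),
                     NA_real_)
    list(
      traces = traces,
      tongue = tibble::tibble(trial_index = trials$trial_index,
                              detect_time_ms = detect),
      onset_ms = config$kinematic_onset_ms
    )
  })
}
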