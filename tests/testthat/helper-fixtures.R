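# Shared fixtures, all built in code.

# Hand-constructed two-unit session: spikes placed deterministically.
toy_session <- function() {
  trials <- tibble::tibble(
    trial_index = 1:4,
    type = c("lick_right", "lick_left", "lick_right", "lick_left"),
    outcome = "correct",
    perturbation = "none",
    t_sample_on = c(1, 11, 21, 31),
    t_delay_on = c(2.4, 12.4, 22.4, 32.4),
    t_go = c(3.6, 13.6, 23.6, 33.6),
    first_lick_time = c(3.7, 13.7, 23.7, 33.7),
    first_lick_direction = c("right", "left", "right", "left")
  )
  units <- tibble::tibble(
    unit_id = c("a", "b"), area_label = "ALM", depth_um = 900,
    spike_width_ms = 0.8, amplitude_uv = 200, isi_violation = 0.1,
    amplitude_cutoff = 0.01, snr = 5, presence_ratio = 1,
    x_um = c(100, 200), y_um = c(100, 200)
  )
  spikes <- tibble::tibble(
    unit_id = c("a", "a", "b"),
    spike_time = c(3.6555, 23.6555, 13.6555)
  )
  new_session_data("animalA", "session1", units, spikes, trials)
}

# Small simulated session cached per test file run.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_animals = 1, sessions_per_animal = 1,
                        neurons_per_session = 30, n_trials_per_type = 30,
                        seed = 101)
      cache <<- c(simulate_session(cfg), list(config = cfg))
    }
    cache
  }
})

# Ideal quality metrics row
ideal_unit <- function(unit_id = "u1", spike_width_ms = 0.8) {
  tibble::tibble(
    unit_id = unit_id, spike_width_ms = spike_width_ms, amplitude_uv = 300,
    isi_violation = 0.1, amplitude_cutoff = 0.01, snr = 6, presence_ratio = 0.99
  )
}

random_mode <- function(n, kind = "custom", ids = sprintf("u%02d", seq_len(n))) {
  v <- rnorm(n)
  popmodes:::new_mode_vector(v / sqrt(sum(v^2)), ids, kind)
}

# Minimal psth_matrix wrapper around a given units x bins x 2 array.
manual_psth <- function(rates_right, rates_left, bin_width = 0.01,
                        t0 = -1) {
  n <- nrow(rates_right)
  nb <- ncol(rates_right)
  rates <- array(0, c(n, nb, 2),
                 dimnames = list(sprintf("u%02d", seq_len(n)), NULL,
                                 c("lick_left", "lick_right")))
  rates[, , "lick_right"] <- rates_right
  rates[, , "lick_left"] <- rates_left
  structure(
    list(rates = rates, time = t0 + (seq_len(nb) - 0.5) * bin_width,
         bin_width = bin_width, smoothing = "none", alignment = "t_go",
         conditions = c("lick_left", "lick_right"),
         n_trials = c(lick_left = 10, lick_right = 10),
         unit_ids = sprintf("u%02d", seq_len(n)),
         epochs = c(sample_on = -2.6, delay_on = -1.2)),
    class = "psth_matrix"
  )
}
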