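# Assign each spike of one unit to (trial, bin) given per-trial alignment
# times and a window. Trials' windows must not overlap (guaranteed by the
# task structure). Returns integer matrix columns: trial row index, bin.
align_spikes <- function(spike_times, align_times, window, bin_width) {
  ord <- order(align_times)
  starts <- align_times[ord] + window[1]
  ends <- align_times[ord] + window[2]
  pos <- findInterval(spike_times, starts)
  ok <- pos >= 1
  ok[ok] <- spike_times[ok] < ends[pos[ok]]
  pos <- pos[ok]
  rel <- spike_times[ok] - (starts[pos] - window[1])
  bin <- floor((rel - window[1]) / bin_width) + 1L
  n_bins <- round((window[2] - window[1]) / bin_width)
  keep <- bin >= 1L & bin <= n_bins
  cbind(trial = ord[pos[keep]], bin = bin[keep])
}

#' Compute peri-event time histograms
#'
#' Bins spikes of every unit relative to an alignment event, averages across
#' the selected trials within each condition, and optionally smooths and
#' z-scores the result. Bins are half-open `[t, t + bin)`; `t = 0` is the
#' alignment event (the go cue for peri-cue analyses).
#'
#' Smoothing options follow the two display conventions for this task:
#' a centered 100 ms boxcar for full-epoch views and causal 5 or 10 ms
#' boxcars for peri-cue views (causal so that no post-cue activity leaks
#' into pre-cue bins).
#'
#' Z-scoring standardizes each unit by the mean and s.d. of its per-trial
#' baseline rate in `baseline_window` (default the 100 ms before the cue).
#' Units with zero baseline s.d. cannot be standardized; they are dropped
#' from the z-scored output and listed in attribute `"zscore_excluded"`.
#'
#' @param session A `session_data`.
#' @param trials Trial subset (rows of `session$trials`), e.g. from
#'   [select_trials()].
#' @param align Name of the trial column holding the alignment event time
#'   (default `"t_go"`).
#' @param window Time window (s) relative to the alignment event.
#' @param bin_width Bin width in seconds.
#' @param smoothing One of `"boxcar_centered_100ms"`, `"boxcar_causal_5ms"`,
#'   `"boxcar_causal_10ms"`, `"none"`.
#' @param zscore Standardize each unit by its pre-cue baseline?
#' @param baseline_window Baseline window (s, relative to `align`) for
#'   z-scoring.
#' @param condition_by Trial column defining the conditions (default
#'   `"type"`, i.e. the two lick directions). Use `"perturbation"` for
#'   control/stimulation splits.
#' @param units Optional character vector restricting the units.
#'
#' @return An object of class `psth_matrix`: list with `rates`
#'   (units x bins x conditions array, spikes/s), `time` (bin centers),
#'   `bin_width`, `smoothing`, `alignment`, `conditions`, `n_trials`,
#'   `unit_ids` and `epochs` (median sample/delay onsets relative to the
#'   alignment event).
#' @export
compute_psth <- function(session, trials = NULL, align = "t_go",
                         window = c(-3.2, 1.5), bin_width = 0.01,
                         smoothing = c("boxcar_centered_100ms",
                                       "boxcar_causal_5ms",
                                       "boxcar_causal_10ms", "none"),
                         zscore = FALSE, baseline_window = c(-0.1, 0),
                         condition_by = "type", units = NULL) {
  stopifnot(inherits(session, "session_data"))
  smoothing <- match.arg(smoothing)
  check_window(window)
  if (is.null(trials)) trials <- select_trials(session$trials)
  if (nrow(trials) == 0) {
    abort("compute_psth: zero trials selected", class = "popmodes_error")
  }
  if (!align %in% names(trials)) {
    abort(sprintf("compute_psth: no alignment column `%s`", align),
          class = "popmodes_error")
  }
  unit_ids <- units %||% session$units$unit_id
  conds <- sort(unique(trials[[condition_by]]))
  n_bins <- round((window[2] - window[1]) / bin_width)
  if (n_bins < 1) abort("compute_psth: window narrower than one bin",
                        class = "popmodes_error")
  time <- window[1] + (seq_len(n_bins) - 0.5) * bin_width
  align_times <- trials[[align]]
  cond_of_trial <- match(trials[[condition_by]], conds)
  n_per_cond <- tabulate(cond_of_trial, length(conds))
  if (any(n_per_cond == 0)) {
    abort("compute_psth: a condition has zero trials", class = "popmodes_error")
  }

  spikes_by_unit <- split(session$spikes$spike_time, session$spikes$unit_id)
  rates <- array(0, dim = c(length(unit_ids), n_bins, length(conds)),
                 dimnames = list(unit_ids, NULL, conds))
  for (i in seq_along(unit_ids)) {
    st <- spikes_by_unit[[unit_ids[i]]]
    if (is.null(st) || length(st) == 0) next
    hits <- align_spikes(st, align_times, window, bin_width)
    if (nrow(hits) == 0) next
    for (ci in seq_along(conds)) {
      sel <- cond_of_trial[hits[, "trial"]] == ci
      if (!any(sel)) next
      counts <- tabulate(hits[sel, "bin"], n_bins)
      rates[i, , ci] <- counts / (n_per_cond[ci] * bin_width)
    }
  }
  if (smoothing != "none") {
    for (ci in seq_along(conds)) {
      m <- matrix(rates[, , ci], nrow = length(unit_ids))
      rates[, , ci] <- smooth_rows(m, smoothing, bin_width)
    }
  }

  out <- structure(
    list(rates = rates, time = time, bin_width = bin_width,
         smoothing = smoothing, alignment = align, conditions = conds,
         n_trials = stats::setNames(n_per_cond, conds), unit_ids = unit_ids,
         epochs = c(sample_on = stats::median(trials$t_sample_on - align_times),
                    delay_on = stats::median(trials$t_delay_on - align_times))),
    class = "psth_matrix"
  )
  if (zscore) out <- zscore_psth(out, session, trials, baseline_window)
  out
}

zscore_psth <- function(psth, session, trials, baseline_window) {
  check_window(baseline_window, "baseline_window")
  if (baseline_window[1] < psth$time[1] - psth$bin_width ||
      baseline_window[2] > psth$time[length(psth$time)] + psth$bin_width) {
    abort("z-score baseline window must lie inside the PSTH window",
          class = "popmodes_error")
  }
  rv <- trial_rate_vectors(session, trials, baseline_window,
                           align = psth$alignment, units = psth$unit_ids)
  mu <- colMeans(rv)
  sigma <- apply(rv, 2, stats::sd)
  keep <- sigma > 0
  excluded <- psth$unit_ids[!keep]
  rates <- psth$rates[keep, , , drop = FALSE]
  for (ci in seq_along(psth$conditions)) {
    rates[, , ci] <- (rates[, , ci] - mu[keep]) / sigma[keep]
  }
  psth$rates <- rates
  psth$unit_ids <- psth$unit_ids[keep]
  psth$zscored <- TRUE
  attr(psth, "zscore_excluded") <- excluded
  psth
}

#' @export
print.psth_matrix <- function(x, ...) {
  cat("<psth_matrix> ", length(x$unit_ids), " units x ", length(x$time),
      " bins x ", length(x$conditions), " condition(s); bin ",
      x$bin_width * 1000, " ms; smoothing ", x$smoothing, "\n", sep = "")
  invisible(x)
}

#' @method as_tibble psth_matrix
#' @export
as_tibble.psth_matrix <- function(x, ...) {
  grid <- expand.grid(unit_id = x$unit_ids, time = x$time,
                      condition = x$conditions, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$rate <- as.vector(x$rates)
  tibble::as_tibble(grid)
}

#' Mean rate of every unit in every trial over a window
#'
#' Entry `(trial, unit)` is the spike count of the unit in
#' `[align + w0, align + w1)` divided by the window duration. This is the
#' input to single-trial mode projections.
#'
#' @inheritParams compute_psth
#' @param window Window (s) relative to the alignment event; must be
#'   nonempty.
#' @return Numeric matrix trials x units (spikes/s), rownames the trial
#'   indices, colnames the unit ids.
#' @export
trial_rate_vectors <- function(session, trials, window, align = "t_go",
                               units = NULL) {
  stopifnot(inherits(session, "session_data"))
  check_window(window)
  if (nrow(trials) == 0) {
    abort("trial_rate_vectors: zero trials", class = "popmodes_error")
  }
  unit_ids <- units %||% session$units$unit_id
  align_times <- trials[[align]]
  dur <- window[2] - window[1]
  spikes_by_unit <- split(session$spikes$spike_time, session$spikes$unit_id)
  out <- matrix(0, nrow(trials), length(unit_ids),
                dimnames = list(trials$trial_index, unit_ids))
  for (i in seq_along(unit_ids)) {
    st <- spikes_by_unit[[unit_ids[i]]]
    if (is.null(st) || length(st) == 0) next
    hits <- align_spikes(st, align_times, window, dur)
    if (nrow(hits) == 0) next
    out[, i] <- tabulate(hits[, "trial"], nrow(trials)) / dur
  }
  out
}
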