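#' Movement onset from kinematic traces (detrended 3-sigma rule)
#'
#' For each hierarchical bootstrap draw of trials: average the traces,
#' linearly detrend the mean using its values inside `detrend_window`
#' (the last 0.6 s of the delay epoch), and report the first post-cue sample
#' whose absolute detrended displacement exceeds `k` times the baseline
#' standard deviation (100 ms window before the cue). The mean and s.e.m.
#' over draws are returned.
#'
#' @param traces Numeric matrix trials x samples (one kinematic coordinate),
#'   aligned to the go cue.
#' @param time Sample times (s, relative to the cue); 400 Hz in the standard
#'   protocol.
#' @param hierarchy Optional tibble (one row per trial) with `animal_id` and
#'   `session_id`; when omitted a flat trial bootstrap is used.
#' @param detrend_window Window (s) on which the linear trend is fitted.
#' @param baseline_window_s Length (s) of the pre-cue baseline window.
#' @param k Threshold in baseline s.d. units.
#' @param n_boot Bootstrap iterations.
#' @param seed RNG seed.
#' @return One-row tibble: `onset_ms`, `sem_ms`, `n_detected` (draws with a
#'   crossing), `n_boot`; attribute `"draws"` with per-draw onsets.
#' @export
kinematic_onset <- function(traces, time, hierarchy = NULL,
                            detrend_window = c(-0.6, 0),
                            baseline_window_s = 0.1, k = 3,
                            n_boot = 1000, seed = 1L) {
  stopifnot(is.matrix(traces), length(time) == ncol(traces))
  detrend_idx <- which(time >= detrend_window[1] & time <= detrend_window[2])
  base_idx <- which(time >= -baseline_window_s & time < 0)
  post_idx <- which(time >= 0)
  if (length(detrend_idx) < 2 || length(base_idx) < 2 || length(post_idx) < 1) {
    abort("kinematic_onset: windows not covered by `time`", class = "popmodes_error")
  }
  one_onset <- function(rows) {
    m <- colMeans(traces[rows, , drop = FALSE])
    fit <- stats::lm.fit(cbind(1, time[detrend_idx]), m[detrend_idx])
    detr <- m - (fit$coefficients[1] + fit$coefficients[2] * time)
    sigma <- stats::sd(detr[base_idx])
    # all-flat (or perfectly detrended) baseline: no noise scale to test against
    if (!is.finite(sigma) || sigma <= 1e-10 * max(diff(range(m)), 1e-300)) {
      return(NA_real_)
    }
    hit <- which(abs(detr[post_idx]) > k * sigma)
    if (length(hit) == 0) return(NA_real_)
    time[post_idx[hit[1]]] * 1000
  }
  idx <- if (is.null(hierarchy)) NULL else hier_index(hierarchy)
  draws <- withr::with_seed(check_seed(seed), {
    vapply(seq_len(n_boot), function(i) {
      rows <- if (is.null(idx)) sample.int(nrow(traces), replace = TRUE)
              else resample_hier(idx)
      one_onset(rows)
    }, numeric(1))
  })
  ok <- draws[!is.na(draws)]
  out <- tibble::tibble(
    onset_ms = if (length(ok)) mean(ok) else NA_real_,
    sem_ms = if (length(ok) > 1) stats::sd(ok) else NA_real_,
    n_detected = length(ok), n_boot = n_boot
  )
  attr(out, "draws") <- draws
  out
}

#' Tongue movement onset from detection-time c.d.f. difference
#'
#' The c.d.f. of the first post-cue tongue detection time is computed for
#' the condition of interest and for the null condition (go cue omitted);
#' onset is the first time at which their difference exceeds `threshold`
#' (0.05). Trials without a detection contribute to the denominator only.
#' The s.e.m. comes from a hierarchical bootstrap over both conditions.
#'
#' @param times_ms Detection times (ms after the cue) for the condition of
#'   interest; `NA` = no detection.
#' @param times_null_ms Same for the null condition (may be all `NA` or
#'   empty).
#' @param hierarchy,hierarchy_null Optional per-trial tibbles with
#'   `animal_id`, `session_id` for hierarchical resampling.
#' @param threshold C.d.f.-difference threshold.
#' @param grid_ms Evaluation grid (ms).
#' @param n_boot,seed Bootstrap settings.
#' @return One-row tibble: `onset_ms`, `sem_ms`, `n_detected`, `n_boot`;
#'   attribute `"draws"`.
#' @export
tongue_onset <- function(times_ms, times_null_ms = numeric(),
                         hierarchy = NULL, hierarchy_null = NULL,
                         threshold = 0.05, grid_ms = seq(0, 600, by = 1),
                         n_boot = 1000, seed = 1L) {
  cdf_at <- function(x, n) {
    if (n == 0) return(numeric(length(grid_ms)))
    findInterval(grid_ms, sort(x[!is.na(x)])) / n
  }
  one_onset <- function(x, x_null) {
    d <- cdf_at(x, length(x)) - cdf_at(x_null, length(x_null))
    hit <- which(d > threshold)
    if (length(hit) == 0) return(NA_real_)
    grid_ms[hit[1]]
  }
  point <- one_onset(times_ms, times_null_ms)
  idx <- if (is.null(hierarchy)) NULL else hier_index(hierarchy)
  idx_null <- if (is.null(hierarchy_null)) NULL else hier_index(hierarchy_null)
  draws <- withr::with_seed(check_seed(seed), {
    vapply(seq_len(n_boot), function(i) {
      r1 <- if (is.null(idx)) sample.int(length(times_ms), replace = TRUE)
            else resample_hier(idx)
      x_null <- if (length(times_null_ms) == 0) numeric() else {
        r0 <- if (is.null(idx_null)) sample.int(length(times_null_ms), replace = TRUE)
              else resample_hier(idx_null)
        times_null_ms[r0]
      }
      one_onset(times_ms[r1], x_null)
    }, numeric(1))
  })
  ok <- draws[!is.na(draws)]
  out <- tibble::tibble(
    onset_ms = point,
    boot_mean_ms = if (length(ok)) mean(ok) else NA_real_,
    sem_ms = if (length(ok) > 1) stats::sd(ok) else NA_real_,
    n_detected = length(ok), n_boot = n_boot
  )
  attr(out, "draws") <- draws
  out
}
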