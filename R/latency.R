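# Per-bin significance of pooled counts against the pre-cue baseline.
# "conditional": exact conditional binomial test of one Poisson count vs the
# pooled baseline count (k | k + N ~ Binom(k + N, 1/(B + 1)) under the
# homogeneous null, B = number of baseline bins) -- exact even though the
# baseline rate is estimated. "plugin": exact Poisson tails against
# mu = baseline_rate * n_trials * bin_width, treating the estimate as known.
bin_tails <- function(counts, n_base, n_base_bins, mu, method) {
  if (method == "conditional") {
    p0 <- 1 / (n_base_bins + 1)
    n_tot <- counts + n_base
    list(up = stats::pbinom(counts - 1, n_tot, p0, lower.tail = FALSE),
         down = stats::pbinom(counts, n_tot, p0))
  } else {
    list(up = 1 - stats::ppois(counts - 1, mu),
         down = stats::ppois(counts, mu))
  }
}

#' Two-step Poisson latency of a single neuron's go-cue response
#'
#' Assumes spike generation is Poisson. Spike counts pooled across trials
#' are aggregated into consecutive `test_bin_ms` analysis bins (5 ms by
#' default, the width also used to smooth peri-cue rates) and each bin is
#' tested against the pre-cue baseline rate. The first post-cue bin whose
#' rate is higher or lower than expected at `alpha1 = 0.001` defines
#' `T_p001`; the latency is then the earliest bin of the contiguous run,
#' containing `T_p001`, that is significant in the same direction at
#' `alpha2 = 0.05` -- i.e. the last time point before `T_p001` at which the
#' rate crosses the second significance level. The two-step rule avoids
#' detecting small-amplitude drifts. No crossing at `alpha1` within the
#' search window means the latency is absent. Latencies are reported as the
#' start (left edge) of the detected bin.
#'
#' @param counts Integer vector of spike counts per 1 ms bin, pooled across
#'   trials, covering at least `baseline_window` and `search_window`.
#' @param time Bin left edges (s, relative to the go cue), same length as
#'   `counts`.
#' @param n_trials Number of pooled trials.
#' @param baseline_window Window (s) for the baseline rate estimate.
#' @param search_window Post-cue search window (s); capped at 200 ms by
#'   default.
#' @param alpha1,alpha2 First- and second-step significance levels.
#' @param bin_width Width (s) of the input count bins; 1 ms.
#' @param test_bin_ms Width (ms) of the non-overlapping analysis bins the
#'   counts are aggregated into before testing. 5 ms bounds the familywise
#'   false-positive rate over a 200 ms search window below 5% while keeping
#'   millisecond-scale resolution; set to 1 for per-millisecond tests.
#' @param baseline_method `"conditional"` (default): exact conditional
#'   binomial test of each bin count against the pooled baseline count,
#'   accounting for baseline estimation. `"plugin"`: exact Poisson tails
#'   against the plug-in baseline mean.
#' @param rule `"run"` (default): latency is the start of the contiguous
#'   `alpha2`-significant run ending at `T_p001`. `"literal"`: the latest
#'   bin at or before `T_p001` at which per-bin significance at `alpha2`
#'   switches on. The two readings coincide whenever the run containing
#'   `T_p001` is unbroken, and are compared in the test suite.
#'
#' @return One-row tibble: `latency_ms`, `direction` (`"up"`/`"down"`/`NA`),
#'   `t_p001_ms`, `baseline_rate`, `n_trials`, `reason` (why absent, if so).
#' @export
neuron_go_latency <- function(counts, time, n_trials,
                              baseline_window = c(-0.1, 0),
                              search_window = c(0, 0.2),
                              alpha1 = 0.001, alpha2 = 0.05,
                              bin_width = 0.001, test_bin_ms = 5,
                              baseline_method = c("conditional", "plugin"),
                              rule = c("run", "literal")) {
  rule <- match.arg(rule)
  baseline_method <- match.arg(baseline_method)
  stopifnot(length(counts) == length(time))
  agg <- max(1L, round(test_bin_ms / (bin_width * 1000)))
  base_idx <- which(time >= baseline_window[1] - 1e-12 &
                      time < baseline_window[2] - 1e-12)
  if (length(base_idx) == 0) {
    abort("neuron_go_latency: baseline window not covered", class = "popmodes_error")
  }
  baseline_rate <- sum(counts[base_idx]) /
    (length(base_idx) * bin_width * n_trials)
  search_idx <- which(time >= search_window[1] - 1e-12 &
                        time < search_window[2] - 1e-12 & time >= 0)
  if (length(search_idx) == 0) {
    abort("neuron_go_latency: empty search window", class = "popmodes_error")
  }
  absent <- function(reason) tibble::tibble(
    latency_ms = NA_real_, direction = NA_character_, t_p001_ms = NA_real_,
    baseline_rate = baseline_rate, n_trials = n_trials, reason = reason
  )
  cp <- counts[search_idx]
  n_test <- floor(length(cp) / agg)
  if (n_test == 0) {
    abort("neuron_go_latency: search window narrower than one analysis bin",
          class = "popmodes_error")
  }
  test_counts <- if (agg == 1L) cp[seq_len(n_test)] else
    colSums(matrix(cp[seq_len(n_test * agg)], agg))
  test_time <- time[search_idx[seq(1, n_test * agg, by = agg)]]
  mu <- baseline_rate * n_trials * bin_width * agg
  tails <- bin_tails(test_counts, sum(counts[base_idx]),
                     length(base_idx) / agg, mu, baseline_method)
  sig1_up <- tails$up < alpha1
  sig1_down <- tails$down < alpha1
  first1 <- which(sig1_up | sig1_down)
  if (length(first1) == 0) return(absent("no alpha1 crossing in search window"))
  first1 <- first1[1]
  direction <- if (sig1_up[first1]) "up" else "down"
  if (direction == "down" && baseline_rate == 0) {
    return(absent("zero baseline: down-latency undetectable"))
  }
  sig2 <- if (direction == "up") tails$up < alpha2 else tails$down < alpha2
  # contiguous alpha2-significant run containing T_p001
  run_start <- first1
  while (run_start > 1 && sig2[run_start - 1]) run_start <- run_start - 1
  lat_idx <- if (rule == "run") {
    run_start
  } else {
    onsets <- which(sig2[seq_len(first1)] &
                      !c(FALSE, sig2[seq_len(first1 - 1)]))
    onsets[length(onsets)]
  }
  tibble::tibble(
    latency_ms = test_time[lat_idx] * 1000,
    direction = direction,
    t_p001_ms = test_time[first1] * 1000,
    baseline_rate = baseline_rate, n_trials = n_trials,
    reason = NA_character_
  )
}

#' Pooled 1 ms spike counts of one unit around the go cue
#'
#' Helper binning a unit's spikes at 1 ms across the given trials, aligned
#' to the go cue, as input to [neuron_go_latency()].
#'
#' @param session A `session_data`.
#' @param unit_id Unit to bin.
#' @param trials Trial subset (typically 40 subsampled correct trials per
#'   type from [select_trials()]).
#' @param window Window (s) around the cue.
#' @return List with `counts`, `time` (bin left edges) and `n_trials`.
#' @export
pooled_cue_counts <- function(session, unit_id, trials, window = c(-0.1, 0.2)) {
  bin <- 0.001
  n_bins <- round((window[2] - window[1]) / bin)
  st <- session$spikes$spike_time[session$spikes$unit_id == unit_id]
  counts <- integer(n_bins)
  if (length(st) > 0) {
    hits <- align_spikes(st, trials$t_go, window, bin)
    if (nrow(hits) > 0) counts <- tabulate(hits[, "bin"], n_bins)
  }
  list(counts = counts, time = window[1] + (seq_len(n_bins) - 1L) * bin,
       n_trials = nrow(trials))
}

#' Area-level latency: time when a fraction of cells responds
#'
#' The area latency is the smallest time `t` at which at least `fraction`
#' (default 1%) of all analyzed cells -- non-responders included in the
#' denominator -- have an upward latency `<= t`. The s.e.m. is estimated by
#' bootstrap over cells.
#'
#' @param latencies_ms Numeric vector of per-cell upward latencies (ms),
#'   `NA` for cells without a detected response.
#' @param fraction Required fraction of cells, in (0, 1].
#' @param n_boot Bootstrap iterations over cells.
#' @param seed RNG seed.
#' @return One-row tibble: `latency_ms`, `sem_ms`, `n_cells`, `n_responders`,
#'   plus attribute `"draws"` with the bootstrap latencies.
#' @export
area_latency <- function(latencies_ms, fraction = 0.01, n_boot = 1000,
                         seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction <= 0 ||
      fraction > 1) {
    abort("`fraction` must be in (0, 1]", class = "popmodes_error")
  }
  point <- area_latency_point(latencies_ms, fraction)
  draws <- withr::with_seed(check_seed(seed), {
    vapply(seq_len(n_boot), function(i) {
      area_latency_point(latencies_ms[sample.int(length(latencies_ms),
                                                 replace = TRUE)], fraction)
    }, numeric(1))
  })
  out <- tibble::tibble(
    latency_ms = point,
    sem_ms = stats::sd(draws, na.rm = TRUE),
    n_cells = length(latencies_ms),
    n_responders = sum(!is.na(latencies_ms))
  )
  attr(out, "draws") <- draws
  out
}

area_latency_point <- function(latencies_ms, fraction) {
  n <- length(latencies_ms)
  need <- ceiling(fraction * n)
  lat <- sort(latencies_ms[!is.na(latencies_ms)])
  if (length(lat) < need) return(NA_real_)
  lat[need]
}

#' Threshold-crossing latency of a population projection
#'
#' The projection is standardized by its mean and s.d. in the pre-cue
#' baseline window and smoothed with a causal 10 ms boxcar. `T_std5` is the
#' first post-cue bin where |z| reaches `hi` (5 s.d.); the latency is the
#' earliest bin of the contiguous |z| >= `lo` (2 s.d.) run containing
#' `T_std5`. Absent when the 5 s.d. level is never reached.
#'
#' @param trace A `projection_trace`, or a numeric vector with `time`.
#' @param time Bin centers (s, relative to the cue) when `trace` is numeric.
#' @param condition Condition column used when the trace has several
#'   (default: mean across columns, the convention for `D_go`; for the CD
#'   modes pass the right-minus-left difference).
#' @param baseline_window Standardization window (s).
#' @param hi,lo First and second thresholds in baseline s.d. units.
#' @param smooth Apply the causal 10 ms boxcar?
#' @return One-row tibble: `latency_ms`, `t_std5_ms`, `reason`.
#' @export
projection_latency <- function(trace, time = NULL, condition = NULL,
                               baseline_window = c(-0.1, 0), hi = 5, lo = 2,
                               smooth = TRUE) {
  if (inherits(trace, "projection_trace")) {
    time <- trace$time
    x <- if (!is.null(condition)) trace$values[, condition]
         else rowMeans(trace$values)
    bin_width <- trace$bin_width
  } else {
    stopifnot(is.numeric(trace), !is.null(time))
    x <- trace
    bin_width <- stats::median(diff(time))
  }
  # baseline strictly before the cue: T_go - 0.1 s < t < T_go
  base_idx <- which(time >= baseline_window[1] - 1e-9 &
                      time < baseline_window[2] - 1e-9)
  if (length(base_idx) < 2) {
    abort("projection_latency: baseline window not covered",
          class = "popmodes_error")
  }
  mu <- mean(x[base_idx])
  sigma <- stats::sd(x[base_idx])
  if (!is.finite(sigma) || sigma == 0) {
    abort("projection_latency: zero baseline s.d.", class = "popmodes_error")
  }
  z <- (x - mu) / sigma
  if (smooth) z <- boxcar_causal(z, max(1L, round(0.01 / bin_width)))
  post <- which(time >= 0)
  z_post <- abs(z[post])
  t5 <- which(z_post >= hi)
  if (length(t5) == 0) {
    return(tibble::tibble(latency_ms = NA_real_, t_std5_ms = NA_real_,
                          reason = "no 5 s.d. crossing"))
  }
  t5 <- t5[1]
  run_start <- t5
  while (run_start > 1 && z_post[run_start - 1] >= lo) run_start <- run_start - 1
  tibble::tibble(latency_ms = time[post[run_start]] * 1000,
                 t_std5_ms = time[post[t5]] * 1000, reason = NA_character_)
}
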