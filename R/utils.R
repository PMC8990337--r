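# Internal helpers shared across modules.

# Half-open bin membership [t0, t1); the convention used everywhere a window
# selects bins or spikes, so each event belongs to exactly one bin.
in_window <- function(x, window) {
  x >= window[1] & x < window[2]
}

# Indices of bin centers falling inside a window. Bin centers are compared
# against the window with a half-bin tolerance so that windows stated in
# multiples of the bin width select the expected bins.
window_bins <- function(time, window, bin_width = NULL) {
  if (is.null(bin_width)) {
    bin_width <- if (length(time) > 1) stats::median(diff(time)) else 0
  }
  idx <- which(time >= window[1] - 1e-9 & time < window[2] - 1e-9 + bin_width / 2)
  if (length(idx) == 0) {
    abort(sprintf("window [%g, %g) contains no time bins", window[1], window[2]),
          class = "popmodes_error")
  }
  idx
}

check_window <- function(window, arg = "window") {
  if (!is.numeric(window) || length(window) != 2 || !all(is.finite(window)) ||
      window[2] <= window[1]) {
    abort(sprintf("`%s` must be a finite numeric pair (t0, t1) with t1 > t0", arg),
          class = "popmodes_error")
  }
  invisible(window)
}

check_count <- function(x, arg, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d", arg, min), class = "popmodes_error")
  }
  as.integer(x)
}

check_prob <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a probability in [0, 1]", arg), class = "popmodes_error")
  }
  x
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1 || !is.finite(seed) ||
      seed != round(seed)) {
    abort("`seed` must be a single integer", class = "popmodes_error")
  }
  as.integer(seed)
}

# Derive a stream of child seeds from a master seed, all below 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(check_seed(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Causal boxcar: mean of the current and the (k - 1) preceding samples, with
# partial windows at the start so output length equals input length and the
# value at index i depends only on indices <= i.
boxcar_causal <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - k, 0L)
  (cs[i + 1L] - cs[lo + 1L]) / (i - lo)
}

# Centered boxcar with partial windows at the edges; k forced odd.
boxcar_centered <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  h <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

smooth_rows <- function(mat, smoothing, bin_width) {
  if (smoothing == "none") return(mat)
  fun <- switch(smoothing,
    boxcar_centered_100ms = function(x) boxcar_centered(x, round(0.1 / bin_width)),
    boxcar_causal_5ms     = function(x) boxcar_causal(x, round(0.005 / bin_width)),
    boxcar_causal_10ms    = function(x) boxcar_causal(x, round(0.01 / bin_width)),
    abort(sprintf("unknown smoothing '%s'", smoothing), class = "popmodes_error")
  )
  t(apply(mat, 1, fun))
}

vector_norm <- function(x) sqrt(sum(x^2))

# Scale-free degeneracy test: a vector counts as zero when its norm is below
# 1e-9 * sqrt(n), i.e. below 1e-9 per-coordinate RMS.
is_degenerate <- function(x) {
  vector_norm(x) < 1e-9 * sqrt(length(x))
}

abort_degenerate <- function(what) {
  abort(sprintf("degenerate mode: %s has (numerically) zero norm", what),
        class = "popmodes_degenerate")
}

abort_ineligible <- function(msg) {
  abort(msg, class = "popmodes_ineligible")
}
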