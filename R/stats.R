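#' Epoch selectivity of a single unit (rank-sum test)
#'
#' Tests whether a unit's per-trial spike counts differ between correct
#' lick-right and lick-left trials during the delay epoch (last 600 ms
#' before the go cue) and the response epoch (first 600 ms after), on 40
#' randomly subsampled correct trials per type. Two-sided Wilcoxon rank-sum;
#' exact enumeration below 10 trials per group, normal approximation with
#' tie correction otherwise. Selective means `p < 0.05`.
#'
#' @param session A `session_data`.
#' @param unit_id Unit to test.
#' @param windows Named list of epoch windows (s relative to the cue).
#' @param n_sub Per-type subsample size (`NULL` to use all correct trials).
#' @param seed Subsample seed.
#' @return Tibble, one row per epoch: `epoch`, `p_value`, `preferred`
#'   (direction with the larger mean count), `selective`.
#' @export
epoch_selectivity_test <- function(session, unit_id,
                                   windows = list(delay = c(-0.6, 0),
                                                  response = c(0, 0.6)),
                                   n_sub = 40, seed = 1L) {
  trials <- select_trials(session$trials, subsample_n = n_sub, seed = seed)
  purrr::map_dfr(names(windows), function(ep) {
    rv <- trial_rate_vectors(session, trials, windows[[ep]], units = unit_id)
    x <- rv[trials$type == "lick_right", 1]
    y <- rv[trials$type == "lick_left", 1]
    res <- ranksum_test(x, y)
    tibble::tibble(
      epoch = ep, p_value = res,
      preferred = if (mean(x) >= mean(y)) "lick_right" else "lick_left",
      selective = res < 0.05
    )
  })
}

# Two-sided rank-sum p-value; exact for small samples without ties, normal
# approximation with tie correction otherwise (stats::wilcox.test).
ranksum_test <- function(x, y) {
  exact <- min(length(x), length(y)) < 10
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' ROC decoding of trial type from single-trial projections
#'
#' Area under the ROC curve for discriminating the two classes from the
#' per-trial projection in each time bin, computed with the rank statistic
#' (equivalent to Mann-Whitney U / (n1 n2)); ties are mid-ranked. AUC 1
#' means the positive class always projects higher.
#'
#' @param projections Numeric vector (one bin) or trials x bins matrix of
#'   per-trial projections.
#' @param labels Class labels, one per trial (two levels; `"lick_right"` is
#'   the positive class when present, otherwise the second sorted level).
#' @param time Optional bin times for the output.
#' @return Tibble with columns `bin` (or `time`) and `auc`.
#' @export
roc_decode <- function(projections, labels, time = NULL) {
  if (!is.matrix(projections)) projections <- matrix(projections, ncol = 1)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) {
    abort("roc_decode: need exactly two classes", class = "popmodes_error")
  }
  positive <- if ("lick_right" %in% lev) "lick_right" else lev[2]
  pos <- labels == positive
  if (sum(pos) < 2 || sum(!pos) < 2) {
    abort("roc_decode: need >= 2 trials per class", class = "popmodes_error")
  }
  auc <- apply(projections, 2, function(x) auc_rank(x, pos))
  out <- tibble::tibble(bin = seq_along(auc), auc = auc)
  if (!is.null(time)) out$time <- time
  out
}

auc_rank <- function(x, pos) {
  r <- rank(x, ties.method = "average")
  n1 <- sum(pos)
  n2 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Time-by-time correlation of the population activity vector
#'
#' Pearson correlation between population vectors at all pairs of time bins,
#' either of the selectivity vector `w_t` (`mode = "selectivity"`) or of a
#' single trial type's mean rates (`mode = "mean"`, averaging the types).
#' The PSTH is re-binned to `bin` (10 ms default) by averaging.
#'
#' @param psth A `psth_matrix`.
#' @param bin Output bin width (s), a multiple of the PSTH bin.
#' @param mode `"selectivity"` or `"mean"`.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `"time"` gives the bin centers.
#' @export
population_vector_correlation <- function(psth, bin = 0.01,
                                          mode = c("selectivity", "mean")) {
  mode <- match.arg(mode)
  if (length(psth$unit_ids) < 2) {
    abort("population_vector_correlation: need >= 2 neurons",
          class = "popmodes_error")
  }
  m <- switch(mode,
    selectivity = selectivity_vector(psth)$w,
    mean = mean_over_types(psth)
  )
  fold <- max(1L, round(bin / psth$bin_width))
  n_out <- floor(ncol(m) / fold)
  if (n_out < 2) abort("population_vector_correlation: fewer than 2 output bins",
                       class = "popmodes_error")
  grp <- rep(seq_len(n_out), each = fold)
  m_binned <- vapply(seq_len(n_out), function(j) {
    rowMeans(m[, which(grp == j) , drop = FALSE])
  }, numeric(nrow(m)))
  cc <- suppressWarnings(stats::cor(m_binned))
  time_binned <- vapply(seq_len(n_out), function(j) {
    mean(psth$time[seq_len(n_out * fold)][grp == j])
  }, numeric(1))
  attr(cc, "time") <- time_binned
  cc
}

#' Trial-by-trial correlation between two mode projections
#'
#' Pearson correlation, across trials, between activity along one mode in
#' pre-cue bins and along another mode in post-cue bins (e.g. `CD_delay`
#' before vs `CD_response` after the go cue). A trial-shuffled control
#' destroys the pairing and should show no correlation.
#'
#' @param proj_pre,proj_post Trials x bins matrices of per-trial projections
#'   (same trial set, same row order).
#' @param shuffle Also compute the shuffled twin?
#' @param seed Shuffle seed.
#' @return List with `r` (pre-bins x post-bins correlation matrix) and, when
#'   requested, `r_shuffled`.
#' @export
trial_mode_correlation <- function(proj_pre, proj_post, shuffle = TRUE,
                                   seed = 1L) {
  proj_pre <- as.matrix(proj_pre)
  proj_post <- as.matrix(proj_post)
  if (nrow(proj_pre) != nrow(proj_post)) {
    abort("trial_mode_correlation: trial sets differ", class = "popmodes_error")
  }
  r <- suppressWarnings(stats::cor(proj_pre, proj_post))
  out <- list(r = r)
  if (shuffle) {
    perm <- withr::with_seed(check_seed(seed),
                             sample.int(nrow(proj_post)))
    out$r_shuffled <- suppressWarnings(stats::cor(proj_pre, proj_post[perm, , drop = FALSE]))
  }
  out
}

#' Go-cue response amplitude per neuron
#'
#' Mean spike rate after the go cue minus mean spike rate before it, over
#' symmetric windows (100 ms default), per trial-type condition.
#'
#' @param psth A `psth_matrix` aligned to the go cue.
#' @param window_s Window length (s) on each side of the cue.
#' @return Tibble: `unit_id`, `condition`, `delta` (spikes/s).
#' @export
go_response_amplitude <- function(psth, window_s = 0.1) {
  pre <- window_bins(psth$time, c(-window_s, 0), psth$bin_width)
  post <- window_bins(psth$time, c(0, window_s), psth$bin_width)
  purrr::map_dfr(psth$conditions, function(cond) {
    r <- matrix(psth$rates[, , cond], nrow = length(psth$unit_ids))
    tibble::tibble(
      unit_id = psth$unit_ids, condition = cond,
      delta = rowMeans(r[, post, drop = FALSE]) - rowMeans(r[, pre, drop = FALSE])
    )
  })
}

#' Logistic regression of lick outcome on mode activity
#'
#' Binomial logit fit (IRLS, deviance tolerance 1e-8, at most 100
#' iterations) of whether the animal licked on per-trial covariates such as
#' pre-cue `CD_delay` activity and post-cue activity changes along
#' `CD_delay`, `CD_response` and `D_go` (200 ms windows). Complete
#' separation is detected (any |coefficient| > 15 on standardized
#' covariates) and flagged. Confidence intervals come from a hierarchical
#' bootstrap when `animal_id`/`session_id` columns are present, a flat trial
#' bootstrap otherwise.
#'
#' @param data Tibble with a logical/0-1 `licked` column, the covariates and
#'   optionally `animal_id`, `session_id`.
#' @param covariates Character vector of covariate column names.
#' @param n_boot Bootstrap iterations for the CIs (0 to skip).
#' @param seed RNG seed.
#' @return Object of class `logit_lick_model` with a [tidy()] method.
#' @export
logit_lick_model <- function(data, covariates, n_boot = 1000, seed = 1L) {
  data <- tibble::as_tibble(data)
  if (!"licked" %in% names(data)) {
    abort("logit_lick_model: need a `licked` column", class = "popmodes_error")
  }
  y <- as.integer(data$licked)
  if (length(unique(y)) < 2) {
    abort("logit_lick_model: both outcome classes must be present",
          class = "popmodes_error")
  }
  x <- data[covariates]
  scl <- lapply(x, function(v) c(mu = mean(v), sd = stats::sd(v)))
  xs <- tibble::as_tibble(lapply(x, function(v) {
    s <- stats::sd(v)
    if (s == 0) v - mean(v) else (v - mean(v)) / s
  }))
  fit_one <- function(df) {
    f <- stats::glm(
      stats::reformulate(covariates, "licked"),
      family = stats::binomial(),
      data = df,
      control = stats::glm.control(epsilon = 1e-8, maxit = 100)
    )
    stats::coef(f)
  }
  dfit <- dplyr::bind_cols(tibble::tibble(licked = y), xs)
  coefs <- fit_one(dfit)
  separated <- any(abs(coefs[-1]) > 15)
  boots <- NULL
  if (n_boot > 0) {
    hier <- all(c("animal_id", "session_id") %in% names(data))
    dboot <- dfit
    if (hier) {
      dboot$animal_id <- data$animal_id
      dboot$session_id <- data$session_id
    }
    idx <- if (hier) hier_index(dboot) else NULL
    boots <- withr::with_seed(check_seed(seed), {
      t(vapply(seq_len(n_boot), function(i) {
        rows <- if (is.null(idx)) sample.int(nrow(dboot), replace = TRUE)
                else resample_hier(idx)
        tryCatch(fit_one(dboot[rows, , drop = FALSE]),
                 error = function(e) rep(NA_real_, length(coefs)))
      }, numeric(length(coefs))))
    })
  }
  structure(
    list(coefficients = coefs, boots = boots, covariates = covariates,
         separated = separated, scaling = scl, n = nrow(data), seed = seed),
    class = "logit_lick_model"
  )
}

#' @export
print.logit_lick_model <- function(x, ...) {
  cat("<logit_lick_model> n = ", x$n,
      if (x$separated) " [complete separation flagged]", "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @method tidy logit_lick_model
#' @export
tidy.logit_lick_model <- function(x, ...) {
  out <- tibble::tibble(term = names(x$coefficients),
                        estimate = unname(x$coefficients))
  if (!is.null(x$boots)) {
    qs <- apply(x$boots, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
    out$conf.low <- qs[1, ]
    out$conf.high <- qs[2, ]
  }
  out
}

#' @method glance logit_lick_model
#' @export
glance.logit_lick_model <- function(x, ...) {
  tibble::tibble(n = x$n, separated = x$separated,
                 n_boot = if (is.null(x$boots)) 0L else nrow(x$boots))
}

#' Sinusoidal modulation of spike rates at a stimulation frequency
#'
#' Fourier coefficient of each unit's mean peri-stimulus rate at `freq`
#' (40 Hz photostimulus modulation by default). The analysis window must
#' contain an integer number of cycles. For a rate
#' `m + A cos(2 pi f t + phi)` the returned amplitude is `A` and the phase
#' `phi` in `(-pi, pi]`.
#'
#' @param rates Units x time matrix (or vector) of mean rates.
#' @param time Sample times (s), uniform spacing.
#' @param freq Modulation frequency (Hz).
#' @return Tibble: `unit_id` (row names or index), `amplitude`, `phase`.
#' @export
sinusoidal_modulation <- function(rates, time, freq = 40) {
  if (!is.matrix(rates)) rates <- matrix(rates, nrow = 1)
  dt <- stats::median(diff(time))
  dur <- length(time) * dt
  cycles <- freq * dur
  if (abs(cycles - round(cycles)) > 1e-6) {
    abort("sinusoidal_modulation: window must span an integer number of cycles",
          class = "popmodes_error")
  }
  basis <- exp(-2i * pi * freq * time)
  coefs <- (rates %*% basis) * (2 / length(time))
  tibble::tibble(
    unit_id = rownames(rates) %||% as.character(seq_len(nrow(rates))),
    amplitude = as.numeric(Mod(coefs)),
    phase = as.numeric(Arg(coefs))
  )
}

#' Smoothed spatial density of flagged neurons
#'
#' Per pixel: Gaussian-smoothed count of flagged neurons (e.g. short-latency
#' or delay-selective cells) divided by the smoothed count of all neurons
#' plus 0.05, the regularizer preventing pixels with few neurons from
#' showing extreme densities. The kernel has value 1 at zero distance and
#' half-width (at half maximum) `half_width_um`.
#'
#' @param x_um,y_um Neuron coordinates (micrometres), finite.
#' @param flagged Logical vector, one per neuron.
#' @param xlim,ylim Map extent (defaults to the data range).
#' @param pixel_um Pixel size (10 um default).
#' @param half_width_um Gaussian half-width at half maximum.
#' @return List with `density` (matrix ny x nx), `x`, `y` (pixel centers).
#' @export
density_map <- function(x_um, y_um, flagged, xlim = range(x_um),
                        ylim = range(y_um), pixel_um = 10,
                        half_width_um = 250) {
  stopifnot(length(x_um) == length(y_um), length(flagged) == length(x_um),
            all(is.finite(x_um)), all(is.finite(y_um)))
  sigma <- half_width_um / sqrt(2 * log(2))
  gx <- seq(xlim[1], xlim[2], by = pixel_um)
  gy <- seq(ylim[1], ylim[2], by = pixel_um)
  kx <- exp(-outer(gx, x_um, "-")^2 / (2 * sigma^2))  # nx x n
  ky <- exp(-outer(gy, y_um, "-")^2 / (2 * sigma^2))  # ny x n
  total <- ky %*% t(kx)
  flag <- ky[, flagged, drop = FALSE] %*% t(kx[, flagged, drop = FALSE])
  list(density = flag / (total + 0.05), x = gx, y = gy)
}

#' Fisher linear discriminant boundary in a 2-D mode plane
#'
#' Closed-form two-class Fisher LDA on points (e.g. per-trial `CD_delay` vs
#' `CD_response` activity): discriminant direction
#' `w = Sw^-1 (m1 - m2)` with pooled within-class scatter `Sw`, threshold at
#' the midpoint of the projected class means (equal priors). The decision
#' boundary `w . x = c` is reported as slope/intercept in the plane (or as a
#' vertical line).
#'
#' @param points Two-column matrix or data frame (x = first mode, y =
#'   second mode), one row per trial.
#' @param labels Two-level class labels.
#' @return List: `direction` (w, length 2), `threshold`, `slope`,
#'   `intercept`, `vertical` (logical), `x_vertical`.
#' @export
lda_boundary <- function(points, labels) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) abort("lda_boundary: need two classes",
                              class = "popmodes_error")
  a <- points[labels == lev[1], , drop = FALSE]
  b <- points[labels == lev[2], , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) {
    abort("lda_boundary: need >= 2 points per class", class = "popmodes_error")
  }
  sw <- crossprod(scale(a, scale = FALSE)) + crossprod(scale(b, scale = FALSE))
  if (abs(det(sw)) < 1e-12 * max(abs(sw))^2) {
    abort("lda_boundary: degenerate pooled covariance", class = "popmodes_error")
  }
  m1 <- colMeans(a)
  m2 <- colMeans(b)
  w <- solve(sw, m1 - m2)
  thr <- sum(w * (m1 + m2)) / 2
  vertical <- abs(w[2]) < 1e-12 * max(abs(w))
  list(
    direction = unname(w), threshold = unname(thr),
    slope = if (vertical) NA_real_ else unname(-w[1] / w[2]),
    intercept = if (vertical) NA_real_ else unname(thr / w[2]),
    vertical = vertical,
    x_vertical = if (vertical) unname(thr / w[1]) else NA_real_,
    classes = lev
  )
}

#' Behavioural response rate within a lick window
#'
#' Proportion of trials whose first lick falls inside the half-open window
#' `[t0, t1)` relative to the go cue. Early-lick trials are always excluded.
#' `type = "correct"` instead returns the proportion of responded trials
#' (no-response trials excluded) whose first lick direction matches the
#' instructed direction.
#'
#' @param trials Trial table with `t_go`, `first_lick_time`, `outcome` and,
#'   for the correct rate, `first_lick_direction` and `type`.
#' @param lick_window Window (s) relative to the go cue.
#' @param type `"response"` or `"correct"`.
#' @return Single proportion in `[0, 1]` (NA if no qualifying trials).
#' @export
response_rate <- function(trials, lick_window = c(0, 0.6),
                          type = c("response", "correct")) {
  type <- match.arg(type)
  keep <- trials$outcome != "early_lick"
  tr <- trials[keep, ]
  rel <- tr$first_lick_time - tr$t_go
  licked_in <- !is.na(rel) & rel >= lick_window[1] & rel < lick_window[2]
  if (type == "response") {
    if (nrow(tr) == 0) return(NA_real_)
    return(mean(licked_in))
  }
  responded <- tr$outcome != "no_response" & !is.na(tr$first_lick_direction) &
    licked_in
  if (!any(responded)) return(NA_real_)
  instructed <- ifelse(tr$type == "lick_right", "right", "left")
  mean(tr$first_lick_direction[responded] == instructed[responded])
}
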