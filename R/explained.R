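#' Fraction of population selectivity explained by a mode set
#'
#' Total selectivity at time `t` is the squared sum of per-neuron
#' selectivity, `||w_t||^2`. The fraction explained by a set of orthonormal
#' modes is `sum_m (w_t . m)^2 / ||w_t||^2`, reported per mode and
#' cumulatively per time bin. Bins where `||w_t||^2 = 0` are flagged
#' (`NA` fraction), not reported as zero.
#'
#' @param psth A `psth_matrix` with both trial-type conditions.
#' @param modes Named list of `mode_vector`s (should be orthonormal, e.g.
#'   from [orthogonalize_set()]).
#' @param window Optional window restricting the reported bins.
#' @return Tibble with columns `time`, `mode`, `fraction` plus rows
#'   `mode == "total"` giving the cumulative fraction. Attribute
#'   `"aggregate"` holds the window-aggregate fraction per mode
#'   (`sum_t (w_t . m)^2 / sum_t ||w_t||^2`) and its total.
#' @export
selectivity_explained <- function(psth, modes, window = NULL) {
  sv <- selectivity_vector(psth)
  explained_core(sv$w, sv$time, psth$bin_width, modes, window,
                 psth$unit_ids)
}

#' Fraction of baseline-subtracted activity explained by a mode set
#'
#' Same decomposition as [selectivity_explained()], applied separately to
#' each trial type's baseline-subtracted population activity (baseline =
#' mean rate per neuron in the 0.6 s before the sample onset).
#'
#' @inheritParams selectivity_explained
#' @param baseline_window Baseline window (s, relative to the alignment
#'   event); defaults to the 0.6 s preceding the sample onset.
#' @return Tibble with columns `condition`, `time`, `mode`, `fraction`;
#'   attribute `"aggregate"` as in [selectivity_explained()] (per
#'   condition).
#' @export
activity_explained <- function(psth, modes, window = NULL,
                               baseline_window = NULL) {
  stopifnot(inherits(psth, "psth_matrix"))
  if (is.null(baseline_window)) {
    s_on <- psth$epochs[["sample_on"]]
    baseline_window <- c(s_on - 0.6, s_on)
  }
  idx_base <- window_bins(psth$time, baseline_window, psth$bin_width)
  pieces <- lapply(psth$conditions, function(cond) {
    r <- matrix(psth$rates[, , cond], nrow = length(psth$unit_ids))
    a <- r - rowMeans(r[, idx_base, drop = FALSE])
    res <- explained_core(a, psth$time, psth$bin_width, modes, window,
                          psth$unit_ids)
    res$condition <- cond
    res
  })
  out <- dplyr::bind_rows(pieces)
  attr(out, "aggregate") <- stats::setNames(
    lapply(pieces, attr, "aggregate"), psth$conditions)
  out
}

explained_core <- function(w, time, bin_width, modes, window, unit_ids) {
  if (inherits(modes, "mode_vector")) modes <- list(modes)
  if (is.null(names(modes))) {
    names(modes) <- vapply(modes, function(m) m$kind, character(1))
  }
  M <- vapply(modes, function(m) {
    check_same_units(unit_ids, m$unit_ids, "explained")
    unname(m$weights)
  }, numeric(length(unit_ids)))
  M <- matrix(M, nrow = length(unit_ids), dimnames = list(NULL, names(modes)))
  if (!is.null(window)) {
    idx <- window_bins(time, window, bin_width)
    w <- w[, idx, drop = FALSE]
    time <- time[idx]
  }
  proj2 <- (t(M) %*% w)^2                       # modes x bins
  total2 <- colSums(w^2)                        # bins
  frac <- sweep(proj2, 2, total2, "/")
  frac[, total2 == 0] <- NA_real_
  cum <- colSums(proj2) / total2
  cum[total2 == 0] <- NA_real_
  n_bins <- length(time)
  out <- tibble::tibble(
    time = rep(time, times = length(modes) + 1L),
    mode = rep(c(names(modes), "total"), each = n_bins),
    fraction = c(as.numeric(t(frac)), cum)
  )
  agg <- c(rowSums(proj2) / sum(total2), total = sum(proj2) / sum(total2))
  attr(out, "aggregate") <- agg
  out
}

#' Window-aggregate explained fraction
#'
#' Convenience accessor: the fraction of total (squared, summed over bins)
#' selectivity in `window` captured jointly by `modes`.
#'
#' @inheritParams selectivity_explained
#' @return Single number in `[0, 1]`.
#' @export
selectivity_explained_total <- function(psth, modes, window = NULL) {
  res <- selectivity_explained(psth, modes, window)
  unname(attr(res, "aggregate")["total"])
}
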