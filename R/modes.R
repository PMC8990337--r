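new_mode_vector <- function(weights, unit_ids, kind, window = NULL,
                            orthogonalized_against = character()) {
  structure(
    list(weights = stats::setNames(as.numeric(weights), unit_ids),
         unit_ids = unit_ids, kind = kind, window = window,
         orthogonalized_against = orthogonalized_against),
    class = "mode_vector"
  )
}

#' @export
print.mode_vector <- function(x, ...) {
  cat("<mode_vector> ", x$kind, ": ", length(x$weights), " units",
      if (length(x$orthogonalized_against))
        paste0("; orthogonalized to ",
               paste(x$orthogonalized_against, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' @method as_tibble mode_vector
#' @export
as_tibble.mode_vector <- function(x, ...) {
  tibble::tibble(unit_id = x$unit_ids, weight = unname(x$weights),
                 kind = x$kind)
}

unit_normalize <- function(v, what) {
  if (is_degenerate(v)) abort_degenerate(what)
  v / vector_norm(v)
}

check_same_units <- function(a_ids, b_ids, what) {
  if (length(a_ids) != length(b_ids) || !all(a_ids == b_ids)) {
    abort(sprintf("%s: neuron sets do not match", what), class = "popmodes_error")
  }
}

#' Population selectivity vector
#'
#' For every time bin, the difference in trial-averaged rate between the two
#' trial types, `w_t = r_right(t) - r_left(t)`, one entry per unit.
#'
#' @param psth A `psth_matrix` with conditions `lick_right` and `lick_left`
#'   on one time base.
#' @return Object of class `selectivity_vector`: list with `w` (units x bins
#'   matrix, spikes/s), `time`, `unit_ids`.
#' @export
selectivity_vector <- function(psth) {
  stopifnot(inherits(psth, "psth_matrix"))
  if (!all(c("lick_right", "lick_left") %in% psth$conditions)) {
    abort("selectivity_vector: need both lick_right and lick_left conditions",
          class = "popmodes_error")
  }
  w <- psth$rates[, , "lick_right", drop = FALSE][, , 1, drop = TRUE] -
    psth$rates[, , "lick_left", drop = FALSE][, , 1, drop = TRUE]
  w <- matrix(w, nrow = length(psth$unit_ids),
              dimnames = list(psth$unit_ids, NULL))
  structure(list(w = w, time = psth$time, unit_ids = psth$unit_ids),
            class = "selectivity_vector")
}

window_mean_w <- function(sv, window, bin_width) {
  idx <- window_bins(sv$time, window, bin_width)
  rowMeans(sv$w[, idx, drop = FALSE])
}

#' Delay coding direction
#'
#' Unit vector in neuron-activity space that maximally distinguishes the two
#' trial types during the late delay: the selectivity vector averaged over
#' the last 600 ms before the go cue, normalized by its norm.
#'
#' @param psth A `psth_matrix` (two trial-type conditions).
#' @param window Averaging window (s relative to the go cue).
#' @return A `mode_vector` of kind `"CD_delay"`.
#' @export
compute_cd_delay <- function(psth, window = c(-0.6, 0)) {
  sv <- selectivity_vector(psth)
  v <- window_mean_w(sv, window, psth$bin_width)
  new_mode_vector(unit_normalize(v, "CD_delay"), sv$unit_ids, "CD_delay", window)
}

#' Response coding direction
#'
#' The selectivity vector averaged over the first 400 ms after the go cue,
#' orthogonalized to the delay coding direction by Gram-Schmidt (set
#' `orthogonalize = FALSE` for the raw variant) and normalized.
#'
#' @inheritParams compute_cd_delay
#' @param cd_delay The `CD_delay` mode to orthogonalize against (required
#'   unless `orthogonalize = FALSE`).
#' @param orthogonalize Remove the `CD_delay` component?
#' @return A `mode_vector` of kind `"CD_response"`.
#' @export
compute_cd_response <- function(psth, window = c(0, 0.4), cd_delay = NULL,
                                orthogonalize = TRUE) {
  sv <- selectivity_vector(psth)
  v <- window_mean_w(sv, window, psth$bin_width)
  if (is_degenerate(v)) abort_degenerate("CD_response")
  if (orthogonalize) {
    if (is.null(cd_delay)) {
      abort("compute_cd_response: `cd_delay` required when orthogonalize = TRUE",
            class = "popmodes_error")
    }
    check_same_units(sv$unit_ids, cd_delay$unit_ids, "compute_cd_response")
    v <- v - sum(v * cd_delay$weights) * cd_delay$weights
    return(new_mode_vector(unit_normalize(v, "CD_response"), sv$unit_ids,
                           "CD_response", window, "CD_delay"))
  }
  new_mode_vector(unit_normalize(v, "CD_response"), sv$unit_ids,
                  "CD_response", window)
}

mean_over_types <- function(psth) {
  if (all(c("lick_right", "lick_left") %in% psth$conditions)) {
    m <- (psth$rates[, , "lick_right", drop = FALSE][, , 1, drop = TRUE] +
            psth$rates[, , "lick_left", drop = FALSE][, , 1, drop = TRUE]) / 2
  } else {
    m <- apply(psth$rates, c(1, 2), mean)
  }
  matrix(m, nrow = length(psth$unit_ids), dimnames = list(psth$unit_ids, NULL))
}

#' Go direction (condition-invariant cue response)
#'
#' Per neuron, the mean of the two trial types' rates after the go cue minus
#' that before the cue (100 ms windows), unit-normalized.
#'
#' @inheritParams compute_cd_delay
#' @param pre_window,post_window Pre/post cue windows (s).
#' @return A `mode_vector` of kind `"D_go"`.
#' @export
compute_d_go <- function(psth, pre_window = c(-0.1, 0), post_window = c(0, 0.1)) {
  m <- mean_over_types(psth)
  pre <- rowMeans(m[, window_bins(psth$time, pre_window, psth$bin_width), drop = FALSE])
  post <- rowMeans(m[, window_bins(psth$time, post_window, psth$bin_width), drop = FALSE])
  new_mode_vector(unit_normalize(post - pre, "D_go"), psth$unit_ids, "D_go",
                  c(pre_window[1], post_window[2]))
}

#' Ramping direction
#'
#' Direction maximally distinguishing mean activity before the trial onset
#' (0.6 s window before the sample epoch) from mean activity just before the
#' go cue (0.1 s window), averaged over trial types and unit-normalized.
#'
#' @inheritParams compute_cd_delay
#' @param pre_trial_window Window before trial onset; defaults to the 0.6 s
#'   preceding the sample onset recorded in the PSTH's `epochs`.
#' @param pre_cue_window Window before the go cue.
#' @return A `mode_vector` of kind `"D_ramp"`.
#' @export
compute_d_ramp <- function(psth, pre_trial_window = NULL,
                           pre_cue_window = c(-0.1, 0)) {
  if (is.null(pre_trial_window)) {
    s_on <- psth$epochs[["sample_on"]]
    pre_trial_window <- c(s_on - 0.6, s_on)
  }
  m <- mean_over_types(psth)
  pre <- rowMeans(m[, window_bins(psth$time, pre_trial_window, psth$bin_width), drop = FALSE])
  cue <- rowMeans(m[, window_bins(psth$time, pre_cue_window, psth$bin_width), drop = FALSE])
  new_mode_vector(unit_normalize(cue - pre, "D_ramp"), psth$unit_ids, "D_ramp",
                  pre_cue_window)
}

#' Stimulation direction
#'
#' Direction maximally distinguishing cue-omitted control trials from
#' optogenetic stimulation trials in the 100 ms after the (omitted) cue /
#' stimulation onset.
#'
#' @param psth_omitted,psth_stim `psth_matrix` objects for go-cue-omitted and
#'   stimulation trials on identical units and time base.
#' @param window Post-onset window (s).
#' @return A `mode_vector` of kind `"D_stim"`.
#' @export
compute_d_stim <- function(psth_omitted, psth_stim, window = c(0, 0.1)) {
  check_same_units(psth_omitted$unit_ids, psth_stim$unit_ids, "compute_d_stim")
  mo <- mean_over_types(psth_omitted)
  ms <- mean_over_types(psth_stim)
  idx <- window_bins(psth_omitted$time, window, psth_omitted$bin_width)
  v <- rowMeans(ms[, idx, drop = FALSE]) - rowMeans(mo[, idx, drop = FALSE])
  new_mode_vector(unit_normalize(v, "D_stim"), psth_omitted$unit_ids,
                  "D_stim", window)
}

#' Gram-Schmidt orthogonalization of a mode set
#'
#' Sequentially orthogonalizes the modes in the given order; each output is
#' unit-norm and orthogonal (|dot| <= 1e-10) to all earlier ones. The first
#' mode is never changed.
#'
#' @param modes Named list of `mode_vector`s on a common neuron set.
#' @param order Character vector giving the orthogonalization order
#'   (defaults to the list order).
#' @return Named list of orthogonalized `mode_vector`s (class `mode_set`).
#' @export
orthogonalize_set <- function(modes, order = names(modes)) {
  stopifnot(length(modes) >= 1, !is.null(names(modes)))
  modes <- modes[order]
  ids <- modes[[1]]$unit_ids
  for (m in modes) check_same_units(ids, m$unit_ids, "orthogonalize_set")
  basis <- list()
  out <- list()
  for (nm in names(modes)) {
    v <- modes[[nm]]$weights
    for (b in basis) v <- v - sum(v * b) * b
    if (is_degenerate(v)) {
      abort(sprintf("orthogonalize_set: mode '%s' is linearly dependent on earlier modes", nm),
            class = "popmodes_degenerate")
    }
    v <- v / vector_norm(v)
    basis[[nm]] <- v
    m <- modes[[nm]]
    m$weights <- stats::setNames(v, ids)
    m$orthogonalized_against <- setdiff(names(basis), nm)
    out[[nm]] <- m
  }
  structure(out, class = c("mode_set", "list"))
}

#' Angle between two modes
#'
#' @param m1,m2 `mode_vector`s (unit norm) on the same neuron set.
#' @return Angle in radians, in `[0, pi]`.
#' @export
mode_angle <- function(m1, m2) {
  check_same_units(m1$unit_ids, m2$unit_ids, "mode_angle")
  acos(max(-1, min(1, sum(m1$weights * m2$weights))))
}

#' Cosine similarity between a mode and an arbitrary pattern
#'
#' Convenience for ground-truth recovery checks; the pattern is normalized
#' internally and sign is preserved.
#'
#' @param mode A `mode_vector`.
#' @param pattern Numeric vector, one entry per unit in the mode's order.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
mode_cosine <- function(mode, pattern) {
  stopifnot(length(pattern) == length(mode$weights))
  sum(mode$weights * pattern) / vector_norm(pattern)
}
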