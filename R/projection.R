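#' Project population activity onto a mode
#'
#' Inner product of the mode's unit weights with population rates, either per
#' time bin and condition (for a `psth_matrix`) or per trial (for a
#' trials x units matrix from [trial_rate_vectors()]). Projection is linear
#' in the rates.
#'
#' @param rates A `psth_matrix`, or a numeric matrix (trials x units).
#' @param mode A `mode_vector` whose units match the rates' units.
#' @return For a PSTH: object of class `projection_trace` (list with
#'   `values` = time x condition matrix, `time`, `kind`, `normalization`).
#'   For a trial matrix: named numeric vector of per-trial projections.
#' @export
project <- function(rates, mode) {
  stopifnot(inherits(mode, "mode_vector"))
  if (inherits(rates, "psth_matrix")) {
    check_same_units(rates$unit_ids, mode$unit_ids, "project")
    vals <- vapply(seq_along(rates$conditions), function(ci) {
      m <- matrix(rates$rates[, , ci], nrow = length(rates$unit_ids))
      as.numeric(crossprod(m, mode$weights))
    }, numeric(length(rates$time)))
    vals <- matrix(vals, ncol = length(rates$conditions),
                   dimnames = list(NULL, rates$conditions))
    return(structure(list(values = vals, time = rates$time, kind = mode$kind,
                          bin_width = rates$bin_width, normalization = NULL),
                     class = "projection_trace"))
  }
  if (is.matrix(rates)) {
    check_same_units(colnames(rates), names(mode$weights), "project")
    return(drop(rates %*% mode$weights))
  }
  abort("project: `rates` must be a psth_matrix or trials x units matrix",
        class = "popmodes_error")
}

#' @export
print.projection_trace <- function(x, ...) {
  cat("<projection_trace> ", x$kind, ": ", length(x$time), " bins x ",
      ncol(x$values), " condition(s)",
      if (!is.null(x$normalization)) "; normalized", "\n", sep = "")
  invisible(x)
}

#' @method as_tibble projection_trace
#' @export
as_tibble.projection_trace <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(x$values), time = x$time),
    -"time", names_to = "condition", values_to = "value"
  )
}

#' Normalize projections for pooling across sessions
#'
#' Applies the session-normalization scheme used to pool trajectories:
#' activity along `CD_delay` is anchored on the 100 ms before the go cue so
#' the lick-left training mean maps to 0 and the lick-right mean to 1;
#' `CD_response` is anchored the same way on the 400 ms after the cue;
#' `D_go` (mean of both trial types) is anchored so the pre-cue mean (100 ms)
#' maps to 0 and the pre-to-post cue change (100 ms windows) to 1.
#'
#' When `anchors` is `NULL` they are computed from `trace` itself (the
#' training trials); pass the returned anchors to normalize held-out-trial
#' traces with the training constants.
#'
#' @param trace A `projection_trace` (condition columns `lick_right` /
#'   `lick_left` for the CD modes).
#' @param kind Normalization scheme; defaults to the trace's mode kind.
#' @param anchors Optional anchors from a previous (training) call.
#' @param tol Minimum |scale| below which the session is flagged
#'   non-normalizable.
#' @return The trace with normalized `values` and a `normalization` field
#'   (list with `offset`, `scale`, `kind`).
#' @export
normalize_projection <- function(trace, kind = trace$kind, anchors = NULL,
                                 tol = 1e-8) {
  stopifnot(inherits(trace, "projection_trace"))
  if (is.null(anchors)) {
    anchors <- switch(kind,
      CD_delay = cd_anchor(trace, c(-0.1, 0)),
      CD_response = cd_anchor(trace, c(0, 0.4)),
      D_go = dgo_anchor(trace, c(-0.1, 0), c(0, 0.1)),
      abort(sprintf("no normalization scheme for kind '%s'", kind),
            class = "popmodes_error")
    )
    anchors$kind <- kind
  }
  if (abs(anchors$scale) < tol) {
    abort("normalize_projection: anchor denominator below tolerance; session non-normalizable",
          class = "popmodes_ineligible")
  }
  trace$values <- (trace$values - anchors$offset) / anchors$scale
  trace$normalization <- anchors
  trace
}

cd_anchor <- function(trace, window) {
  if (!all(c("lick_right", "lick_left") %in% colnames(trace$values))) {
    abort("normalize_projection: need lick_right and lick_left conditions",
          class = "popmodes_error")
  }
  idx <- window_bins(trace$time, window, trace$bin_width)
  left <- mean(trace$values[idx, "lick_left"])
  right <- mean(trace$values[idx, "lick_right"])
  list(offset = left, scale = right - left, window = window)
}

dgo_anchor <- function(trace, pre_window, post_window) {
  idx_pre <- window_bins(trace$time, pre_window, trace$bin_width)
  idx_post <- window_bins(trace$time, post_window, trace$bin_width)
  m <- rowMeans(trace$values)
  pre <- mean(m[idx_pre])
  post <- mean(m[idx_post])
  list(offset = pre, scale = post - pre,
       window = c(pre_window[1], post_window[2]))
}

#' Split trials into mode-defining and projection halves
#'
#' Randomly selects a fraction (default 50%) of unperturbed correct trials of
#' each type to define the coding directions; the held-out remainder is used
#' for projections. The two halves are disjoint and type-balanced.
#'
#' @param trials Trial table.
#' @param fraction Training fraction in (0, 1).
#' @param seed RNG seed (split reproducible from the seed).
#' @return List with tibbles `train` and `test`.
#' @export
split_train_test <- function(trials, fraction = 0.5, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be in (0, 1)", class = "popmodes_error")
  }
  eligible <- select_trials(trials)
  types <- c("lick_right", "lick_left")
  n_by_type <- table(factor(eligible$type, levels = types))
  if (any(n_by_type < 2)) {
    abort_ineligible("split_train_test: need >= 2 unperturbed correct trials per type")
  }
  train_idx <- withr::with_seed(check_seed(seed), {
    unlist(lapply(types, function(ty) {
      idx <- which(eligible$type == ty)
      n_train <- max(1L, min(length(idx) - 1L, round(length(idx) * fraction)))
      idx[sample.int(length(idx), n_train)]
    }))
  })
  list(train = eligible[sort(train_idx), ],
       test = eligible[setdiff(seq_len(nrow(eligible)), train_idx), ])
}

#' Build a pseudopopulation PSTH pair across sessions
#'
#' Pools units recorded in different sessions as if simultaneously recorded:
#' cells are sampled with replacement, and for each cell disjoint train/test
#' sets of `trials_per_type` correct trials per lick direction are drawn from
#' its own session. Cells with fewer than `2 * trials_per_type` correct
#' trials per direction are excluded (logged in the `cells` attribute of the
#' result). Call repeatedly with different seeds for the resampling loop.
#'
#' @param sessions List of `session_data` objects.
#' @param n_cells Number of cells to sample with replacement.
#' @param trials_per_type Trials per direction in each of the train and test
#'   sets.
#' @param seed RNG seed.
#' @param window,bin_width,smoothing Passed to [compute_psth()].
#' @return List with `train` and `test` `psth_matrix` objects (pseudounits
#'   named by draw) and a `cells` tibble recording provenance.
#' @export
build_pseudopopulation <- function(sessions, n_cells, trials_per_type = 20,
                                   seed = 1L, window = c(-3.2, 1),
                                   bin_width = 0.01,
                                   smoothing = "boxcar_centered_100ms") {
  seed <- check_seed(seed)
  pool <- purrr::map_dfr(seq_along(sessions), function(si) {
    s <- sessions[[si]]
    correct <- select_trials(s$trials)
    n_r <- sum(correct$type == "lick_right")
    n_l <- sum(correct$type == "lick_left")
    tibble::tibble(session = si, unit_id = s$units$unit_id,
                   eligible = n_r >= 2 * trials_per_type & n_l >= 2 * trials_per_type)
  })
  eligible_pool <- pool[pool$eligible, ]
  if (nrow(eligible_pool) == 0) {
    abort_ineligible("build_pseudopopulation: no eligible cells")
  }
  n_bins <- round((window[2] - window[1]) / bin_width)
  withr::with_seed(seed, {
    draws <- sample.int(nrow(eligible_pool), n_cells, replace = TRUE)
    train_rates <- array(0, c(n_cells, n_bins, 2))
    test_rates <- array(0, c(n_cells, n_bins, 2))
    time <- NULL
    epochs <- NULL
    for (k in seq_len(n_cells)) {
      row <- eligible_pool[draws[k], ]
      s <- sessions[[row$session]]
      correct <- select_trials(s$trials)
      picked <- lapply(c("lick_right", "lick_left"), function(ty) {
        idx <- which(correct$type == ty)
        idx[sample.int(length(idx), 2 * trials_per_type)]
      })
      train_tr <- correct[sort(c(picked[[1]][seq_len(trials_per_type)],
                                 picked[[2]][seq_len(trials_per_type)])), ]
      test_tr <- correct[sort(c(picked[[1]][-seq_len(trials_per_type)],
                                picked[[2]][-seq_len(trials_per_type)])), ]
      p_train <- compute_psth(s, train_tr, window = window, bin_width = bin_width,
                              smoothing = smoothing, units = row$unit_id)
      p_test <- compute_psth(s, test_tr, window = window, bin_width = bin_width,
                             smoothing = smoothing, units = row$unit_id)
      train_rates[k, , ] <- p_train$rates[1, , c("lick_left", "lick_right")]
      test_rates[k, , ] <- p_test$rates[1, , c("lick_left", "lick_right")]
      if (is.null(time)) {
        time <- p_train$time
        epochs <- p_train$epochs
      }
    }
    ids <- sprintf("pseudo%04d", seq_len(n_cells))
    make_psth <- function(rates, n_tr) {
      dimnames(rates) <- list(ids, NULL, c("lick_left", "lick_right"))
      structure(
        list(rates = rates, time = time, bin_width = bin_width,
             smoothing = smoothing, alignment = "t_go",
             conditions = c("lick_left", "lick_right"),
             n_trials = c(lick_left = n_tr, lick_right = n_tr),
             unit_ids = ids, epochs = epochs),
        class = "psth_matrix"
      )
    }
    cells <- tibble::tibble(
      pseudo_id = ids,
      session = eligible_pool$session[draws],
      unit_id = eligible_pool$unit_id[draws]
    )
    out <- list(train = make_psth(train_rates, trials_per_type),
                test = make_psth(test_rates, trials_per_type),
                cells = cells,
                excluded = pool[!pool$eligible, c("session", "unit_id")])
    out
  })
}
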