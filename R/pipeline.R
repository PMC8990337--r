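#' Configuration for an end-to-end analysis run
#'
#' @param sim A [sim_config()] describing the input dataset (simulated), or
#'   `NULL` when `sessions` are passed to [run_analysis()] directly.
#' @param split_fraction Training fraction for the mode-defining /
#'   projection trial split.
#' @param bin_width PSTH bin width (s) for full-epoch analyses.
#' @param psth_window Full-epoch analysis window (s relative to the cue).
#' @param min_rate Exclusion threshold: units with session-mean rate below
#'   this (spikes/s, strict `<`) over analyzed trials are excluded.
#' @param min_cells Sessions with fewer eligible cells are skipped.
#' @param latency_subsample Correct trials per type for single-unit latency
#'   and selectivity tests (40 in the standard protocol; reduced
#'   automatically when a session has fewer).
#' @param roc_bin ROC decoding bin width (s).
#' @param corr_bin Bin width (s) for the trial-by-trial mode correlation.
#' @param n_boot Bootstrap iterations for session-level summaries.
#' @param seed Master analysis seed (trial splits, subsamples, bootstraps).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), split_fraction = 0.5,
                       bin_width = 0.01, psth_window = c(-3.2, 1.4),
                       min_rate = 2, min_cells = 5, latency_subsample = 40,
                       roc_bin = 0.05, corr_bin = 0.1, n_boot = 200,
                       seed = 1L, out_dir = NULL) {
  structure(
    list(sim = sim, split_fraction = split_fraction, bin_width = bin_width,
         psth_window = psth_window, min_rate = min_rate,
         min_cells = min_cells, latency_subsample = latency_subsample,
         roc_bin = roc_bin, corr_bin = corr_bin, n_boot = n_boot,
         seed = check_seed(seed), out_dir = out_dir),
    class = "run_config"
  )
}

# Session gate: >= min_cells units and significant pre-cue selectivity
# (rank-sum on per-trial projections onto the pre-cue rate-difference
# pattern, 100 ms window, p < 0.05).
session_eligible <- function(session, unit_ids, trials, min_cells = 5) {
  if (length(unit_ids) < min_cells) {
    return(list(ok = FALSE, reason = sprintf("fewer than %d cells", min_cells)))
  }
  rv <- trial_rate_vectors(session, trials, c(-0.1, 0), units = unit_ids)
  right <- trials$type == "lick_right"
  w <- colMeans(rv[right, , drop = FALSE]) - colMeans(rv[!right, , drop = FALSE])
  if (sum(w^2) == 0) {
    return(list(ok = FALSE, reason = "no pre-cue selectivity"))
  }
  proj <- as.numeric(rv %*% w)
  p <- ranksum_test(proj[right], proj[!right])
  if (is.na(p) || p >= 0.05) {
    return(list(ok = FALSE, reason = "pre-cue selectivity not significant"))
  }
  list(ok = TRUE, reason = NA_character_)
}

# Per-trial projections of window-mean rates in consecutive bins.
binned_trial_projections <- function(session, trials, mode, windows) {
  vapply(windows, function(w) {
    rv <- trial_rate_vectors(session, trials, w, units = mode$unit_ids)
    project(rv, mode)
  }, numeric(nrow(trials)))
}

seq_windows <- function(from, to, by) {
  starts <- seq(from, to - by + 1e-9, by = by)
  lapply(starts, function(s) c(s, s + by))
}

analyze_session <- function(session, cfg, seeds) {
  exclusions <- list()
  log_excl <- function(entity, id, rule) {
    exclusions[[length(exclusions) + 1L]] <<-
      tibble::tibble(entity = entity, id = as.character(id), rule = rule)
  }

  kept <- filter_units(session$units)
  for (i in seq_len(nrow(filter_rejections(kept)))) {
    rej <- filter_rejections(kept)
    log_excl("unit", rej$unit_id[i], paste0("quality:", rej$criterion[i]))
  }
  correct <- select_trials(session$trials)
  for (id in setdiff(session$trials$trial_index, correct$trial_index)) {
    log_excl("trial", id, "not unperturbed correct")
  }
  if (nrow(correct) == 0 || nrow(kept) == 0) {
    return(list(skipped = TRUE, reason = "no analyzable units/trials",
                exclusions = dplyr::bind_rows(exclusions)))
  }
  rates <- trial_rate_vectors(session, correct, cfg$psth_window,
                              units = kept$unit_id)
  mean_rate <- colMeans(rates)
  low <- names(mean_rate)[mean_rate < cfg$min_rate]
  for (id in low) log_excl("unit", id, sprintf("mean rate < %g spikes/s", cfg$min_rate))
  unit_ids <- setdiff(kept$unit_id, low)

  gate <- session_eligible(session, unit_ids, correct, cfg$min_cells)
  if (!gate$ok) {
    log_excl("session", paste(session$animal_id, session$session_id, sep = "/"),
             gate$reason)
    return(list(skipped = TRUE, reason = gate$reason,
                exclusions = dplyr::bind_rows(exclusions)))
  }

  split <- split_train_test(session$trials, cfg$split_fraction, seed = seeds[1])
  psth_train <- compute_psth(session, split$train, window = cfg$psth_window,
                             bin_width = cfg$bin_width, units = unit_ids)
  psth_test <- compute_psth(session, split$test, window = cfg$psth_window,
                            bin_width = cfg$bin_width, units = unit_ids)
  cd_delay <- compute_cd_delay(psth_train)
  cd_response <- compute_cd_response(psth_train, cd_delay = cd_delay)
  d_go <- compute_d_go(psth_train)
  d_ramp <- compute_d_ramp(psth_train)
  modes <- orthogonalize_set(
    list(CD_delay = cd_delay, CD_response = cd_response,
         D_go = d_go, D_ramp = d_ramp))

  train_proj <- lapply(modes, function(m) project(psth_train, m))
  test_proj <- lapply(modes, function(m) project(psth_test, m))
  norm_test <- list()
  for (kind in c("CD_delay", "CD_response", "D_go")) {
    tr <- normalize_projection(train_proj[[kind]], kind)
    norm_test[[kind]] <- normalize_projection(test_proj[[kind]], kind,
                                              anchors = tr$normalization)
  }

  # fine-binned peri-cue projection latency for D_go on held-out trials
  psth_fine <- compute_psth(session, split$test, window = c(-0.2, 0.2),
                            bin_width = 0.002, smoothing = "none",
                            units = unit_ids)
  dgo_lat <- projection_latency(project(psth_fine, modes$D_go))

  sel_expl <- selectivity_explained(
    psth_test, modes[c("CD_delay", "CD_response")], window = c(-0.6, 0.4))

  roc_windows <- seq_windows(-0.6, 0.6, cfg$roc_bin)
  roc <- purrr::map_dfr(c("CD_delay", "CD_response", "D_go"), function(kind) {
    pr <- binned_trial_projections(session, split$test, modes[[kind]], roc_windows)
    out <- roc_decode(pr, split$test$type,
                      time = vapply(roc_windows, mean, numeric(1)))
    out$mode <- kind
    out
  })

  pre_w <- seq_windows(-0.6, 0, cfg$corr_bin)
  post_w <- seq_windows(0, 0.4, cfg$corr_bin)
  # within one trial type, as in the trial-by-trial coupling analysis --
  # across types the selectivity itself would induce correlation
  right_test <- split$test[split$test$type == "lick_right", ]
  tmc <- trial_mode_correlation(
    binned_trial_projections(session, right_test, modes$CD_delay, pre_w),
    binned_trial_projections(session, right_test, modes$CD_response, post_w),
    seed = seeds[2])

  n_sub <- min(cfg$latency_subsample,
               min(table(factor(correct$type, c("lick_right", "lick_left")))))
  lat_trials <- select_trials(session$trials, subsample_n = n_sub,
                              seed = seeds[3])
  latencies <- purrr::map_dfr(unit_ids, function(uid) {
    pc <- pooled_cue_counts(session, uid, lat_trials)
    res <- neuron_go_latency(pc$counts, pc$time, pc$n_trials)
    res$unit_id <- uid
    res
  })

  list(
    skipped = FALSE,
    animal_id = session$animal_id, session_id = session$session_id,
    unit_ids = unit_ids, modes = modes,
    projections = norm_test, selectivity_explained = sel_expl,
    d_go_latency = dgo_lat, roc = roc, trial_correlation = tmc,
    unit_latencies = latencies, split = split,
    exclusions = dplyr::bind_rows(exclusions)
  )
}

#' Run the full analysis pipeline
#'
#' Simulate (or take) a multi-session dataset and run every stage in fixed
#' order for each session: unit quality filtering, low-rate exclusion, the
#' session eligibility gate, the train/test trial split, mode estimation and
#' Gram-Schmidt orthogonalization, held-out projections with session
#' normalization, projection and single-unit latencies, ROC decoding and the
#' trial-by-trial mode correlation. Every excluded unit, trial or session is
#' logged with the rule that triggered it. A rerun with the same config
#' reproduces the outputs exactly.
#'
#' @param config A [run_config()].
#' @param sessions Optional named list of `session_data` (overrides
#'   simulation).
#' @return List of class `report_bundle`: per-session results, the pooled
#'   exclusion log, summary tibbles and (when simulated) the dataset bundle.
#' @export
run_analysis <- function(config = run_config(), sessions = NULL) {
  stopifnot(inherits(config, "run_config"))
  bundle <- NULL
  if (is.null(sessions)) {
    if (is.null(config$sim)) {
      abort("run_analysis: no input (neither `sessions` nor `config$sim`)",
            class = "popmodes_error")
    }
    bundle <- simulate_dataset(config$sim)
    sessions <- bundle$sessions
  }
  seeds <- matrix(derive_seeds(config$seed, 8L * length(sessions)),
                  nrow = length(sessions))
  results <- vector("list", length(sessions))
  names(results) <- names(sessions) %||%
    vapply(sessions, function(s) paste(s$animal_id, s$session_id, sep = "/"),
           character(1))
  for (i in seq_along(sessions)) {
    results[[i]] <- analyze_session(sessions[[i]], config, seeds[i, ])
  }
  analyzed <- results[!vapply(results, function(r) r$skipped, logical(1))]
  summary_tbl <- purrr::map_dfr(names(analyzed), function(key) {
    r <- analyzed[[key]]
    agg <- attr(r$selectivity_explained, "aggregate")
    tibble::tibble(
      session = key, n_units = length(r$unit_ids),
      selectivity_explained = unname(agg["total"]),
      d_go_latency_ms = r$d_go_latency$latency_ms,
      mean_coupling_r = mean(r$trial_correlation$r),
      mean_auc_precue = mean(r$roc$auc[r$roc$mode == "CD_delay" & r$roc$time < 0])
    )
  })
  out <- structure(
    list(config = config, results = results, summary = summary_tbl,
         exclusions = purrr::map_dfr(results, "exclusions"),
         dataset = bundle),
    class = "report_bundle"
  )
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", length(x$results), " session(s), ",
      nrow(x$summary), " analyzed\n", sep = "")
  print(x$summary)
  invisible(x)
}

# Each file is written to a temp path then renamed, so a crash never leaves
# a half-written artifact under its final name.
write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_atomic(function(p) fmt_csv(bundle$summary, p),
               file.path(out_dir, "summary.csv"))
  write_atomic(function(p) fmt_csv(bundle$exclusions, p),
               file.path(out_dir, "exclusions.csv"))
  lat <- purrr::map_dfr(names(bundle$results), function(key) {
    r <- bundle$results[[key]]
    if (r$skipped) return(NULL)
    dplyr::mutate(r$unit_latencies, session = key)
  })
  write_atomic(function(p) fmt_csv(lat, p),
               file.path(out_dir, "unit_latencies.csv"))
  weights <- purrr::map_dfr(names(bundle$results), function(key) {
    r <- bundle$results[[key]]
    if (r$skipped) return(NULL)
    dplyr::mutate(purrr::map_dfr(r$modes, as_tibble), session = key)
  })
  write_atomic(function(p) fmt_csv(weights, p),
               file.path(out_dir, "mode_weights.csv"))
  cfg <- bundle$config
  cfg$sim <- unclass(cfg$sim)
  write_atomic(
    function(p) jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("popmodes")),
           config = unclass(cfg)),
      p, auto_unbox = TRUE, digits = NA, null = "null"),
    file.path(out_dir, "run_config.json"))
  invisible(out_dir)
}

#' Ground-truth recovery metrics for a simulated run
#'
#' Compares estimated quantities with the planted simulation parameters:
#' cosine similarity of `CD_delay` (and orthogonalized `CD_response`) with
#' the planted selectivity patterns, single-unit latency bias and RMSE for
#' detected go-up cells, pre-cue decoding AUC and the trial-gain coupling.
#'
#' @param bundle A `report_bundle` from a simulated [run_analysis()].
#' @param ground_truth The dataset's ground truth (defaults to the bundle's
#'   own simulated dataset).
#' @return Tibble, one row per analyzed session.
#' @export
recovery_report <- function(bundle, ground_truth = NULL) {
  stopifnot(inherits(bundle, "report_bundle"))
  truth <- ground_truth %||% bundle$dataset$ground_truth
  if (is.null(truth)) {
    abort("recovery_report: run did not use simulated input", class = "popmodes_error")
  }
  purrr::map_dfr(names(bundle$results), function(key) {
    r <- bundle$results[[key]]
    if (r$skipped) return(NULL)
    tu <- truth[[key]]$units
    tu <- tu[match(r$unit_ids, tu$unit_id), ]
    pat <- planted_mode_patterns(tu, bundle$config$sim)
    planted_delay <- pat$delay
    planted_resp_orth <- pat$response_orth
    lat <- dplyr::left_join(
      r$unit_latencies[r$unit_latencies$direction %in% "up", ],
      tu[, c("unit_id", "go_latency_ms")], by = "unit_id")
    err <- lat$latency_ms - lat$go_latency_ms
    err <- err[!is.na(err)]
    tibble::tibble(
      session = key,
      cd_delay_cosine = abs(mode_cosine(r$modes$CD_delay, planted_delay)),
      cd_response_cosine = if (sum(planted_resp_orth^2) > 0)
        abs(mode_cosine(r$modes$CD_response, planted_resp_orth)) else NA_real_,
      latency_bias_ms = if (length(err)) mean(err) else NA_real_,
      latency_rmse_ms = if (length(err)) sqrt(mean(err^2)) else NA_real_,
      n_latency_cells = length(err),
      mean_auc_precue = bundle$summary$mean_auc_precue[bundle$summary$session == key],
      mean_coupling_r = bundle$summary$mean_coupling_r[bundle$summary$session == key]
    )
  })
}
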