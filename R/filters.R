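#' Unit quality filtering
#'
#' Applies the post-hoc sorting quality thresholds used for extracellular
#' recordings: amplitude > 100 uV, ISI violation < 0.5, amplitude cutoff
#' < 0.1, SNR > 2.5, spike width < 1.2 ms and presence ratio > 0.95 (all
#' strict inequalities). Profiles add a cell-class criterion on spike width:
#' `alm_pyramidal` keeps putative pyramidal neurons (width > 0.5 ms),
#' `thalamus` keeps width > 0.35 ms, `snr` (substantia nigra pars reticulata)
#' keeps width < 0.35 ms, `generic` adds nothing.
#'
#' @param units Tibble of unit metadata (see [new_session_data()]). A missing
#'   metric column is an error, never a silent pass.
#' @param profile One of `"generic"`, `"alm_pyramidal"`, `"thalamus"`, `"snr"`.
#'
#' @return The kept units (tibble). The rejection log -- one row per failed
#'   (unit, criterion) pair -- is attached as attribute `"rejections"` and
#'   also available via [filter_rejections()].
#' @export
filter_units <- function(units, profile = c("generic", "alm_pyramidal",
                                            "thalamus", "snr")) {
  profile <- match.arg(profile)
  units <- tibble::as_tibble(units)
  criteria <- list(
    amplitude_uv = function(x) x > 100,
    isi_violation = function(x) x < 0.5,
    amplitude_cutoff = function(x) x < 0.1,
    snr = function(x) x > 2.5,
    spike_width_ms = function(x) x < 1.2,
    presence_ratio = function(x) x > 0.95
  )
  extra <- switch(profile,
    alm_pyramidal = list(spike_width_class = function(u) u$spike_width_ms > 0.5),
    thalamus = list(spike_width_class = function(u) u$spike_width_ms > 0.35),
    snr = list(spike_width_class = function(u) u$spike_width_ms < 0.35),
    list()
  )
  missing <- setdiff(names(criteria), names(units))
  if (length(missing)) {
    abort(paste("filter_units: missing quality metric(s):",
                paste(missing, collapse = ", ")), class = "popmodes_error")
  }
  pass <- rep(TRUE, nrow(units))
  rejections <- list()
  for (metric in names(criteria)) {
    ok <- criteria[[metric]](units[[metric]])
    if (anyNA(ok)) {
      abort(sprintf("filter_units: metric `%s` contains NA", metric),
            class = "popmodes_error")
    }
    if (any(!ok)) {
      rejections[[metric]] <- tibble::tibble(
        unit_id = units$unit_id[!ok], criterion = metric,
        value = units[[metric]][!ok]
      )
    }
    pass <- pass & ok
  }
  for (nm in names(extra)) {
    ok <- extra[[nm]](units)
    if (any(!ok)) {
      rejections[[nm]] <- tibble::tibble(
        unit_id = units$unit_id[!ok], criterion = paste0(nm, "_", profile),
        value = units$spike_width_ms[!ok]
      )
    }
    pass <- pass & ok
  }
  log <- if (length(rejections)) dplyr::bind_rows(rejections) else
    tibble::tibble(unit_id = character(), criterion = character(), value = numeric())
  out <- units[pass, ]
  attr(out, "rejections") <- log
  out
}

#' @rdname filter_units
#' @param filtered Output of [filter_units()].
#' @export
filter_rejections <- function(filtered) {
  attr(filtered, "rejections") %||%
    tibble::tibble(unit_id = character(), criterion = character(), value = numeric())
}

#' Select and optionally subsample trials
#'
#' Trial selection for all downstream analyses. Early-lick trials are always
#' excluded unless `"early_lick"` is explicitly requested in `outcomes`.
#' When `subsample_n` is given, exactly `subsample_n` trials per trial type
#' are drawn without replacement (reproducibly from `seed`); a type with too
#' few qualifying trials raises a `popmodes_ineligible` condition so the
#' caller can exclude the unit or session rather than crash.
#'
#' @param trials Trial table of a `session_data`.
#' @param types Trial types to keep (default both lick directions).
#' @param outcomes Outcomes to keep (default `"correct"`).
#' @param perturbation Perturbation labels to keep (default `"none"`).
#' @param subsample_n Per-type subsample size, or `NULL` for all qualifying
#'   trials. `0` returns an empty selection.
#' @param seed RNG seed for the subsample.
#'
#' @return Tibble of selected trials.
#' @export
select_trials <- function(trials, types = c("lick_right", "lick_left"),
                          outcomes = "correct", perturbation = "none",
                          subsample_n = NULL, seed = 1L) {
  keep <- trials$type %in% types &
    trials$outcome %in% outcomes &
    trials$perturbation %in% perturbation
  if (!"early_lick" %in% outcomes) keep <- keep & trials$outcome != "early_lick"
  out <- trials[keep, ]
  if (is.null(subsample_n)) return(out)
  subsample_n <- check_count(subsample_n, "subsample_n", min = 0)
  if (subsample_n == 0L) return(out[0, ])
  picks <- withr::with_seed(check_seed(seed), {
    lapply(types, function(ty) {
      idx <- which(out$type == ty)
      if (length(idx) < subsample_n) {
        abort_ineligible(sprintf(
          "select_trials: %d qualifying '%s' trials, need %d",
          length(idx), ty, subsample_n))
      }
      idx[sample.int(length(idx), subsample_n)]
    })
  })
  out[sort(unlist(picks)), ]
}
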