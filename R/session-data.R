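#' Construct a trial-aligned session container
#'
#' A `session_data` bundles one recording session: unit metadata, a long
#' spike table, and a trial table with event times and labels. All analysis
#' functions in the package consume this container.
#'
#' @param animal_id,session_id Identity labels (character scalars).
#' @param units Tibble of unit metadata; must contain `unit_id` (unique) and,
#'   for quality filtering, the sorting metrics (`amplitude_uv`,
#'   `isi_violation`, `amplitude_cutoff`, `snr`, `spike_width_ms`,
#'   `presence_ratio`).
#' @param spikes Tibble with columns `unit_id`, `spike_time` (seconds on the
#'   session clock, nonnegative). Sorted internally per unit.
#' @param trials Tibble with `trial_index`, `type`, `outcome`,
#'   `perturbation`, `t_sample_on`, `t_delay_on`, `t_go` and optional
#'   `first_lick_time`, `first_lick_direction`.
#'
#' @return An object of class `session_data`.
#' @export
new_session_data <- function(animal_id, session_id, units, spikes, trials) {
  units <- tibble::as_tibble(units)
  spikes <- tibble::as_tibble(spikes)
  trials <- tibble::as_tibble(trials)
  if (anyDuplicated(units$unit_id)) {
    abort("units: `unit_id` must be unique", class = "popmodes_error")
  }
  if (!all(c("unit_id", "spike_time") %in% names(spikes))) {
    abort("spikes: need columns `unit_id`, `spike_time`", class = "popmodes_error")
  }
  if (nrow(spikes) > 0) {
    if (any(spikes$spike_time < 0)) {
      abort("spikes: `spike_time` must be nonnegative", class = "popmodes_error")
    }
    if (!all(spikes$unit_id %in% units$unit_id)) {
      abort("spikes: unknown `unit_id`", class = "popmodes_error")
    }
    spikes <- dplyr::arrange(spikes, .data$unit_id, .data$spike_time)
  }
  need <- c("trial_index", "type", "outcome", "t_sample_on", "t_delay_on", "t_go")
  if (!all(need %in% names(trials))) {
    abort(paste("trials: need columns", paste(need, collapse = ", ")),
          class = "popmodes_error")
  }
  if (!all(trials$t_sample_on < trials$t_delay_on & trials$t_delay_on < trials$t_go)) {
    abort("trials: require t_sample_on < t_delay_on < t_go", class = "popmodes_error")
  }
  bad_type <- setdiff(unique(trials$type), c("lick_right", "lick_left"))
  if (length(bad_type)) {
    abort(paste("trials: unknown type:", paste(bad_type, collapse = ", ")),
          class = "popmodes_error")
  }
  bad_out <- setdiff(unique(trials$outcome),
                     c("correct", "incorrect", "no_response", "early_lick"))
  if (length(bad_out)) {
    abort(paste("trials: unknown outcome:", paste(bad_out, collapse = ", ")),
          class = "popmodes_error")
  }
  if (!"perturbation" %in% names(trials)) trials$perturbation <- "none"
  structure(
    list(animal_id = animal_id, session_id = session_id,
         units = units, spikes = spikes, trials = trials),
    class = "session_data"
  )
}

#' @export
print.session_data <- function(x, ...) {
  cat("<session_data> ", x$animal_id, "/", x$session_id, ": ",
      nrow(x$units), " units, ", nrow(x$spikes), " spikes, ",
      nrow(x$trials), " trials\n", sep = "")
  invisible(x)
}

# readr writes doubles with full precision; round-trips are exact.
fmt_csv <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
}

#' Read / write the on-disk session format
#'
#' A session is stored as a directory containing `units.csv`, `spikes.csv`,
#' `trials.csv` and `session.json` (identity labels). The round trip
#' `read_session(write_session(x))` is lossless.
#'
#' @param session A `session_data` object.
#' @param path Directory to write to / read from.
#' @return `write_session` returns `path` invisibly; `read_session` returns a
#'   `session_data`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_data"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fmt_csv(session$units, file.path(path, "units.csv"))
  fmt_csv(session$spikes, file.path(path, "spikes.csv"))
  fmt_csv(session$trials, file.path(path, "trials.csv"))
  jsonlite::write_json(
    list(animal_id = session$animal_id, session_id = session$session_id),
    file.path(path, "session.json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  for (f in c("units.csv", "spikes.csv", "trials.csv", "session.json")) {
    if (!file.exists(file.path(path, f))) {
      abort(sprintf("malformed session directory: missing %s", f),
            class = "popmodes_parse_error")
    }
  }
  meta <- jsonlite::read_json(file.path(path, "session.json"))
  read_tbl <- function(file, spec) {
    out <- tryCatch(
      suppressWarnings(
        readr::read_csv(file.path(path, file), col_types = spec,
                        progress = FALSE)),
      error = function(e) {
        abort(sprintf("failed to parse %s: %s", file, conditionMessage(e)),
              class = "popmodes_parse_error")
      }
    )
    probs <- readr::problems(out)
    if (nrow(probs) > 0) {
      abort(sprintf("failed to parse %s (column `%s`)", file,
                    paste(unique(probs$col %||% "?"), collapse = ", ")),
            class = "popmodes_parse_error")
    }
    out
  }
  units <- read_tbl("units.csv", readr::cols(unit_id = "c", .default = "?"))
  spikes <- read_tbl("spikes.csv", readr::cols(unit_id = "c", spike_time = "d"))
  trials <- read_tbl("trials.csv", readr::cols(
    trial_index = "i", type = "c", outcome = "c", perturbation = "c",
    first_lick_direction = "c", .default = "d"
  ))
  new_session_data(meta$animal_id, meta$session_id, units, spikes, trials)
}
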