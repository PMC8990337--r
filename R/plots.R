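#' Plot a projection trace
#'
#' One line per condition, time relative to the go cue (dashed line at 0).
#'
#' @param object A `projection_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot projection_trace
#' @export
autoplot.projection_trace <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$condition)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from go cue (s)",
                  y = paste0("activity along ", object$kind,
                             if (!is.null(object$normalization)) " (normalized)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot condition-average PSTHs
#'
#' Population-mean rate per condition over time.
#'
#' @param object A `psth_matrix`.
#' @param units Optional subset of unit ids (default: population mean).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psth_matrix
#' @export
autoplot.psth_matrix <- function(object, units = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(units)) df <- df[df$unit_id %in% units, ]
  df <- dplyr::summarise(dplyr::group_by(df, .data$time, .data$condition),
                         rate = mean(.data$rate), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$rate,
                                   colour = .data$condition)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0("time from ", object$alignment, " (s)"),
                  y = "spike rate (spikes/s)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the selectivity (or activity) explained per mode
#'
#' @param explained Output of [selectivity_explained()] or
#'   [activity_explained()].
#' @return A ggplot object.
#' @export
plot_explained <- function(explained) {
  ggplot2::ggplot(explained,
                  ggplot2::aes(.data$time, .data$fraction, colour = .data$mode)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time from go cue (s)", y = "fraction explained",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cumulative latency distribution across cells
#'
#' Empirical c.d.f. of single-unit latencies (fraction of all cells,
#' non-responders included in the denominator), optionally per area.
#'
#' @param latencies Tibble with `latency_ms` (NA for non-responders) and
#'   optionally an `area` column.
#' @return A ggplot object.
#' @export
plot_latency_cdf <- function(latencies) {
  has_area <- "area" %in% names(latencies)
  grp <- if (has_area) latencies$area else "all"
  df <- purrr::map_dfr(split(latencies$latency_ms, grp), function(l) {
    xs <- sort(l[!is.na(l)])
    tibble::tibble(latency_ms = xs, frac = seq_along(xs) / length(l))
  }, .id = "area")
  ggplot2::ggplot(df, ggplot2::aes(.data$latency_ms, .data$frac,
                                   colour = .data$area)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "latency from go cue (ms)", y = "fraction of cells",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
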