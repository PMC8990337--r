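# Nested index of rows by animal -> session, for hierarchical resampling.
hier_index <- function(data) {
  if (!all(c("animal_id", "session_id") %in% names(data))) {
    abort("hierarchical data needs `animal_id` and `session_id` columns",
          class = "popmodes_error")
  }
  by_animal <- split(seq_len(nrow(data)), data$animal_id)
  lapply(by_animal, function(rows) {
    split(rows, data$session_id[rows])
  })
}

# One three-level draw: animals with replacement, then sessions of each
# sampled animal with replacement, then trials within each sampled session
# with replacement. Returns row indices.
resample_hier <- function(idx) {
  animals <- sample.int(length(idx), replace = TRUE)
  unlist(lapply(animals, function(a) {
    sess <- idx[[a]]
    picked <- sample.int(length(sess), replace = TRUE)
    unlist(lapply(picked, function(s) {
      rows <- sess[[s]]
      rows[sample.int(length(rows), replace = TRUE)]
    }), use.names = FALSE)
  }), use.names = FALSE)
}

#' Hierarchical (animal / session / trial) bootstrap
#'
#' Nested resampling with replacement that respects the data hierarchy:
#' first animals, then sessions within each sampled animal, then trials
#' within each sampled session. The statistic is evaluated on each of
#' `n_iter` resampled datasets; the returned p-value is the one-sided
#' fraction of draws consistent with the null (floored at `1/n_iter`).
#'
#' With a single animal and session this reduces exactly to an ordinary
#' trial bootstrap.
#'
#' @param data Tibble with `animal_id` and `session_id` columns; rows are
#'   the trial-level records.
#' @param statistic Function `data -> scalar`.
#' @param n_iter Bootstrap iterations (1000 in the standard protocol).
#' @param seed RNG seed.
#' @param null_value Optional null value for the one-sided p-value.
#' @param alternative `"greater"` tests H1: statistic > null.
#' @param max_failures Draws on which `statistic` errors are rejected and
#'   redrawn implicitly (recorded); more than this many failures aborts.
#' @return Object of class `bootstrap_result`: point estimate, draws, 2.5
#'   and 97.5 percentiles, p-value, seed.
#' @export
hierarchical_bootstrap <- function(data, statistic, n_iter = 1000, seed = 1L,
                                   null_value = NULL,
                                   alternative = c("greater", "less"),
                                   max_failures = 50) {
  alternative <- match.arg(alternative)
  n_iter <- check_count(n_iter, "n_iter")
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) abort("empty data", class = "popmodes_error")
  idx <- hier_index(data)
  point <- statistic(data)
  failures <- 0L
  draws <- withr::with_seed(check_seed(seed), {
    vapply(seq_len(n_iter), function(i) {
      rows <- resample_hier(idx)
      val <- tryCatch(statistic(data[rows, , drop = FALSE]),
                      error = function(e) NA_real_)
      if (is.na(val)) failures <<- failures + 1L
      val
    }, numeric(1))
  })
  if (failures > max_failures) {
    abort(sprintf("statistic failed on %d bootstrap draws", failures),
          class = "popmodes_error")
  }
  ok <- draws[!is.na(draws)]
  p_value <- NA_real_
  if (!is.null(null_value)) {
    frac <- if (alternative == "greater") mean(ok <= null_value)
            else mean(ok >= null_value)
    p_value <- max(frac, 1 / n_iter)
  }
  structure(
    list(point_estimate = point, draws = draws,
         ci_low = unname(stats::quantile(ok, 0.025)),
         ci_high = unname(stats::quantile(ok, 0.975)),
         p_value = p_value, n_iter = n_iter, n_failed = failures,
         seed = seed, alternative = alternative, null_value = null_value),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> estimate ", signif(x$point_estimate, 4),
      " [", signif(x$ci_low, 4), ", ", signif(x$ci_high, 4), "] (",
      x$n_iter, " iterations",
      if (!is.na(x$p_value)) paste0("; one-sided p = ", signif(x$p_value, 3)),
      ")\n", sep = "")
  invisible(x)
}

#' @method tidy bootstrap_result
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$point_estimate,
    std.error = stats::sd(x$draws, na.rm = TRUE),
    conf.low = x$ci_low, conf.high = x$ci_high,
    p.value = x$p_value
  )
}

#' @method glance bootstrap_result
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble::tibble(n_iter = x$n_iter, n_failed = x$n_failed, seed = x$seed,
                 alternative = x$alternative)
}
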