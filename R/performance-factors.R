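#' Performance vs evidence magnitude, tower count, and duration
#'
#' Quantifies the relative contributions of evidence strength |#R - #L|,
#' total tower count #R + #L, and effective period duration to percent
#' correct. |delta| and total count are binned in groups of two, duration
#' (of the cue or the delay period) in 10-cm bins. For each mouse, percent
#' correct is computed for every 3-way bin combination and the mouse's
#' average performance subtracted; the mean-subtracted values are then
#' averaged across mice and a 3-parameter linear regression fitted, with
#' coefficient significance from the t statistic on n - p - 1 degrees of
#' freedom.
#'
#' @param trials Trial tibble.
#' @param period Which duration to use: effective cue duration (last minus
#'   first tower) or effective delay (stem end minus last tower).
#' @param min_trials_per_cell Bin combinations with fewer trials per mouse
#'   are dropped.
#' @return An object of class `performance_factors_fit` with `cells` (the
#'   across-mice averaged table) and `coefficients` (estimate, se, t,
#'   p-value, df per predictor). Single-mouse input is allowed but flagged
#'   in the `n_mice` field.
#' @export
performance_factors <- function(trials, period = c("cue", "delay"),
                                min_trials_per_cell = 5) {
  period <- match.arg(period)
  ev <- trial_evidence(effective_durations(trials))
  ev <- ev[ev$n_total > 0, , drop = FALSE]
  dur <- if (period == "cue") ev$effective_cue_cm else ev$effective_delay_cm
  ev$abs_delta_bin <- 2 * floor(abs(ev$delta) / 2) + 0.5
  ev$total_bin <- 2 * floor(ev$n_total / 2) + 0.5
  ev$duration_bin <- 10 * floor(dur / 10) + 5

  per_mouse <- dplyr::summarise(
    dplyr::group_by(ev, .data$mouse_id, .data$abs_delta_bin,
                    .data$total_bin, .data$duration_bin),
    percent_correct = 100 * mean(.data$outcome == "correct"),
    n = dplyr::n(), .groups = "drop_last"
  )
  per_mouse <- dplyr::ungroup(per_mouse)
  per_mouse <- per_mouse[per_mouse$n >= min_trials_per_cell, , drop = FALSE]
  mouse_mean <- dplyr::summarise(
    dplyr::group_by(per_mouse, .data$mouse_id),
    mouse_avg = sum(.data$percent_correct * .data$n) / sum(.data$n),
    .groups = "drop"
  )
  per_mouse <- dplyr::left_join(per_mouse, mouse_mean, by = "mouse_id")
  per_mouse$centered <- per_mouse$percent_correct - per_mouse$mouse_avg

  cells <- dplyr::summarise(
    dplyr::group_by(per_mouse, .data$abs_delta_bin, .data$total_bin,
                    .data$duration_bin),
    performance = mean(.data$centered),
    n_mice_cell = dplyr::n(),
    n_trials = sum(.data$n),
    .groups = "drop"
  )
  if (nrow(cells) < 5) abort("too few populated bin combinations")

  fit <- lm(performance ~ abs_delta_bin + total_bin + duration_bin,
            data = cells)
  sm <- summary(fit)$coefficients
  preds <- c("abs_delta_bin", "total_bin", "duration_bin")
  df <- nrow(cells) - length(preds) - 1
  coefs <- tibble::tibble(
    term = c("abs_delta", "total_towers", paste0(period, "_duration")),
    estimate = sm[preds, "Estimate"],
    se = sm[preds, "Std. Error"],
    t = sm[preds, "t value"],
    df = df,
    p_value = 2 * pt(-abs(sm[preds, "t value"]), df)
  )
  structure(
    list(cells = cells, coefficients = coefs, model = fit,
         n_mice = length(unique(per_mouse$mouse_id)), period = period),
    class = "performance_factors_fit"
  )
}

#' @export
print.performance_factors_fit <- function(x, ...) {
  cat(sprintf("Performance-factors fit (%d mice, %s period, %d cells)\n",
              x$n_mice, x$period, nrow(x$cells)))
  if (x$n_mice < 2) cat("  [flagged: single-mouse path]\n")
  print(x$coefficients)
  invisible(x)
}
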