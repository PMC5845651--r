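#' Apply the block-wise trial-selection criteria
#'
#' Selection proceeds block-wise: whole blocks (maximal runs of consecutive
#' same-maze-level trials within a session) with overall performance below
#' the threshold are removed; then trials with excess travel beyond the cap,
#' timed-out or aborted trials are dropped; then mice left with fewer than
#' the minimum number of trials are dropped entirely. Optionally the first k
#' trials of every block are removed (so each kept trial has k trials of
#' history) and sessions containing opto trials are dropped whole. Warm-up
#' and easy-block trials (maze_level < 11) are excluded unless
#' `include_warmup` is set.
#'
#' @param trials Trial tibble (see [trial_template()]).
#' @param criteria A [selection_criteria()].
#' @return A list with `trials` (the surviving tibble) and `exclusions`
#'   (a tibble of per-criterion excluded-trial counts). Errors if nothing
#'   survives.
#' @export
select_trials <- function(trials, criteria = selection_criteria()) {
  stopifnot(is.data.frame(trials))
  n0 <- nrow(trials)
  ledger <- list()
  note <- function(ledger, rule, n) c(ledger, stats::setNames(list(n), rule))

  if (!criteria$include_warmup) {
    keep <- trials$maze_level >= 11L
    ledger <- note(ledger, "non_main_maze", sum(!keep))
    trials <- trials[keep, , drop = FALSE]
  }

  if (criteria$exclude_opto_sessions && nrow(trials) > 0) {
    opto_key <- unique(paste(trials$mouse_id, trials$session_id)[trials$opto])
    keep <- !(paste(trials$mouse_id, trials$session_id) %in% opto_key)
    ledger <- note(ledger, "opto_session", sum(!keep))
    trials <- trials[keep, , drop = FALSE]
  }

  if (nrow(trials) > 0) {
    blocks <- dplyr::group_by(trials, .data$mouse_id, .data$session_id, .data$block_id)
    perf <- dplyr::summarise(blocks,
                             p = mean(.data$outcome == "correct"),
                             .groups = "drop")
    bad <- perf[perf$p < criteria$min_block_performance, , drop = FALSE]
    key <- paste(trials$mouse_id, trials$session_id, trials$block_id)
    keep <- !(key %in% paste(bad$mouse_id, bad$session_id, bad$block_id))
    ledger <- note(ledger, "low_performance_block", sum(!keep))
    trials <- trials[keep, , drop = FALSE]
  }

  if (nrow(trials) > 0) {
    keep <- trials$excess_travel_fraction <= criteria$max_excess_travel &
      !trials$timed_out & !trials$aborted
    ledger <- note(ledger, "bad_trial", sum(!keep))
    trials <- trials[keep, , drop = FALSE]
  }

  if (criteria$require_history_trials > 0 && nrow(trials) > 0) {
    k <- criteria$require_history_trials
    trials <- dplyr::group_by(trials, .data$mouse_id, .data$session_id, .data$block_id)
    trials <- dplyr::mutate(trials, .rank = dplyr::row_number())
    trials <- dplyr::ungroup(trials)
    keep <- trials$.rank > k
    ledger <- note(ledger, "insufficient_history", sum(!keep))
    trials <- trials[keep, , drop = FALSE]
    trials$.rank <- NULL
  }

  if (nrow(trials) > 0) {
    per_mouse <- table(trials$mouse_id)
    small <- names(per_mouse)[per_mouse < criteria$min_trials_per_mouse]
    keep <- !(trials$mouse_id %in% small)
    ledger <- note(ledger, "mouse_too_few_trials", sum(!keep))
    trials <- trials[keep, , drop = FALSE]
  }

  if (nrow(trials) == 0) {
    abort("no trials survive the selection criteria")
  }
  exclusions <- tibble::tibble(
    rule = names(ledger),
    n_excluded = as.integer(unlist(ledger))
  )
  exclusions <- dplyr::bind_rows(
    exclusions,
    tibble::tibble(rule = c("kept", "input"),
                   n_excluded = c(nrow(trials), n0))
  )
  list(trials = tibble::as_tibble(trials), exclusions = exclusions)
}

#' Effective cue and delay durations of a trial
#'
#' The effective cue duration is the distance between the last and the first
#' tower (both sides pooled); the effective delay is the stem length (300 cm)
#' minus the position of the last tower.
#'
#' @param trials Trial tibble.
#' @param stem_cm Stem length used for the delay calculation, cm.
#' @return The input with columns `effective_cue_cm` and
#'   `effective_delay_cm` appended; both are `NA` for zero-tower trials.
#' @export
effective_durations <- function(trials, stem_cm = 300) {
  pooled <- purrr::map2(trials$towers_left, trials$towers_right, c)
  first <- purrr::map_dbl(pooled, ~ if (length(.x) == 0) NA_real_ else min(.x))
  last <- purrr::map_dbl(pooled, ~ if (length(.x) == 0) NA_real_ else max(.x))
  dplyr::mutate(trials,
                effective_cue_cm = last - first,
                effective_delay_cm = stem_cm - last)
}

#' Drop bouts of low running performance
#'
#' Smooths the correct/error sequence with a Gaussian window (in trials) and
#' removes every trial whose smoothed running accuracy falls below the
#' threshold. The kernel is renormalized near the sequence edges.
#'
#' @param trials Trial tibble, in session order.
#' @param window_sigma_trials Gaussian sd of the smoothing window, trials.
#' @param threshold Running-accuracy threshold below which trials are
#'   removed.
#' @return A list with `trials` (survivors) and `removed_spans` (a tibble of
#'   removed index ranges per mouse/session). Errors if nothing survives.
#' @export
exclude_low_performance_bouts <- function(trials, window_sigma_trials = 10,
                                          threshold = 0.55) {
  if (window_sigma_trials <= 0) abort("`window_sigma_trials` must be positive.")
  groups <- dplyr::group_split(
    dplyr::group_by(trials, .data$mouse_id, .data$session_id)
  )
  kept <- list()
  spans <- list()
  for (g in groups) {
    g <- g[order(g$trial_index), , drop = FALSE]
    y <- as.numeric(g$outcome == "correct")
    n <- length(y)
    half <- ceiling(3 * window_sigma_trials)
    smooth <- vapply(seq_len(n), function(i) {
      idx <- max(1, i - half):min(n, i + half)
      w <- exp(-((idx - i)^2) / (2 * window_sigma_trials^2))
      sum(w * y[idx]) / sum(w)
    }, numeric(1))
    ok <- smooth >= threshold
    if (any(!ok)) {
      r <- rle(!ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      bad <- which(r$values)
      spans[[length(spans) + 1]] <- tibble::tibble(
        mouse_id = g$mouse_id[1], session_id = g$session_id[1],
        from = g$trial_index[starts[bad]], to = g$trial_index[ends[bad]]
      )
    }
    kept[[length(kept) + 1]] <- g[ok, , drop = FALSE]
  }
  out <- dplyr::bind_rows(kept)
  if (nrow(out) == 0) abort("no trials survive the running-performance filter")
  list(
    trials = out,
    removed_spans = if (length(spans) > 0) dplyr::bind_rows(spans) else
      tibble::tibble(mouse_id = character(), session_id = integer(),
                     from = integer(), to = integer())
  )
}
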