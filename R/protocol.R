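#' Session shaping state machine
#'
#' Every session starts in a visually-guided warm-up maze. The animal
#' advances to the main maze once it has run at least `warmup_min_trials`
#' warm-up trials at `warmup_min_accuracy` or better, with a side bias
#' (right minus left percent correct) of at most `warmup_max_bias` and at
#' least `warmup_min_good_fraction` good-quality trials (excess travel at
#' most 1.10). In the main maze, performance over a running window of
#' `window` trials is monitored: if it drops below `easy_entry_accuracy` the
#' animal is moved to an easier single-sided block of exactly
#' `easy_block_trials` trials, after which it returns to the main maze
#' regardless of performance.
#'
#' Maze levels: 0 = warm-up, 10 = easy block, 11 = main.
#'
#' @param warmup_min_trials,warmup_min_accuracy,warmup_max_bias,warmup_min_good_fraction
#'   Warm-up advancement rules.
#' @param window Running performance window length, trials.
#' @param easy_entry_accuracy Threshold below which the easy block starts.
#' @param easy_block_trials Fixed easy-block length, trials.
#' @return `new_protocol()` returns a `protocol_state` object whose `phase`
#'   is one of "warmup", "main", "easy_block".
#' @export
new_protocol <- function(warmup_min_trials = 10, warmup_min_accuracy = 0.85,
                         warmup_max_bias = 0.10, warmup_min_good_fraction = 0.75,
                         window = 40, easy_entry_accuracy = 0.55,
                         easy_block_trials = 10) {
  structure(
    list(
      warmup_min_trials = warmup_min_trials,
      warmup_min_accuracy = warmup_min_accuracy,
      warmup_max_bias = warmup_max_bias,
      warmup_min_good_fraction = warmup_min_good_fraction,
      window = window,
      easy_entry_accuracy = easy_entry_accuracy,
      easy_block_trials = easy_block_trials,
      phase = "warmup",
      warmup = tibble::tibble(correct = logical(0), side = character(0),
                              good = logical(0)),
      main_recent = logical(0),
      easy_remaining = 0L
    ),
    class = "protocol_state"
  )
}

#' @describeIn new_protocol Maze level (0, 10 or 11) the current phase
#'   presents.
#' @param state A `protocol_state`.
#' @export
protocol_maze_level <- function(state) {
  switch(state$phase, warmup = 0L, easy_block = 10L, main = 11L)
}

#' @describeIn new_protocol Advance the state machine with one finished
#'   trial. `correct`, `side` (rewarded side) and `good` (excess travel at
#'   most 1.10) describe the trial just run in the current phase.
#' @param correct Logical, was the trial correct?
#' @param side Rewarded side of the trial, "L" or "R".
#' @param good Logical, good-quality trial?
#' @export
protocol_step <- function(state, correct, side, good = TRUE) {
  stopifnot(inherits(state, "protocol_state"))
  if (state$phase == "warmup") {
    state$warmup <- dplyr::bind_rows(
      state$warmup,
      tibble::tibble(correct = correct, side = side, good = good)
    )
    w <- state$warmup
    if (nrow(w) >= state$warmup_min_trials) {
      acc <- mean(w$correct)
      p_r <- mean(w$correct[w$side == "R"])
      p_l <- mean(w$correct[w$side == "L"])
      bias <- abs(p_r - p_l)
      if (!is.nan(bias) && acc >= state$warmup_min_accuracy &&
          bias <= state$warmup_max_bias &&
          mean(w$good) >= state$warmup_min_good_fraction) {
        state$phase <- "main"
      }
    }
  } else if (state$phase == "main") {
    state$main_recent <- tail(c(state$main_recent, correct), state$window)
    if (length(state$main_recent) >= state$window &&
        mean(state$main_recent) < state$easy_entry_accuracy) {
      state$phase <- "easy_block"
      state$easy_remaining <- state$easy_block_trials
      state$main_recent <- logical(0)
    }
  } else { # easy_block: fixed length, performance ignored
    state$easy_remaining <- state$easy_remaining - 1L
    if (state$easy_remaining <= 0L) state$phase <- "main"
  }
  state
}
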