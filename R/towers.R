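#' Draw tower positions for one trial
#'
#' Counts on each side are drawn independently from Poisson distributions
#' (mean `mean_towers_rewarded` on the rewarded side, `mean_towers_minority`
#' on the other), capped at the packing limit of the cue region. If the
#' rewarded side does not end up with a strict majority the whole trial is
#' redrawn, so the rewarded side always holds the most towers. Positions are
#' placed uniformly over the cue region subject to the within-side
#' refractory spacing, by the exact gap transform: the spacing constraint is
#' absorbed by shrinking the span, drawing order statistics of uniforms, and
#' re-inflating.
#'
#' @param config A [maze_config()].
#' @param rewarded_side "L" or "R".
#' @return A list with `towers_left` and `towers_right`, sorted positions in
#'   cm.
#' @export
#' @examples
#' set.seed(1)
#' draw_towers(maze_config(), "R")
draw_towers <- function(config = maze_config(), rewarded_side = c("R", "L")) {
  rewarded_side <- match.arg(rewarded_side)
  counts <- draw_tower_counts(config)
  reward_n <- counts[1]
  minority_n <- counts[2]
  n_right <- if (rewarded_side == "R") reward_n else minority_n
  n_left <- if (rewarded_side == "R") minority_n else reward_n
  list(
    towers_left = place_towers(n_left, config),
    towers_right = place_towers(n_right, config)
  )
}

#' @describeIn draw_towers The count stage alone: returns
#'   `c(rewarded, minority)` after capping and the strict-majority redraw.
#'   `conditioned = FALSE` returns a single raw (uncapped, unconditioned)
#'   Poisson draw, which is what the nominal 7.7/2.3 means describe.
#' @param conditioned Apply the cap and strict-majority redraw.
#' @export
draw_tower_counts <- function(config = maze_config(), conditioned = TRUE) {
  cap <- max_towers_per_side(config)
  repeat {
    reward_n <- rpois(1, config$mean_towers_rewarded)
    minority_n <- rpois(1, config$mean_towers_minority)
    if (!conditioned) return(c(rewarded = reward_n, minority = minority_n))
    reward_n <- min(reward_n, cap)
    minority_n <- min(minority_n, cap)
    if (reward_n > minority_n) {
      return(c(rewarded = reward_n, minority = minority_n))
    }
  }
}

# Exact uniform-with-minimum-gap placement on [earliest, cue_end].
place_towers <- function(n, config) {
  if (n == 0) return(numeric(0))
  span <- config$cue_region_cm - config$earliest_tower_cm
  gap <- config$refractory_cm
  free <- span - (n - 1) * gap
  if (free < 0) abort("tower count exceeds the packing capacity")
  u <- sort(runif(n, 0, free))
  config$earliest_tower_cm + u + (seq_len(n) - 1) * gap
}

#' Simulate a batch of stimulus-only trials
#'
#' Draws `n` trials of towers with rewarded sides assigned by independent
#' fair coin flips (no debiasing), returning a trial tibble with choices
#' left empty. Useful for stimulus-statistics checks and as input to
#' open-loop agents.
#'
#' @param n Number of trials.
#' @param config A [maze_config()].
#' @return A trial tibble (choice and outcome columns set to `NA`).
#' @export
simulate_stimuli <- function(n, config = maze_config()) {
  sides <- ifelse(runif(n) < 0.5, "R", "L")
  draws <- lapply(sides, function(s) draw_towers(config, s))
  tibble::tibble(
    mouse_id = "sim",
    session_id = 1L,
    block_id = 1L,
    maze_level = 11L,
    trial_index = seq_len(n),
    towers_left = lapply(draws, `[[`, "towers_left"),
    towers_right = lapply(draws, `[[`, "towers_right"),
    rewarded_side = sides,
    choice = NA_character_,
    outcome = NA_character_,
    excess_travel_fraction = 1.0,
    timed_out = FALSE,
    aborted = FALSE,
    opto = FALSE
  )
}
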