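#' Simulate complete behavioral sessions
#'
#' Runs the full closed loop of the task: the shaping state machine decides
#' the maze (warm-up, main, or easy block), the debiaser draws the rewarded
#' side, towers are drawn from the capped Poisson process, the agent
#' chooses, and (optionally) a trajectory is generated. Warm-up and
#' easy-block trials present towers on the rewarded side only.
#'
#' @param agent An [agents] object making the choices.
#' @param n_sessions Number of sessions.
#' @param trials_per_session Trials per session.
#' @param config A [maze_config()].
#' @param trajectories Generate within-trial trajectories?
#' @param traj_params A [trajectory_params()].
#' @param mouse_id Mouse identifier stamped on every trial.
#' @param warmup Run the warm-up/easy-block shaping machinery (default);
#'   when `FALSE` every trial is a main-maze trial.
#' @param excess_travel_rate Fraction of trials flagged with excess travel
#'   beyond 110% of the maze length (drawn independently).
#' @return A list with `trials` (trial tibble), `truth` (sidecar tibble of
#'   per-trial ground-truth right-choice probabilities, `NA` for the
#'   Monte-Carlo accumulator agent), and `trajectories` (tibble or `NULL`).
#' @export
#' @examples
#' set.seed(1)
#' sim <- simulate_dataset(agent_k_tower(1), n_sessions = 1,
#'                         trials_per_session = 50, warmup = FALSE)
#' head(sim$trials)
simulate_dataset <- function(agent, n_sessions = 1, trials_per_session = 200,
                             config = maze_config(), trajectories = FALSE,
                             traj_params = trajectory_params(),
                             mouse_id = "sim", warmup = TRUE,
                             excess_travel_rate = 0.03) {
  n_max <- n_sessions * trials_per_session
  col_session <- integer(n_max)
  col_block <- integer(n_max)
  col_level <- integer(n_max)
  col_trial <- integer(n_max)
  col_left <- vector("list", n_max)
  col_right <- vector("list", n_max)
  col_side <- character(n_max)
  col_choice <- character(n_max)
  col_outcome <- character(n_max)
  col_excess <- numeric(n_max)
  truth <- numeric(n_max)
  trajs <- list()
  idx <- 0L
  for (s in seq_len(n_sessions)) {
    session_speed <- max(5, rnorm(1, traj_params$mean_speed_cm_s,
                                  traj_params$across_session_sd))
    protocol <- new_protocol()
    if (!warmup) protocol$phase <- "main"
    debias <- new_debiaser()
    prev_choice <- NA_character_
    prev_outcome <- NA_character_
    prev_level <- NA_integer_
    block_id <- 0L
    for (tr in seq_len(trials_per_session)) {
      level <- protocol_maze_level(protocol)
      if (is.na(prev_level) || level != prev_level) block_id <- block_id + 1L
      prev_level <- level
      side <- draw_trial_side(debias)
      cfg_trial <- config
      if (level < 11L) cfg_trial$mean_towers_minority <- 0
      tw <- draw_towers(cfg_trial, side)
      ans <- agent_choice(agent, tw$towers_left, tw$towers_right,
                          prev_choice, prev_outcome)
      outcome <- if (ans$choice == side) "correct" else "error"
      excess <- if (runif(1) < excess_travel_rate) {
        1.1 + stats::rexp(1, 5)
      } else {
        1 + runif(1, 0, 0.08)
      }
      idx <- idx + 1L
      col_session[idx] <- s
      col_block[idx] <- block_id
      col_level[idx] <- level
      col_trial[idx] <- tr
      col_left[[idx]] <- tw$towers_left
      col_right[[idx]] <- tw$towers_right
      col_side[idx] <- side
      col_choice[idx] <- ans$choice
      col_outcome[idx] <- outcome
      col_excess[idx] <- excess
      truth[idx] <- ans$p_right %||% NA_real_
      if (trajectories) {
        delta <- length(tw$towers_right) - length(tw$towers_left)
        tp <- traj_params
        tp$across_session_sd <- 0
        traj <- simulate_trajectory(
          ans$choice, delta, tp,
          speed_cm_s = max(5, rnorm(1, session_speed, tp$within_session_sd)),
          config = config
        )
        traj$mouse_id <- mouse_id
        traj$session_id <- s
        traj$trial_index <- tr
        trajs[[idx]] <- traj
      }
      debias <- debias_update(debias, side, outcome == "error")
      protocol <- protocol_step(protocol, outcome == "correct", side,
                                good = excess <= 1.10)
      prev_choice <- ans$choice
      prev_outcome <- outcome
    }
  }
  keep <- seq_len(idx)
  trials <- tibble::tibble(
    mouse_id = mouse_id, session_id = col_session[keep],
    block_id = col_block[keep], maze_level = col_level[keep],
    trial_index = col_trial[keep], towers_left = col_left[keep],
    towers_right = col_right[keep], rewarded_side = col_side[keep],
    choice = col_choice[keep], outcome = col_outcome[keep],
    excess_travel_fraction = col_excess[keep],
    timed_out = FALSE, aborted = FALSE, opto = FALSE
  )
  list(
    trials = trials,
    truth = tibble::tibble(
      mouse_id = trials$mouse_id, session_id = trials$session_id,
      trial_index = trials$trial_index, p_right = truth[seq_len(idx)]
    ),
    trajectories = if (trajectories) {
      dplyr::bind_rows(trajs)[, c("mouse_id", "session_id", "trial_index",
                                  "t", "x", "y", "view_angle")]
    } else {
      NULL
    }
  )
}
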