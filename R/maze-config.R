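#' Maze geometry and stimulus configuration
#'
#' Bundles the geometry of the virtual T-maze stem and the parameters of the
#' spatial-Poisson tower draw. Defaults describe the standard maze: a 330-cm
#' stem whose first 200 cm form the cue region and whose last 100 cm form a
#' cue-free delay region. Towers appear when the animal is 10 cm away (so the
#' earliest possible tower sits at y = 10 cm), live for 200 ms, and successive
#' towers on the same side are separated by at least a 12-cm refractory
#' distance. Counts are drawn per cue period with mean 7.7 on the rewarded
#' side and 2.3 on the minority side, i.e. an overall density of 5 towers/m.
#'
#' @param total_length_cm Stem length in cm.
#' @param cue_region_cm Length of the cue region (towers allowed), cm.
#' @param delay_region_cm Length of the delay region (no towers), cm.
#' @param start_buffer_cm Initial segment in which the view angle is clamped
#'   to zero, cm.
#' @param tower_visibility_trigger_cm Distance ahead at which a tower becomes
#'   visible, cm.
#' @param tower_lifetime_ms How long a tower stays visible, ms.
#' @param refractory_cm Minimum within-side spacing between towers, cm.
#' @param mean_towers_rewarded Poisson mean tower count on the rewarded side,
#'   per cue period.
#' @param mean_towers_minority Poisson mean tower count on the minority side,
#'   per cue period.
#' @param earliest_tower_cm Smallest possible tower position, cm.
#'
#' @return A list of class `maze_config`.
#' @seealso [maze_config_dat_cre()] for the 220/80-cm variant preset,
#'   [draw_towers()], [max_towers_per_side()].
#' @export
#' @examples
#' cfg <- maze_config()
#' max_towers_per_side(cfg)
maze_config <- function(total_length_cm = 330,
                        cue_region_cm = 200,
                        delay_region_cm = 100,
                        start_buffer_cm = 30,
                        tower_visibility_trigger_cm = 10,
                        tower_lifetime_ms = 200,
                        refractory_cm = 12,
                        mean_towers_rewarded = 7.7,
                        mean_towers_minority = 2.3,
                        earliest_tower_cm = 10) {
  cfg <- list(
    total_length_cm = total_length_cm,
    cue_region_cm = cue_region_cm,
    delay_region_cm = delay_region_cm,
    start_buffer_cm = start_buffer_cm,
    tower_visibility_trigger_cm = tower_visibility_trigger_cm,
    tower_lifetime_ms = tower_lifetime_ms,
    refractory_cm = refractory_cm,
    mean_towers_rewarded = mean_towers_rewarded,
    mean_towers_minority = mean_towers_minority,
    earliest_tower_cm = earliest_tower_cm
  )
  if (refractory_cm <= 0) abort("`refractory_cm` must be positive.")
  if (mean_towers_rewarded <= 0 || mean_towers_minority < 0) {
    abort("tower count means must be positive (minority may be zero).")
  }
  if (cue_region_cm + delay_region_cm > total_length_cm) {
    abort("cue + delay regions exceed the total maze length.")
  }
  structure(cfg, class = "maze_config")
}

#' @describeIn maze_config Preset for the variant maze used by the DAT-Cre
#'   cohort: 220-cm cue region, 80-cm delay, overall density 3.5 towers/m,
#'   14-cm refractory. Provided as a configuration only.
#' @export
maze_config_dat_cre <- function() {
  # 3.5 / m over 2.2 m = 7.7 total; keep the same ~77/23 majority split
  maze_config(
    cue_region_cm = 220, delay_region_cm = 80, refractory_cm = 14,
    mean_towers_rewarded = 7.7 * 0.77, mean_towers_minority = 7.7 * 0.23
  )
}

#' Largest per-side tower count the maze can hold
#'
#' The packing cap implied by the minimum within-side spacing: the largest
#' integer m such that m positions at pairwise distance >= `refractory_cm`
#' fit between `earliest_tower_cm` and the end of the cue region.
#'
#' @param config A [maze_config()].
#' @return Integer count.
#' @export
max_towers_per_side <- function(config = maze_config()) {
  span <- config$cue_region_cm - config$earliest_tower_cm
  1L + as.integer(floor(span / config$refractory_cm))
}

#' Trial-selection criteria
#'
#' Thresholds used to select analyzable trials: whole blocks below 60%
#' correct are dropped, trials with excess travel beyond 110% of the nominal
#' maze length (or timed-out/aborted trials) are removed, and mice must
#' retain at least 1,000 trials.
#'
#' @param min_block_performance Minimum overall fraction correct per block.
#' @param max_excess_travel Maximum traveled distance as a fraction of
#'   nominal maze length.
#' @param min_trials_per_mouse Minimum surviving trials for a mouse to be
#'   kept.
#' @param require_history_trials Drop this many trials at the start of every
#'   block (so each kept trial has that much within-block history).
#' @param exclude_opto_sessions Drop whole sessions containing opto trials
#'   (keeps consecutive-trial structure intact for history analyses).
#' @param include_warmup Analyze warm-up maze trials too (default drops
#'   them).
#' @return A list of class `selection_criteria`.
#' @export
selection_criteria <- function(min_block_performance = 0.60,
                               max_excess_travel = 1.10,
                               min_trials_per_mouse = 1000,
                               require_history_trials = 0,
                               exclude_opto_sessions = FALSE,
                               include_warmup = FALSE) {
  if (min_trials_per_mouse < 1) abort("`min_trials_per_mouse` must be >= 1.")
  if (min_block_performance < 0 || min_block_performance > 1) {
    abort("`min_block_performance` must lie in [0, 1].")
  }
  if (require_history_trials < 0) abort("`require_history_trials` must be >= 0.")
  structure(
    list(
      min_block_performance = min_block_performance,
      max_excess_travel = max_excess_travel,
      min_trials_per_mouse = min_trials_per_mouse,
      require_history_trials = require_history_trials,
      exclude_opto_sessions = exclude_opto_sessions,
      include_warmup = include_warmup
    ),
    class = "selection_criteria"
  )
}

#' Read or write a maze/selection configuration as YAML
#'
#' @param path File path.
#' @return `read_task_config()` returns a list with elements `maze` and
#'   `selection`; `write_task_config()` returns `path` invisibly.
#' @export
read_task_config <- function(path) {
  raw <- yaml::read_yaml(path)
  maze <- do.call(maze_config, raw$maze %||% list())
  sel <- do.call(selection_criteria, raw$selection %||% list())
  list(maze = maze, selection = sel)
}

#' @rdname read_task_config
#' @param maze,selection Configuration objects to serialize.
#' @export
write_task_config <- function(path, maze = maze_config(),
                              selection = selection_criteria()) {
  yaml::write_yaml(list(maze = unclass(maze), selection = unclass(selection)), path)
  invisible(path)
}
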