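#' Per-trial behavioral records
#'
#' Analyses in this package operate on a tibble with one row per trial and
#' the columns below. `towers_left`/`towers_right` are list-columns of sorted
#' tower positions in cm; everything else is scalar per trial.
#'
#' \describe{
#'   \item{mouse_id}{character mouse identifier}
#'   \item{session_id}{integer session index}
#'   \item{block_id}{integer block index (maximal run of consecutive trials
#'     at the same maze level within a session)}
#'   \item{maze_level}{integer; 11 = main accumulation maze, 10 = easy
#'     (single-sided) block, 0 = visually-guided warm-up}
#'   \item{trial_index}{integer position within the session}
#'   \item{towers_left, towers_right}{list of tower positions, cm, sorted
#'     ascending with within-side gaps >= the refractory distance}
#'   \item{rewarded_side, choice}{"L" or "R"}
#'   \item{outcome}{"correct" or "error" (always `choice == rewarded_side`)}
#'   \item{excess_travel_fraction}{traveled distance / nominal maze length}
#'   \item{timed_out, aborted, opto}{logical flags}
#' }
#'
#' @param n Number of empty rows.
#' @return A zero-filled trial tibble, useful as a column template.
#' @export
trial_template <- function(n = 0) {
  tibble::tibble(
    mouse_id = character(n),
    session_id = integer(n),
    block_id = integer(n),
    maze_level = integer(n),
    trial_index = integer(n),
    towers_left = vector("list", n),
    towers_right = vector("list", n),
    rewarded_side = character(n),
    choice = character(n),
    outcome = character(n),
    excess_travel_fraction = numeric(n),
    timed_out = logical(n),
    aborted = logical(n),
    opto = logical(n)
  )
}

trial_columns <- names(trial_template())

#' Add evidence summary columns to a trial table
#'
#' @param trials A trial tibble (see [trial_template()]).
#' @return The input with columns `n_left`, `n_right`, `n_total`, and
#'   `delta` (#R - #L) appended.
#' @export
trial_evidence <- function(trials) {
  dplyr::mutate(
    trials,
    n_left = lengths(.data$towers_left),
    n_right = lengths(.data$towers_right),
    n_total = .data$n_left + .data$n_right,
    delta = .data$n_right - .data$n_left
  )
}

#' Validate trial-record invariants
#'
#' Checks that tower positions are sorted with at least the refractory
#' spacing within each side and lie inside the cue region, that the rewarded
#' side holds the strict tower majority, and that `outcome` is consistent
#' with `choice` and `rewarded_side`.
#'
#' @param trials Trial tibble.
#' @param config [maze_config()] supplying the geometry.
#' @param tol Numeric slack on spacing comparisons, cm.
#' @return `trials`, invisibly, if valid; otherwise an error naming the
#'   first offending trial and rule.
#' @export
validate_trials <- function(trials, config = maze_config(), tol = 1e-6) {
  stopifnot(is.data.frame(trials))
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing) > 0) {
    abort(paste0("missing required field(s): ", paste(missing, collapse = ", ")))
  }
  check_side <- function(pos, i, side) {
    pos <- pos[[i]]
    if (length(pos) == 0) return(invisible(NULL))
    if (is.unsorted(pos, strictly = TRUE)) {
      abort(sprintf("trial %d: unsorted %s tower positions", i, side))
    }
    if (length(pos) > 1 && any(diff(pos) < config$refractory_cm - tol)) {
      abort(sprintf("trial %d: %s towers violate the %g-cm refractory spacing",
                    i, side, config$refractory_cm))
    }
    if (min(pos) < config$earliest_tower_cm - tol ||
        max(pos) > config$cue_region_cm + tol) {
      abort(sprintf("trial %d: %s towers outside the cue region", i, side))
    }
    invisible(NULL)
  }
  ev <- trial_evidence(trials)
  for (i in seq_len(nrow(trials))) {
    check_side(trials$towers_left, i, "left")
    check_side(trials$towers_right, i, "right")
    maj <- if (ev$delta[i] > 0) "R" else if (ev$delta[i] < 0) "L" else NA_character_
    if (ev$n_total[i] > 0 && !is.na(maj) && trials$rewarded_side[i] != maj &&
        trials$maze_level[i] >= 11L) {
      abort(sprintf("trial %d: rewarded side is not the tower majority", i))
    }
    expected <- if (trials$choice[i] == trials$rewarded_side[i]) "correct" else "error"
    if (trials$outcome[i] != expected) {
      abort(sprintf("trial %d: outcome inconsistent with choice and rewarded side", i))
    }
  }
  invisible(trials)
}

#' Read and write session logs (JSON Lines)
#'
#' One JSON object per line, keys matching the trial-record columns; tower
#' positions are arrays of numbers in cm (2 decimals on write). Reading
#' validates every record and reports malformed lines by line number.
#'
#' @param path File path.
#' @param config [maze_config()] used for validation.
#' @param validate Validate invariants after parsing (default TRUE).
#' @return `read_session_log()` returns a trial tibble;
#'   `write_session_log()` returns `path` invisibly.
#' @export
read_session_log <- function(path, config = maze_config(), validate = TRUE) {
  if (!file.exists(path)) abort(paste0("no such session log: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) abort(sprintf("line %d: malformed JSON (%s)",
                                                      i, conditionMessage(e))))
    missing <- setdiff(trial_columns, names(obj))
    if (length(missing) > 0) {
      abort(sprintf("line %d: missing required field(s): %s",
                    i, paste(missing, collapse = ", ")))
    }
    recs[[i]] <- tibble::tibble(
      mouse_id = as.character(obj$mouse_id),
      session_id = as.integer(obj$session_id),
      block_id = as.integer(obj$block_id),
      maze_level = as.integer(obj$maze_level),
      trial_index = as.integer(obj$trial_index),
      towers_left = list(as.numeric(obj$towers_left)),
      towers_right = list(as.numeric(obj$towers_right)),
      rewarded_side = as.character(obj$rewarded_side),
      choice = as.character(obj$choice),
      outcome = as.character(obj$outcome),
      excess_travel_fraction = as.numeric(obj$excess_travel_fraction),
      timed_out = as.logical(obj$timed_out),
      aborted = as.logical(obj$aborted),
      opto = as.logical(obj$opto)
    )
  }
  trials <- dplyr::bind_rows(recs)
  if (nrow(trials) == 0) trials <- trial_template()
  if (validate && nrow(trials) > 0) validate_trials(trials, config)
  trials
}

#' @rdname read_session_log
#' @param trials Trial tibble to serialize.
#' @export
write_session_log <- function(trials, path) {
  lines <- vapply(seq_len(nrow(trials)), function(i) {
    jsonlite::toJSON(
      list(
        mouse_id = trials$mouse_id[i],
        session_id = trials$session_id[i],
        block_id = trials$block_id[i],
        maze_level = trials$maze_level[i],
        trial_index = trials$trial_index[i],
        towers_left = round(as.numeric(trials$towers_left[[i]]), 2),
        towers_right = round(as.numeric(trials$towers_right[[i]]), 2),
        rewarded_side = trials$rewarded_side[i],
        choice = trials$choice[i],
        outcome = trials$outcome[i],
        excess_travel_fraction = trials$excess_travel_fraction[i],
        timed_out = trials$timed_out[i],
        aborted = trials$aborted[i],
        opto = trials$opto[i]
      ),
      auto_unbox = TRUE, digits = NA
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write within-trial trajectories (CSV)
#'
#' Columns: `mouse_id, session_id, trial_index, t, x, y, view_angle`, with
#' `t` in seconds, `x`/`y` in cm, and `view_angle` in radians (positive =
#' rightward turn).
#'
#' @param path File path.
#' @return A tibble of trajectory samples.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) abort(paste0("no such trajectory file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("mouse_id", "session_id", "trial_index", "t", "x", "y", "view_angle")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("trajectory file missing column(s): ", paste(missing, collapse = ", ")))
  }
  tibble::as_tibble(df)
}

#' @rdname read_trajectories
#' @param traj Trajectory tibble to serialize.
#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}
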