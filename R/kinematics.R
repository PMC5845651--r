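#' View angle at a maze position
#'
#' Running trajectories can backtrack, so the view angle at position Y is
#' defined as the angle at the first sample whose y meets or exceeds Y (no
#' interpolation).
#'
#' @param trajectory Tibble with `t`, `y`, `view_angle` (one trial, in
#'   time order).
#' @param Y Query position, cm.
#' @return View angle in radians; `NA` when the trajectory never reaches
#'   Y.
#' @export
view_angle_at <- function(trajectory, Y) {
  i <- which(trajectory$y >= Y)
  if (length(i) == 0) return(NA_real_)
  trajectory$view_angle[min(i)]
}

# Wide matrix of theta(y) over a grid for many trials.
view_angle_matrix <- function(trajectories, y_grid) {
  keys <- dplyr::group_split(
    dplyr::group_by(trajectories, .data$mouse_id, .data$session_id,
                    .data$trial_index)
  )
  theta <- vapply(keys, function(g) {
    g <- g[order(g$t), , drop = FALSE]
    vapply(y_grid, function(Y) view_angle_at(g, Y), numeric(1))
  }, numeric(length(y_grid)))
  theta <- matrix(theta, nrow = length(keys), ncol = length(y_grid),
                  byrow = TRUE)
  info <- dplyr::bind_rows(lapply(keys, function(g) g[1, c("mouse_id", "session_id", "trial_index")]))
  list(theta = theta, info = info)
}

#' Choice decoding from the view angle
#'
#' At each y position, the decoding boundary `theta_cd(y)` is the angle at
#' which the fraction of right-choice trials above it equals the fraction
#' of left-choice trials below it (found by bisection on the two empirical
#' CDFs) - the boundary that most equally separates the choice
#' distributions. Decoding accuracy is the percent of right-choice trials
#' above the boundary.
#'
#' @param trials Trial tibble (supplies choices).
#' @param trajectories Trajectory tibble covering those trials.
#' @param y_grid Positions (cm) at which to decode.
#' @return A `decoder_result` tibble: `y`, `boundary`, `accuracy_percent`,
#'   and per-class trial counts (`NA` accuracy where a class is absent).
#' @export
choice_decoder <- function(trials, trajectories,
                           y_grid = seq(0, 295, by = 5)) {
  vm <- view_angle_matrix(trajectories, y_grid)
  key <- paste(vm$info$mouse_id, vm$info$session_id, vm$info$trial_index)
  tkey <- paste(trials$mouse_id, trials$session_id, trials$trial_index)
  choice <- trials$choice[match(key, tkey)]
  out <- lapply(seq_along(y_grid), function(col) {
    th <- vm$theta[, col]
    ok <- !is.na(th) & !is.na(choice)
    th_r <- th[ok & choice == "R"]
    th_l <- th[ok & choice == "L"]
    if (length(th_r) == 0 || length(th_l) == 0) {
      return(tibble::tibble(y = y_grid[col], boundary = NA_real_,
                            accuracy_percent = NA_real_,
                            n_right = length(th_r), n_left = length(th_l)))
    }
    # g(t) = P(theta_R > t) - P(theta_L < t) is non-increasing in t
    g <- function(t) mean(th_r > t) - mean(th_l < t)
    lo <- min(th_r, th_l) - 1e-9
    hi <- max(th_r, th_l) + 1e-9
    for (iter in 1:60) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    boundary <- (lo + hi) / 2
    tibble::tibble(y = y_grid[col], boundary = boundary,
                   accuracy_percent = 100 * mean(th_r > boundary),
                   n_right = length(th_r), n_left = length(th_l))
  })
  structure(dplyr::bind_rows(out), class = c("decoder_result",
                                             class(tibble::tibble())))
}

#' Tower-triggered view-angle deviations
#'
#' Subtracts each trial's view-angle trajectory from the mean trajectory
#' of trials with the same choice, then averages these deviations in a
#' window following each tower (y = 0 at tower appearance), separately for
#' left and right towers. Also reports the ratio of the across-trial 1-sd
#' deviation spread to the separation between the right- and left-tower
#' triggered mean deviation traces: a per-tower mnemonic view-angle
#' strategy would need cue-locked steps large relative to the
#' trial-to-trial spread, so a large ratio argues against one.
#'
#' @param trials Trial tibble.
#' @param trajectories Trajectory tibble.
#' @param window_cm Post-tower window length, cm.
#' @param step_cm Sampling step within the window, cm.
#' @param y_grid Grid used for the choice-mean trajectories, cm.
#' @return A list with `traces` (tibble: tower side, offset, mean
#'   deviation, sd, n) and `spread_ratio`.
#' @export
tower_triggered_view_angle <- function(trials, trajectories, window_cm = 80,
                                       step_cm = 5,
                                       y_grid = seq(0, 295, by = 5)) {
  vm <- view_angle_matrix(trajectories, y_grid)
  key <- paste(vm$info$mouse_id, vm$info$session_id, vm$info$trial_index)
  tkey <- paste(trials$mouse_id, trials$session_id, trials$trial_index)
  idx <- match(tkey, key)
  choice <- trials$choice
  mean_prof <- list(
    R = colMeans(vm$theta[idx[choice == "R"], , drop = FALSE], na.rm = TRUE),
    L = colMeans(vm$theta[idx[choice == "L"], , drop = FALSE], na.rm = TRUE)
  )
  offsets <- seq(0, window_cm, by = step_cm)
  acc <- list(R = list(), L = list())
  for (i in seq_len(nrow(trials))) {
    row <- idx[i]
    if (is.na(row)) next
    dev <- vm$theta[row, ] - mean_prof[[choice[i]]]
    for (side in c("R", "L")) {
      towers <- if (side == "R") trials$towers_right[[i]] else trials$towers_left[[i]]
      for (tw in towers) {
        ys <- tw + offsets
        ok <- ys <= max(y_grid)
        if (sum(ok) < length(offsets)) next # insufficient post-tower track
        vals <- vapply(ys, function(Y) {
          dev[which.min(abs(y_grid - Y))]
        }, numeric(1))
        acc[[side]][[length(acc[[side]]) + 1]] <- vals
      }
    }
  }
  traces <- dplyr::bind_rows(lapply(c("R", "L"), function(side) {
    if (length(acc[[side]]) == 0) {
      return(tibble::tibble(tower_side = character(), offset_cm = numeric(),
                            mean_deviation = numeric(), sd = numeric(),
                            n = integer()))
    }
    m <- do.call(rbind, acc[[side]])
    tibble::tibble(tower_side = side, offset_cm = offsets,
                   mean_deviation = colMeans(m, na.rm = TRUE),
                   sd = apply(m, 2, sd, na.rm = TRUE),
                   n = nrow(m))
  }))
  spread <- mean(traces$sd, na.rm = TRUE)
  tr_r <- traces$mean_deviation[traces$tower_side == "R"]
  tr_l <- traces$mean_deviation[traces$tower_side == "L"]
  cue_diff <- if (length(tr_r) == length(tr_l) && length(tr_r) > 0) {
    mean(abs(tr_r - tr_l), na.rm = TRUE)
  } else {
    NA_real_
  }
  list(traces = traces,
       spread_ratio = spread / max(cue_diff, 1e-12, na.rm = TRUE))
}

#' Running-speed summary
#'
#' Per-trial stem speed is the summed x-y path length over 0 < y < 300 cm
#' divided by the traversal time. The summary gives session means, the
#' within-session sd (sd across trials in a session, averaged over
#' sessions), and the across-session sd (sd of session mean speeds).
#'
#' @param trajectories Trajectory tibble.
#' @param stem_cm Stem extent used for the speed window, cm.
#' @return A list with `per_trial`, `per_session`, and `summary` tibbles
#'   (zero-duration trials are excluded and counted).
#' @export
speed_summary <- function(trajectories, stem_cm = 300) {
  groups <- dplyr::group_split(
    dplyr::group_by(trajectories, .data$mouse_id, .data$session_id,
                    .data$trial_index)
  )
  per_trial <- dplyr::bind_rows(lapply(groups, function(g) {
    g <- g[order(g$t), , drop = FALSE]
    in_stem <- g$y > 0 & g$y < stem_cm
    if (sum(in_stem) < 2) return(NULL)
    gs <- g[in_stem, , drop = FALSE]
    path <- sum(sqrt(diff(gs$x)^2 + diff(gs$y)^2))
    dt <- max(gs$t) - min(gs$t)
    if (dt <= 0) return(NULL)
    tibble::tibble(mouse_id = g$mouse_id[1], session_id = g$session_id[1],
                   trial_index = g$trial_index[1], speed_cm_s = path / dt)
  }))
  n_dropped <- length(groups) - nrow(per_trial)
  per_session <- dplyr::summarise(
    dplyr::group_by(per_trial, .data$mouse_id, .data$session_id),
    mean_speed = mean(.data$speed_cm_s),
    sd_speed = sd(.data$speed_cm_s),
    n_trials = dplyr::n(), .groups = "drop"
  )
  summary <- dplyr::summarise(
    dplyr::group_by(per_session, .data$mouse_id),
    across_session_sd = sd(.data$mean_speed),
    within_session_sd = mean(.data$sd_speed, na.rm = TRUE),
    mean_speed = mean(.data$mean_speed),
    n_sessions = dplyr::n(), .groups = "drop"
  )
  list(per_trial = per_trial, per_session = per_session, summary = summary,
       n_dropped = n_dropped)
}

#' Mean view-angle trajectories by evidence strength
#'
#' Bins trials by |#R - #L| and returns the mean view angle as a function
#' of y per bin and choice. With several mice, each mouse's
#' choice-conditioned mean trajectory is first aligned to the aggregate
#' (its own choice mean is replaced by the metamouse mean) before
#' averaging, so mouse-specific offsets do not blur the evidence ordering.
#'
#' @param trials Trial tibble.
#' @param trajectories Trajectory tibble.
#' @param delta_breaks Bin edges on |delta|.
#' @param y_grid Positions, cm.
#' @return Tibble: `choice`, `delta_bin`, `y`, `mean_theta`, `n`.
#' @export
view_angle_by_evidence <- function(trials, trajectories,
                                   delta_breaks = c(0, 3, 6, 10, 26),
                                   y_grid = seq(0, 295, by = 5)) {
  vm <- view_angle_matrix(trajectories, y_grid)
  key <- paste(vm$info$mouse_id, vm$info$session_id, vm$info$trial_index)
  ev <- trial_evidence(trials)
  tkey <- paste(ev$mouse_id, ev$session_id, ev$trial_index)
  row <- match(tkey, key)
  ok <- !is.na(row)
  ev <- ev[ok, , drop = FALSE]
  theta <- vm$theta[row[ok], , drop = FALSE]
  # metamouse alignment: remove each mouse's choice-mean, add the aggregate
  for (ch in c("L", "R")) {
    agg <- colMeans(theta[ev$choice == ch, , drop = FALSE], na.rm = TRUE)
    for (m in unique(ev$mouse_id)) {
      sel <- ev$choice == ch & ev$mouse_id == m
      if (!any(sel)) next
      own <- colMeans(theta[sel, , drop = FALSE], na.rm = TRUE)
      theta[sel, ] <- sweep(theta[sel, , drop = FALSE], 2, own - agg)
    }
  }
  ev$delta_bin <- cut(abs(ev$delta), delta_breaks, right = FALSE,
                      include.lowest = TRUE)
  out <- list()
  for (ch in c("L", "R")) {
    for (b in levels(ev$delta_bin)) {
      sel <- ev$choice == ch & !is.na(ev$delta_bin) & ev$delta_bin == b
      if (!any(sel)) next
      out[[length(out) + 1]] <- tibble::tibble(
        choice = ch, delta_bin = b, y = y_grid,
        mean_theta = colMeans(theta[sel, , drop = FALSE], na.rm = TRUE),
        n = sum(sel)
      )
    }
  }
  dplyr::bind_rows(out)
}
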