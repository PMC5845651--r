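make_traj <- function(y, theta, id = 1L, dt = 0.05) {
  tibble::tibble(mouse_id = "m", session_id = 1L, trial_index = id,
                 t = seq_along(y) * dt - dt, x = 0, y = y,
                 view_angle = theta)
}

test_that("view angle at Y uses the first crossing, without interpolation", {
  tr <- make_traj(c(0, 50, 40, 60), c(0, 5, 6, 7) * pi / 180)
  expect_equal(view_angle_at(tr, 45), 5 * pi / 180) # first crossing at y=50
  expect_equal(view_angle_at(tr, 50), 5 * pi / 180) # exactly on a sample
  expect_equal(view_angle_at(tr, 0), 0)             # boundary: first sample
  expect_true(is.na(view_angle_at(tr, 100)))
  # refining the sampling keeps the first-crossing angle within one sample
  fine <- make_traj(seq(0, 60, by = 1), seq(0, 0.12, length.out = 61))
  coarse <- fine[seq(1, 61, by = 5), ]
  expect_lt(abs(view_angle_at(fine, 37) - view_angle_at(coarse, 37)), 0.012)
})

test_that("choice decoder handles separation, identity, and the Gaussian case", {
  mk_set <- function(th_r, th_l) {
    n_r <- length(th_r)
    n_l <- length(th_l)
    trials <- tibble::tibble(
      mouse_id = "m", session_id = 1L, block_id = 1L, maze_level = 11L,
      trial_index = seq_len(n_r + n_l),
      towers_left = replicate(n_r + n_l, numeric(0), simplify = FALSE),
      towers_right = replicate(n_r + n_l, c(50), simplify = FALSE),
      rewarded_side = "R",
      choice = rep(c("R", "L"), c(n_r, n_l)),
      outcome = "correct", excess_travel_fraction = 1,
      timed_out = FALSE, aborted = FALSE, opto = FALSE
    )
    trials$outcome <- ifelse(trials$choice == trials$rewarded_side,
                             "correct", "error")
    traj <- dplyr::bind_rows(lapply(seq_len(n_r + n_l), function(i) {
      make_traj(c(0, 100), rep(c(th_r, th_l)[i], 2), id = i)
    }))
    list(trials = trials, traj = traj)
  }
  sep <- mk_set(th_r = seq(1, 2, length.out = 40),
                th_l = seq(-2, -1, length.out = 40))
  d <- choice_decoder(sep$trials, sep$traj, y_grid = 100)
  expect_equal(d$accuracy_percent, 100)

  same <- mk_set(th_r = rep(c(-1, 1), 30), th_l = rep(c(-1, 1), 30))
  d2 <- choice_decoder(same$trials, same$traj, y_grid = 100)
  expect_equal(d2$accuracy_percent, 50, tolerance = 6)

  withr::with_seed(91, {
    gauss <- mk_set(th_r = rnorm(4000, 1, 1), th_l = rnorm(4000, -1, 1))
    d3 <- choice_decoder(gauss$trials, gauss$traj, y_grid = 100)
  })
  # analytic equal-error point for N(+1,1) vs N(-1,1): accuracy pnorm(1)
  expect_equal(d3$accuracy_percent, 100 * pnorm(1), tolerance = 2.5)

  # monotone transforms of theta leave the accuracy unchanged
  gauss_t <- gauss
  gauss_t$traj$view_angle <- tanh(gauss_t$traj$view_angle / 2)
  d4 <- choice_decoder(gauss_t$trials, gauss_t$traj, y_grid = 100)
  expect_equal(d4$accuracy_percent, d3$accuracy_percent, tolerance = 0.5)

  # mirroring flips the boundary sign, keeps the accuracy
  gauss_m <- gauss
  gauss_m$traj$view_angle <- -gauss_m$traj$view_angle
  gauss_m$trials$choice <- ifelse(gauss$trials$choice == "R", "L", "R")
  d5 <- choice_decoder(gauss_m$trials, gauss_m$traj, y_grid = 100)
  expect_equal(d5$accuracy_percent, d3$accuracy_percent, tolerance = 0.5)
  # the equal-error boundary has a small plateau on empirical CDFs
  expect_lt(abs(d5$boundary + d3$boundary), 0.02)
})

test_that("decoding accuracy rises along the maze for the trajectory generator", {
  withr::with_seed(92, {
    sim <- simulate_dataset(agent_k_tower(1), n_sessions = 2,
                            trials_per_session = 400, warmup = FALSE,
                            trajectories = TRUE, excess_travel_rate = 0)
    dec <- choice_decoder(sim$trials, sim$trajectories,
                          y_grid = c(50, 100, 150, 200, 250))
  })
  acc <- dec$accuracy_percent
  expect_true(all(diff(acc) > -3)) # monotone up to small noise
  expect_gt(acc[4], 85) # strong separation by the end of the cue region
})

test_that("tower-triggered deviations vanish for deterministic trajectories", {
  withr::with_seed(93, {
    sim <- simulate_dataset(
      agent_k_tower(1), n_sessions = 1, trials_per_session = 60,
      warmup = FALSE, trajectories = TRUE, excess_travel_rate = 0,
      traj_params = trajectory_params(noise_sd_rad = 0, evidence_gain_cm = 0,
                                      within_session_sd = 0,
                                      across_session_sd = 0)
    )
    res <- tower_triggered_view_angle(sim$trials, sim$trajectories)
  })
  expect_lt(max(abs(res$traces$mean_deviation), na.rm = TRUE), 1e-9)
})

test_that("noisy trajectories show spread well above the choice-mean difference", {
  withr::with_seed(94, {
    sim <- simulate_dataset(agent_k_tower(1), n_sessions = 2,
                            trials_per_session = 300, warmup = FALSE,
                            trajectories = TRUE, excess_travel_rate = 0)
    res <- tower_triggered_view_angle(sim$trials, sim$trajectories)
  })
  expect_gt(res$spread_ratio, 5)
})

test_that("speed summaries recover the generating speed structure", {
  const <- make_traj(seq(0, 330, by = 3), rep(0, 111), dt = 0.05)
  s <- speed_summary(const)
  expect_equal(s$per_trial$speed_cm_s, 60, tolerance = 1e-9)

  withr::with_seed(95, {
    tp <- trajectory_params(mean_speed_cm_s = 60, within_session_sd = 5,
                            across_session_sd = 8, noise_sd_rad = 0)
    sim <- simulate_dataset(agent_constant(0.5), n_sessions = 30,
                            trials_per_session = 25, warmup = FALSE,
                            trajectories = TRUE, traj_params = tp,
                            excess_travel_rate = 0)
    s2 <- speed_summary(sim$trajectories)
  })
  expect_equal(s2$summary$within_session_sd, 5, tolerance = 1.5)
  expect_equal(s2$summary$across_session_sd, 8, tolerance = 3)
  expect_equal(mean(s2$per_trial$speed_cm_s), 60, tolerance = 4)
})

test_that("view-angle trajectories diverge earlier with stronger evidence", {
  withr::with_seed(96, {
    sim <- simulate_dataset(agent_k_tower(1), n_sessions = 3,
                            trials_per_session = 300, warmup = FALSE,
                            trajectories = TRUE, excess_travel_rate = 0)
    prof <- view_angle_by_evidence(sim$trials, sim$trajectories,
                                   delta_breaks = c(0, 3, 6, 26))
  })
  at <- prof[prof$y == 150 & prof$choice == "R", ]
  at <- at[order(at$delta_bin), ]
  expect_true(all(diff(at$mean_theta) > 0))
})
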