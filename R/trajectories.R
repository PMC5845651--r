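#' Trajectory generator parameters
#'
#' The package has no generative model of running inherited from data;
#' this is a descriptive stand-in (clearly non-inferential) that reproduces
#' the qualitative structure of real trajectories: stereotyped forward
#' running, view angles near zero in the start buffer, gradual divergence
#' toward the chosen side that begins earlier on trials with stronger
#' evidence, and large trial-to-trial variability around the
#' choice-conditioned mean.
#'
#' The choice-conditioned mean profile is logistic in y:
#' `theta(y) = sign(choice) * theta_max / (1 + exp(-(y - y_mid_eff) / y_scale))`
#' with `y_mid_eff = y_mid - evidence_gain * |delta|`, so stronger evidence
#' shifts the divergence earlier. Per-trial noise is an
#' Ornstein-Uhlenbeck process in y added to the mean profile.
#'
#' @param mean_speed_cm_s Population mean running speed, cm/s.
#' @param within_session_sd,across_session_sd Speed variability components,
#'   cm/s.
#' @param theta_max_rad Asymptotic view angle at the arms, radians.
#' @param y_mid_cm,y_scale_cm Midpoint and steepness of the logistic mean
#'   profile, cm.
#' @param evidence_gain_cm Leftward shift of the midpoint per unit |delta|,
#'   cm.
#' @param noise_sd_rad Stationary sd of the Ornstein-Uhlenbeck view-angle
#'   noise, radians.
#' @param noise_tau_cm Correlation length of the noise, cm.
#' @param dt_s Sampling interval, s.
#' @return A list of class `trajectory_params`.
#' @export
trajectory_params <- function(mean_speed_cm_s = 61,
                              within_session_sd = 5,
                              across_session_sd = 8,
                              theta_max_rad = 1.0,
                              y_mid_cm = 220,
                              y_scale_cm = 40,
                              evidence_gain_cm = 4,
                              noise_sd_rad = 0.25,
                              noise_tau_cm = 50,
                              dt_s = 0.05) {
  stopifnot(mean_speed_cm_s > 0, within_session_sd >= 0,
            across_session_sd >= 0, noise_sd_rad >= 0)
  structure(
    list(mean_speed_cm_s = mean_speed_cm_s,
         within_session_sd = within_session_sd,
         across_session_sd = across_session_sd,
         theta_max_rad = theta_max_rad,
         y_mid_cm = y_mid_cm, y_scale_cm = y_scale_cm,
         evidence_gain_cm = evidence_gain_cm,
         noise_sd_rad = noise_sd_rad, noise_tau_cm = noise_tau_cm,
         dt_s = dt_s),
    class = "trajectory_params"
  )
}

#' Simulate one trial's trajectory
#'
#' @param choice "L" or "R"; the trajectory is conditioned on the choice.
#' @param delta Signed evidence #R - #L of the trial (modulates how early
#'   the view angle diverges).
#' @param params A [trajectory_params()].
#' @param speed_cm_s Trial running speed; drawn from the params when `NULL`.
#' @param config [maze_config()] for the maze geometry.
#' @return A tibble with columns `t`, `x`, `y`, `view_angle`; `y` reaches
#'   the end of the stem.
#' @export
simulate_trajectory <- function(choice, delta, params = trajectory_params(),
                                speed_cm_s = NULL, config = maze_config()) {
  stopifnot(choice %in% c("L", "R"))
  v <- speed_cm_s %||%
    max(5, rnorm(1, params$mean_speed_cm_s, params$within_session_sd))
  total <- config$total_length_cm
  dt <- params$dt_s
  n <- ceiling(total / (v * dt)) + 1L
  t <- (seq_len(n) - 1) * dt
  y <- pmin(t * v, total)
  sgn <- if (choice == "R") 1 else -1
  y_mid <- params$y_mid_cm - params$evidence_gain_cm * abs(delta)
  mu <- sgn * params$theta_max_rad / (1 + exp(-(y - y_mid) / params$y_scale_cm))
  noise <- numeric(n)
  if (params$noise_sd_rad > 0) {
    rho <- exp(-(v * dt) / params$noise_tau_cm)
    innov_sd <- params$noise_sd_rad * sqrt(1 - rho^2)
    noise[1] <- rnorm(1, 0, params$noise_sd_rad)
    for (i in seq_len(n - 1)) {
      noise[i + 1] <- rho * noise[i] + rnorm(1, 0, innov_sd)
    }
  }
  theta <- mu + noise
  theta[y < config$start_buffer_cm] <- 0 # view angle clamped in the buffer
  # lateral drift consistent with heading; kept small so the stem is ~1 cm wide
  x <- cumsum(c(0, diff(y) * tan(pmin(pmax(theta[-n], -1.2), 1.2)) * 0.01))
  tibble::tibble(t = t, x = x, y = y, view_angle = theta)
}
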