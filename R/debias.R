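#' Adaptive side-debiasing of trial draws
#'
#' The rig counteracts side bias by adjusting the probability of drawing a
#' right-rewarded trial from recent side-conditional error rates. `e_R`
#' (`e_L`) is the half-Gaussian-weighted (sd 20 trials) mean of the error
#' indicator over the most recent 40 right (left) trials; the square roots
#' of both are capped into \[0.15, 0.85\] to avoid all-one-side runs, and
#' the target probability is `p_R = e_R / (e_R + e_L)`. A pseudo-random
#' prescription then keeps the realized right fraction (half-Gaussian
#' weighted, sd 60 trials) close to `p_R`: when the realized fraction is
#' above target, a right trial is drawn with probability `0.5 * p_R`; when
#' below, with probability `0.5 * (1 + p_R)`; at equality, with `p_R`.
#'
#' @param window Number of recent per-side trials entering the error
#'   averages.
#' @param sigma_error Half-Gaussian sd (trials) of the error-average weights.
#' @param sigma_fraction Half-Gaussian sd (trials) of the realized-fraction
#'   weights.
#' @param sqrt_cap Two-element range into which sqrt(e) is capped.
#' @return `new_debiaser()` returns a `debiaser` state object with fields
#'   `right_errors`, `left_errors` (newest first), and `sides` (full side
#'   history, newest first).
#' @seealso [debias_update()], [debias_p_right()], [draw_trial_side()]
#' @export
new_debiaser <- function(window = 40, sigma_error = 20, sigma_fraction = 60,
                         sqrt_cap = c(0.15, 0.85)) {
  structure(
    list(
      window = window, sigma_error = sigma_error,
      sigma_fraction = sigma_fraction, sqrt_cap = sqrt_cap,
      right_errors = logical(0), left_errors = logical(0),
      sides = character(0)
    ),
    class = "debiaser"
  )
}

half_gaussian_mean <- function(x, sigma) {
  # x newest first; weights decay with age; normalized to unit mass
  if (length(x) == 0) return(NA_real_)
  age <- seq_along(x) - 1
  w <- exp(-age^2 / (2 * sigma^2))
  sum(w * x) / sum(w)
}

#' @describeIn new_debiaser Record one finished trial (its rewarded side and
#'   whether the choice was an error) and return the updated state.
#' @param state A `debiaser` object.
#' @param side Rewarded side of the finished trial, "L" or "R".
#' @param error Logical, was the trial an error?
#' @export
debias_update <- function(state, side, error) {
  stopifnot(inherits(state, "debiaser"), side %in% c("L", "R"))
  if (side == "R") {
    state$right_errors <- head(c(error, state$right_errors), state$window)
  } else {
    state$left_errors <- head(c(error, state$left_errors), state$window)
  }
  state$sides <- c(side, state$sides)
  state
}

#' @describeIn new_debiaser Current target probability of drawing a
#'   right-rewarded trial. Returns 0.5 until both sides have history.
#' @export
debias_p_right <- function(state) {
  e_r <- half_gaussian_mean(as.numeric(state$right_errors), state$sigma_error)
  e_l <- half_gaussian_mean(as.numeric(state$left_errors), state$sigma_error)
  if (is.na(e_r) || is.na(e_l)) return(0.5)
  cap <- state$sqrt_cap
  e_r <- pmin(pmax(sqrt(e_r), cap[1]), cap[2])^2
  e_l <- pmin(pmax(sqrt(e_l), cap[1]), cap[2])^2
  e_r / (e_r + e_l)
}

#' @describeIn new_debiaser Realized right-trial fraction under the
#'   half-Gaussian (sd `sigma_fraction`) weighting, `NA` with no history.
#' @export
debias_right_fraction <- function(state) {
  half_gaussian_mean(as.numeric(state$sides == "R"), state$sigma_fraction)
}

#' @describeIn new_debiaser The effective probability with which the next
#'   trial is drawn right-rewarded, after the pseudo-random prescription.
#' @export
draw_side_probability <- function(state) {
  p_r <- debias_p_right(state)
  f_hat <- debias_right_fraction(state)
  if (is.na(f_hat) || f_hat == p_r) return(p_r)
  if (f_hat > p_r) 0.5 * p_r else 0.5 * (1 + p_r)
}

#' @describeIn new_debiaser Draw the rewarded side of the next trial.
#' @export
draw_trial_side <- function(state) {
  if (runif(1) < draw_side_probability(state)) "R" else "L"
}
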