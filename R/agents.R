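#' Synthetic choice agents
#'
#' Agents map a trial's tower configuration (and, for history-aware kinds,
#' the previous trial) to a right-choice probability, providing ground truth
#' for parameter-recovery tests of every analysis in the package. Kinds:
#'
#' * `agent_constant(p)`: chooses right with fixed probability `p`.
#' * `agent_k_tower(k, lapse_r, lapse_l)`: picks `k` towers at random
#'   without replacement and follows their majority (hypergeometric
#'   closed form; `k = 1` reduces to #R / (#R + #L)), then mixes in side
#'   lapses.
#' * `agent_first_tower(...)`, `agent_last_tower(...)`: follow the side of
#'   the first (last) tower, with side lapses.
#' * `agent_logistic_history(...)`: the history-modulated logistic choice
#'   model (see [fit_history_model()]) with known coefficients.
#' * `agent_ddm(params, ...)`: forward Monte-Carlo simulation of the
#'   pulse-based accumulator (Euler steps of 0.5 cm), deliberately
#'   independent of the likelihood propagation in [ddm_trial_pr()] so the
#'   two can cross-validate each other.
#'
#' @param p Right-choice probability of the constant agent.
#' @return An object of class `accum_agent`.
#' @name agents
NULL

new_agent <- function(.kind, ...) {
  structure(c(list(kind = .kind), list(...)), class = "accum_agent")
}

#' @rdname agents
#' @export
agent_constant <- function(p = 0.5) {
  stopifnot(p >= 0, p <= 1)
  new_agent("constant_p", p = p)
}

#' @rdname agents
#' @param k Number of towers sampled; odd and >= 1.
#' @param lapse_r,lapse_l Side lapse probabilities (probability of a right
#'   choice on an easy left trial, and vice versa); their sum must stay
#'   below 1.
#' @export
agent_k_tower <- function(k = 1, lapse_r = 0, lapse_l = 0) {
  stopifnot(k >= 1, k %% 2 == 1, lapse_r + lapse_l < 1)
  new_agent("k_random_tower", k = k, lapse_r = lapse_r, lapse_l = lapse_l)
}

#' @rdname agents
#' @export
agent_first_tower <- function(lapse_r = 0, lapse_l = 0) {
  new_agent("first_tower", lapse_r = lapse_r, lapse_l = lapse_l)
}

#' @rdname agents
#' @export
agent_last_tower <- function(lapse_r = 0, lapse_l = 0) {
  new_agent("last_tower", lapse_r = lapse_r, lapse_l = lapse_l)
}

#' @rdname agents
#' @param beta0 Evidence-independent offset inside the logistic.
#' @param beta_delta Per-spatial-bin evidence weights (length 5).
#' @param beta_e Post-error evidence-slope modulation.
#' @param beta0_r,beta0_l Baseline lapse arguments (radians).
#' @param beta_h History weights for (previous choice, previous outcome,
#'   their product), each coded +1/-1.
#' @param f_r Reference right-choice fraction defining the zero-parameter
#'   baseline.
#' @export
agent_logistic_history <- function(beta0 = 0, beta_delta = rep(0.5, 5),
                                   beta_e = 0, beta0_r = 0, beta0_l = 0,
                                   beta_h = c(0, 0, 0), f_r = 0.5) {
  new_agent("logistic_history",
            beta0 = beta0, beta_delta = beta_delta, beta_e = beta_e,
            beta0_r = beta0_r, beta0_l = beta0_l, beta_h = beta_h, f_r = f_r)
}

#' @rdname agents
#' @param params A [ddm_params()] parameter set.
#' @param n_paths Paths used when a probability (rather than a sampled
#'   choice) is requested; the sampled choice always uses one fresh path,
#'   which is an exact draw from the agent's p_R.
#' @param dy_cm Euler step, cm.
#' @export
agent_ddm <- function(params, n_paths = 1000, dy_cm = 0.5) {
  stopifnot(inherits(params, "ddm_params"))
  new_agent("ddm_mc", params = params, n_paths = n_paths, dy_cm = dy_cm)
}

#' Right-choice probability of an agent on one trial
#'
#' @param agent An [agents] object.
#' @param towers_left,towers_right Tower positions, cm.
#' @param prev_choice,prev_outcome Previous trial's choice ("L"/"R") and
#'   outcome ("correct"/"error"); `NA` for a history-free context (history
#'   terms then drop out).
#' @return The probability of a right choice. For the Monte-Carlo
#'   accumulator agent this is an `n_paths`-path estimate.
#' @export
agent_p_right <- function(agent, towers_left, towers_right,
                          prev_choice = NA, prev_outcome = NA) {
  stopifnot(inherits(agent, "accum_agent"))
  switch(
    agent$kind,
    constant_p = agent$p,
    k_random_tower = strategy_predict(
      strategy_spec("k_random", k = agent$k,
                    lapse_r = agent$lapse_r, lapse_l = agent$lapse_l),
      towers_left, towers_right
    ),
    first_tower = strategy_predict(
      strategy_spec("first_tower", lapse_r = agent$lapse_r, lapse_l = agent$lapse_l),
      towers_left, towers_right
    ),
    last_tower = strategy_predict(
      strategy_spec("last_tower", lapse_r = agent$lapse_r, lapse_l = agent$lapse_l),
      towers_left, towers_right
    ),
    logistic_history = history_model_p_right(
      towers_left, towers_right, prev_choice, prev_outcome,
      beta0 = agent$beta0, beta_delta = agent$beta_delta, beta_e = agent$beta_e,
      beta0_r = agent$beta0_r, beta0_l = agent$beta0_l, beta_h = agent$beta_h,
      f_r = agent$f_r
    ),
    ddm_mc = ddm_mc_p_right(towers_left, towers_right, agent$params,
                            n_paths = agent$n_paths, dy_cm = agent$dy_cm),
    abort(paste0("unknown agent kind: ", agent$kind))
  )
}

#' Draw an agent's choice on one trial
#'
#' For every kind the returned choice is an exact Bernoulli draw from the
#' agent's right-choice probability; for the Monte-Carlo accumulator agent
#' this is achieved with a single fresh forward path rather than an
#' estimated probability.
#'
#' @inheritParams agent_p_right
#' @return A list with `choice` ("L"/"R") and `p_right` (the analytic
#'   probability where available, otherwise `NA`).
#' @export
agent_choice <- function(agent, towers_left, towers_right,
                         prev_choice = NA, prev_outcome = NA) {
  if (agent$kind == "ddm_mc") {
    right <- ddm_mc_paths(towers_left, towers_right, agent$params,
                          n_paths = 1L, dy_cm = agent$dy_cm)
    return(list(choice = if (right > 0.5) "R" else "L", p_right = NA_real_))
  }
  p <- agent_p_right(agent, towers_left, towers_right, prev_choice, prev_outcome)
  list(choice = if (runif(1) < p) "R" else "L", p_right = p)
}

# Eq-style history-modulated logistic probability shared by the agent and
# the fitted model.
history_model_p_right <- function(towers_left, towers_right,
                                  prev_choice, prev_outcome,
                                  beta0, beta_delta, beta_e,
                                  beta0_r, beta0_l, beta_h, f_r,
                                  bin_edges = spatial_bin_edges()) {
  delta_vec <- spatial_bin_evidence(towers_left, towers_right, bin_edges)
  if (is.na(prev_choice) || is.na(prev_outcome)) {
    h <- c(0, 0, 0)
    e <- 0
  } else {
    c_prev <- if (prev_choice == "R") 1 else -1
    o_prev <- if (prev_outcome == "correct") 1 else -1
    h <- c(c_prev, o_prev, c_prev * o_prev)
    e <- if (prev_outcome == "error") 1 else -1
  }
  p0 <- qlogis(f_r)
  arg_r <- lapse_arg(beta0_r + sum(beta_h * h))
  arg_l <- lapse_arg(beta0_l - sum(beta_h * h))
  l_r <- 0.5 * (1 - cos(arg_r))
  l_l <- 0.5 * (1 - cos(arg_l))
  core <- plogis(p0 + (1 + beta_e * e) * (beta0 + sum(beta_delta * delta_vec)))
  l_l + (1 - l_l - l_r) * core
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Smooth saturation of the cosine-lapse argument onto (-pi/2, pi/2):
# odd, ~identity near zero, differentiable everywhere (a hard clamp would
# leave the optimizer without gradients at the box edge), so lapses stay
# in [0, 0.5] for every history state.
lapse_arg <- function(x) (pi / 2) * tanh(2 * x / pi)
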