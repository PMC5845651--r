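#' Pulse-based accumulator (drift-diffusion) model parameters
#'
#' The latent decision variable `a` evolves over maze position y (meters):
#' it leaks or grows at rate `lambda` (memory time constant 1/lambda),
#' diffuses with variance `sigma2_a` per meter, and receives an impulse at
#' each tower whose magnitude is adapted by the running factor C (see
#' [adaptation_trace()]) and corrupted by per-pulse sensory noise with
#' variance `sigma2_s * C^2`. The initial value is drawn from
#' N(0, `sigma2_i`). Bounds at +/-`bound` are sticky. At the end of the
#' stem a right choice is made if `a` exceeds `bias` (absorbed mass counts
#' by bound sign), and with probability `lapse` the stimulus is ignored and
#' the choice is random.
#'
#' @param lambda Leak (negative) or instability (positive), 1/m.
#' @param sigma2_a Diffusion variance per meter.
#' @param sigma2_s Per-pulse sensory variance (fractional, multiplies C^2).
#' @param sigma2_i Initial-value variance.
#' @param bound Sticky bound height B.
#' @param phi Adaptation multiplier (1 = no adaptation; < 1 depression,
#'   > 1 facilitation).
#' @param tau_phi Adaptation recovery constant, m.
#' @param bias Decision threshold on the final accumulator value.
#' @param lapse Probability of ignoring the stimulus and choosing at
#'   random.
#' @return A list of class `ddm_params`.
#' @export
ddm_params <- function(lambda = 0, sigma2_a = 1, sigma2_s = 4, sigma2_i = 1,
                       bound = 15, phi = 1, tau_phi = 0.5, bias = 0,
                       lapse = 0) {
  p <- list(lambda = lambda, sigma2_a = sigma2_a, sigma2_s = sigma2_s,
            sigma2_i = sigma2_i, bound = bound, phi = phi,
            tau_phi = tau_phi, bias = bias, lapse = lapse)
  b <- ddm_bounds()
  for (nm in names(p)) {
    if (p[[nm]] < b$lower[nm] || p[[nm]] > b$upper[nm]) {
      abort(sprintf("`%s` = %g outside the fit bounds [%g, %g]",
                    nm, p[[nm]], b$lower[nm], b$upper[nm]))
    }
  }
  structure(p, class = "ddm_params")
}

#' @describeIn ddm_params The box constraints used when fitting.
#' @export
ddm_bounds <- function() {
  nm <- c("lambda", "sigma2_a", "sigma2_s", "sigma2_i", "bound", "phi",
          "tau_phi", "bias", "lapse")
  list(
    lower = stats::setNames(c(-5, 0, 0, 0, 5, 0, 0.001, -5, 0), nm),
    upper = stats::setNames(c(5, 200, 200, 30, 25, 1.2, 2, 5, 1), nm)
  )
}

#' Sensory adaptation trace
#'
#' Both tower streams share one adaptation process: the pulse magnitude C
#' starts at 1; each pulse is delivered at the current C, after which C is
#' multiplied by `phi`; between pulses C recovers toward 1 as
#' `dC/dy = (1 - C) / tau_phi` (closed-form exponential).
#'
#' @param positions_m Pooled pulse positions in meters, sorted ascending.
#' @param phi Adaptation multiplier.
#' @param tau_phi Recovery constant, m (> 0).
#' @return Numeric vector of effective magnitudes C_i, one per pulse.
#' @export
#' @examples
#' adaptation_trace(c(0.50, 0.62), phi = 0.5, tau_phi = 0.5)
adaptation_trace <- function(positions_m, phi, tau_phi) {
  if (tau_phi <= 0) abort("`tau_phi` must be positive.")
  n <- length(positions_m)
  if (n == 0) return(numeric(0))
  if (is.unsorted(positions_m)) abort("positions must be sorted ascending")
  C <- numeric(n)
  c_now <- 1
  y_prev <- positions_m[1]
  for (i in seq_len(n)) {
    gap <- positions_m[i] - y_prev
    c_now <- 1 - (1 - c_now) * exp(-gap / tau_phi)
    C[i] <- c_now
    c_now <- c_now * phi
    y_prev <- positions_m[i]
  }
  C
}

# Build the pulse schedule (meters) shared by propagation and Monte Carlo.
ddm_pulse_schedule <- function(towers_left, towers_right, params) {
  pos <- c(towers_right, towers_left) / 100
  sgn <- c(rep(1, length(towers_right)), rep(-1, length(towers_left)))
  ord <- order(pos)
  pos <- pos[ord]
  sgn <- sgn[ord]
  C <- adaptation_trace(pos, params$phi, params$tau_phi)
  list(pos = pos, mean = sgn * C, sd = sqrt(params$sigma2_s) * C)
}

#' Right-choice probability of the accumulator model on one trial
#'
#' Exact trial likelihood by propagating the accumulator distribution over
#' maze position on a discretized grid with sticky bound bins: linear
#' segments are advanced with the closed-form decay/diffusion map
#' (subdivided so absorption is checked at least every `dy_max` m) and each
#' tower applies an adapted, noisy impulse.
#'
#' @param towers_left,towers_right Tower positions, cm.
#' @param params A [ddm_params()].
#' @param dy_max Largest propagation interval, m.
#' @param n_grid Number of grid points spanning \[-B, B\] (two of which
#'   are the bound bins).
#' @param stem_m Accumulation endpoint (end of the stem), m.
#' @param mass_tol Mass-conservation audit tolerance; a coarser grid is
#'   automatically refined once, then an error is raised.
#' @return `ddm_trial_pr()`: the probability of a right choice.
#'   `ddm_trial_detail()`: a list with `p_right`, `mass` (conservation
#'   audit), `mean` (final first moment), and the final `density`.
#' @export
ddm_trial_pr <- function(towers_left, towers_right, params, dy_max = 0.01,
                         n_grid = 281, stem_m = 3.0, mass_tol = 1e-6) {
  ddm_trial_detail(towers_left, towers_right, params, dy_max, n_grid,
                   stem_m, mass_tol)$p_right
}

#' @rdname ddm_trial_pr
#' @export
ddm_trial_detail <- function(towers_left, towers_right, params,
                             dy_max = 0.01, n_grid = 281, stem_m = 3.0,
                             mass_tol = 1e-6) {
  stopifnot(inherits(params, "ddm_params"))
  sched <- ddm_pulse_schedule(towers_left, towers_right, params)
  run <- function(n_grid, dy_max) {
    segs <- build_segments(sched, stem_m, dy_max)
    out <- ddm_propagate_cpp(segs$dy, segs$mean, segs$sd, params$lambda,
                             params$sigma2_a, params$sigma2_i,
                             params$bound, params$bias, as.integer(n_grid))
    out
  }
  out <- run(n_grid, dy_max)
  if (abs(out$mass - 1) > mass_tol) {
    out <- run(2 * n_grid - 1, dy_max / 2)
    if (abs(out$mass - 1) > mass_tol) {
      abort(sprintf("mass leak %.2e persists after grid refinement",
                    abs(out$mass - 1)))
    }
  }
  list(p_right = params$lapse / 2 + (1 - params$lapse) * out$p_right,
       mass = out$mass, mean = out$mean, density = out$density)
}

build_segments <- function(sched, stem_m, dy_max) {
  # breakpoints: pulse positions, with propagation intervals subdivided
  y <- 0
  dy <- numeric(0)
  mean <- numeric(0)
  sd <- numeric(0)
  add_gap <- function(gap) {
    if (gap <= 0) return()
    k <- ceiling(gap / dy_max)
    dy <<- c(dy, rep(gap / k, k))
    mean <<- c(mean, rep(0, k))
    sd <<- c(sd, rep(-1, k)) # no pulse after these segments
  }
  for (i in seq_along(sched$pos)) {
    add_gap(sched$pos[i] - y)
    y <- sched$pos[i]
    if (length(dy) == 0 || sd[length(sd)] >= 0) {
      # consecutive pulses at the same position: zero-length segment
      dy <- c(dy, 0); mean <- c(mean, 0); sd <- c(sd, -1)
    }
    mean[length(mean)] <- sched$mean[i]
    sd[length(sd)] <- sched$sd[i]
  }
  add_gap(stem_m - y)
  list(dy = dy, mean = mean, sd = sd)
}

#' Monte-Carlo right-choice probability (forward simulation)
#'
#' Euler forward simulation of the accumulator SDE (default step 0.5 cm),
#' algorithmically independent of the distribution propagation in
#' [ddm_trial_pr()] so the two can cross-validate each other.
#'
#' @inheritParams ddm_trial_pr
#' @param n_paths Number of simulated paths.
#' @param dy_cm Euler step, cm.
#' @return `ddm_mc_p_right()` returns the lapse-mixed right-choice
#'   probability estimate; `ddm_mc_paths()` the raw (pre-lapse) fraction
#'   of paths choosing right.
#' @export
ddm_mc_p_right <- function(towers_left, towers_right, params,
                           n_paths = 1000, dy_cm = 0.5, stem_m = 3.0) {
  raw <- ddm_mc_paths(towers_left, towers_right, params, n_paths, dy_cm,
                      stem_m)
  params$lapse / 2 + (1 - params$lapse) * raw
}

#' @rdname ddm_mc_p_right
#' @export
ddm_mc_paths <- function(towers_left, towers_right, params, n_paths = 1,
                         dy_cm = 0.5, stem_m = 3.0) {
  sched <- ddm_pulse_schedule(towers_left, towers_right, params)
  ddm_mc_cpp(sched$pos, sched$mean, sched$sd, stem_m, params$lambda,
             params$sigma2_a, params$sigma2_i, params$bound, params$bias,
             as.integer(n_paths), dy_cm / 100)
}

#' Log-likelihood of observed choices under the accumulator model
#'
#' @param trials Trial tibble.
#' @param params A [ddm_params()].
#' @inheritParams ddm_trial_pr
#' @return Sum over trials of the Bernoulli log-likelihood of the observed
#'   choice given the propagated right-choice probability. Probabilities
#'   are floored at 1e-10 (with a warning; cannot occur with lapse > 0).
#' @export
ddm_loglik <- function(trials, params, dy_max = 0.01, n_grid = 281,
                       stem_m = 3.0) {
  design <- ddm_design(trials)
  ddm_loglik_design(design, params, dy_max, n_grid, stem_m)
}

# Parameter-independent pulse design: concatenated sorted pulse positions
# (m) and signs with per-trial offsets. Built once per dataset so repeated
# likelihood evaluations during fitting cost no R-side work.
ddm_design <- function(trials) {
  scheds <- lapply(seq_len(nrow(trials)), function(i) {
    pos <- c(trials$towers_right[[i]], trials$towers_left[[i]]) / 100
    sgn <- rep(c(1, -1), c(length(trials$towers_right[[i]]),
                           length(trials$towers_left[[i]])))
    ord <- order(pos)
    list(pos = pos[ord], sgn = sgn[ord])
  })
  offset <- c(0L, cumsum(vapply(scheds, function(s) length(s$pos),
                                integer(1))))
  list(
    # trailing sentinel keeps the arrays non-empty for zero-tower inputs
    pos = c(unlist(lapply(scheds, `[[`, "pos")), 0),
    sgn = c(unlist(lapply(scheds, `[[`, "sgn")), 0),
    offset = as.integer(offset),
    choice_right = as.integer(trials$choice == "R")
  )
}

ddm_loglik_design <- function(design, params, dy_max, n_grid, stem_m = 3.0) {
  ddm_loglik_cpp(design$pos, design$sgn, design$offset,
                 design$choice_right, stem_m, dy_max, params$lambda,
                 params$sigma2_a, params$sigma2_s, params$sigma2_i,
                 params$bound, params$phi, params$tau_phi, params$bias,
                 params$lapse, as.integer(n_grid))
}

#' Fit the accumulator model by bounded maximum likelihood
#'
#' Minimizes the negative log-likelihood with box-constrained quasi-Newton
#' (L-BFGS-B) from `n_starts` interior starting points (a default start
#' plus random perturbations), with forward-difference numeric gradients.
#' A coarser propagation grid than the per-trial default keeps fitting
#' tractable; refit the returned optimum with finer settings if needed.
#'
#' @param trials Trial tibble.
#' @param n_starts Number of starts.
#' @param dy_max,n_grid Propagation resolution used during fitting.
#' @param maxit Optimizer iteration cap per start.
#' @param fixed Named list of parameters to hold fixed (e.g.
#'   `list(phi = 1, tau_phi = 0.5)` disables adaptation fitting).
#' @return An object of class `ddm_fit`: `params` (best [ddm_params()]),
#'   `loglik`, `converged`, and `starts` (per-start results).
#' @export
fit_ddm <- function(trials, n_starts = 2, dy_max = 0.25, n_grid = 101,
                    maxit = 30, fixed = list()) {
  if (nrow(trials) < 100) warn("fewer than 100 trials: accumulator fit will be unstable")
  b <- ddm_bounds()
  nm <- names(b$lower)
  free <- setdiff(nm, names(fixed))
  default_start <- c(lambda = 0, sigma2_a = 5, sigma2_s = 5, sigma2_i = 2,
                     bound = 15, phi = 0.9, tau_phi = 0.5, bias = 0,
                     lapse = 0.1)
  # optimize on an unconstrained, unit-scale parameterization: log for the
  # variances and tau, scaled logit for bounded parameters, identity for
  # the sign-indefinite ones; this keeps quasi-Newton line searches well
  # conditioned across the very different natural scales
  logit_tr <- function(lo, hi) {
    list(fwd = function(v) qlogis((clamp(v, lo + 1e-9, hi - 1e-9) - lo) /
                                    (hi - lo)),
         inv = function(z) lo + (hi - lo) * plogis(z))
  }
  log_tr <- list(fwd = function(v) log(pmax(v, 1e-8)),
                 inv = function(z) exp(clamp(z, -18, 8)))
  id_tr <- list(fwd = identity, inv = function(z) clamp(z, -5, 5))
  trs <- list(lambda = id_tr, sigma2_a = log_tr, sigma2_s = log_tr,
              sigma2_i = log_tr, bound = logit_tr(5, 25),
              phi = logit_tr(0.005, 1.2), tau_phi = logit_tr(0.001, 2),
              bias = id_tr, lapse = logit_tr(0.001, 1))
  to_raw <- function(v) {
    vapply(free, function(p) trs[[p]]$fwd(v[[p]]), numeric(1))
  }
  make_params <- function(z) {
    full <- as.list(default_start)
    for (i in seq_along(free)) full[[free[i]]] <- trs[[free[i]]]$inv(z[i])
    full[names(fixed)] <- unlist(fixed)
    # variance inverses can exceed the declared box; clamp to the fit range
    for (p in c("sigma2_a", "sigma2_s", "sigma2_i")) {
      full[[p]] <- min(full[[p]], b$upper[[p]])
    }
    do.call(ddm_params, full)
  }
  design <- ddm_design(trials)
  nll <- function(z) {
    -ddm_loglik_design(design, make_params(z), dy_max, n_grid)
  }
  starts <- list(to_raw(default_start))
  if (n_starts > 1) {
    # deterministic leak-displaced starts before random jitter: the
    # likelihood can be multimodal in the leak sign
    alt <- default_start
    alt["lambda"] <- -1.5
    starts <- c(starts, list(to_raw(alt)))
  }
  if (n_starts > 2) {
    for (s in seq_len(n_starts - 2)) {
      starts <- c(starts, list(starts[[1]] + rnorm(length(free), 0, 0.5)))
    }
  }
  results <- list()
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, nll, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-8,
                           ndeps = rep(1e-3, length(free)))),
      error = function(e) NULL
    )
    results <- c(results, list(o))
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) abort("all accumulator-fit starts failed")
  structure(
    list(params = make_params(best$par), loglik = -best$value,
         converged = best$convergence == 0, starts = results,
         free = free, dy_max = dy_max, n_grid = n_grid,
         n_trials = nrow(trials)),
    class = "ddm_fit"
  )
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("Accumulator model fit (%d trials, lnL = %.1f%s)\n",
              x$n_trials, x$loglik, if (x$converged) "" else ", flagged"))
  print(round(unlist(unclass(x$params)), 4))
  invisible(x)
}
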