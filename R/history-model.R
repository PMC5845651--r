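#' Attach previous-trial history columns
#'
#' Adds `prev_choice` and `prev_outcome` (the immediately preceding trial
#' within the same session, by trial index) to a trial table. Trials
#' without a predecessor get `NA`.
#'
#' @param trials Trial tibble.
#' @return The input with `prev_choice`, `prev_outcome` appended.
#' @export
attach_history <- function(trials) {
  trials <- dplyr::arrange(trials, .data$mouse_id, .data$session_id,
                           .data$trial_index)
  trials <- dplyr::group_by(trials, .data$mouse_id, .data$session_id)
  trials <- dplyr::mutate(
    trials,
    prev_choice = dplyr::lag(.data$choice),
    prev_outcome = dplyr::lag(.data$outcome),
    .consecutive = c(TRUE, diff(.data$trial_index) == 1)
  )
  trials <- dplyr::ungroup(trials)
  trials$prev_choice[!trials$.consecutive] <- NA_character_
  trials$prev_outcome[!trials$.consecutive] <- NA_character_
  trials$.consecutive <- NULL
  trials
}

#' Cue-order evidence design
#'
#' Ranks the pooled towers of each trial by position (ascending; cross-side
#' ties break right-before-left), downsamples ranks by 3, and builds the
#' evidence vector whose j-th coordinate is #R - #L among ranks 3(j-1)+1 to
#' 3j. The dimensionality D is the largest j such that at least
#' `min_trials_last` trials have a full j-th rank triplet (total count >=
#' 3j); higher coordinates are zero for shorter trials. Each trial's vector
#' is divided by the square root of the mean |#R - #L| over trials with the
#' same total count (the per-n normalization table).
#'
#' @param trials Trial tibble.
#' @param min_trials_last Minimum trials informing the last coordinate.
#' @return An object of class `cue_order_design` with the design matrix
#'   `X`, the dimensionality `D`, and the `normalization` table. Apply it
#'   to new trials with [cue_order_evidence()].
#' @export
build_cue_order_design <- function(trials, min_trials_last = 50) {
  ev <- trial_evidence(trials)
  D <- 0L
  while (sum(ev$n_total >= 3 * (D + 1L)) >= min_trials_last) D <- D + 1L
  if (D < 1L) abort("dataset too small to support any cue-order coordinate")
  normalization <- dplyr::summarise(
    dplyr::group_by(ev, .data$n_total),
    mean_abs_delta = mean(abs(.data$delta)),
    n = dplyr::n(), .groups = "drop"
  )
  design <- structure(
    list(D = D, normalization = normalization,
         fallback = mean(abs(ev$delta))),
    class = "cue_order_design"
  )
  design$X <- cue_order_evidence(design, trials)
  design
}

#' @describeIn build_cue_order_design Evidence matrix for (new) trials
#'   under an existing design's dimensionality and normalization.
#' @param design A `cue_order_design`.
#' @export
cue_order_evidence <- function(design, trials) {
  ev <- trial_evidence(trials)
  norm <- stats::setNames(design$normalization$mean_abs_delta,
                          design$normalization$n_total)
  X <- matrix(0, nrow(trials), design$D)
  colnames(X) <- paste0("rank_triplet", seq_len(design$D))
  for (i in seq_len(nrow(trials))) {
    tl <- trials$towers_left[[i]]
    tr <- trials$towers_right[[i]]
    pos <- c(tr, tl)
    if (length(pos) == 0) next
    side_r <- c(rep(1, length(tr)), rep(-1, length(tl)))
    ord <- order(pos, -side_r) # ties: right before left
    signs <- side_r[ord]
    for (j in seq_len(design$D)) {
      ranks <- (3 * (j - 1) + 1):min(3 * j, length(signs))
      if (ranks[1] > length(signs)) break
      X[i, j] <- sum(signs[ranks])
    }
    m <- norm[as.character(ev$n_total[i])]
    if (is.na(m) || m <= 0) m <- max(design$fallback, 1e-6)
    X[i, ] <- X[i, ] / sqrt(m)
  }
  X
}

# -- Eq-style history model ------------------------------------------------

history_design <- function(trials, evidence_form, edges, cue_design,
                           min_trials_last = 50) {
  trials <- attach_history(trials)
  has_hist <- !is.na(trials$prev_choice)
  X <- switch(
    evidence_form,
    spatial_bins = spatial_design(trials, edges),
    cue_order = {
      if (is.null(cue_design)) cue_design <- build_cue_order_design(trials, min_trials_last)
      cue_order_evidence(cue_design, trials)
    },
    none = matrix(0, nrow(trials), 0)
  )
  c_prev <- ifelse(trials$prev_choice == "R", 1, -1)
  o_prev <- ifelse(trials$prev_outcome == "correct", 1, -1)
  h <- cbind(choice = c_prev, outcome = o_prev, interaction = c_prev * o_prev)
  e <- ifelse(trials$prev_outcome == "error", 1, -1)
  list(X = X, h = h, e = e, y = as.numeric(trials$choice == "R"),
       has_hist = has_hist, cue_design = cue_design)
}

history_p_right_vec <- function(par, p0, X, h, e) {
  D <- ncol(X)
  beta0 <- par[1]
  beta_delta <- if (D > 0) par[1 + seq_len(D)] else numeric(0)
  beta_e <- par[D + 2]
  beta0_r <- par[D + 3]
  beta0_l <- par[D + 4]
  beta_h <- par[D + 4 + 1:3]
  drive <- beta0 + if (D > 0) drop(X %*% beta_delta) else 0
  core <- plogis(p0 + (1 + beta_e * e) * drive)
  hb <- drop(h %*% beta_h)
  l_r <- 0.5 * (1 - cos(lapse_arg(beta0_r + hb)))
  l_l <- 0.5 * (1 - cos(lapse_arg(beta0_l - hb)))
  l_l + (1 - l_l - l_r) * core
}

#' Fit the history-modulated logistic choice model
#'
#' The model nests a constant right-choice probability `f_R`: the
#' right-choice probability is
#' `p_R = l_L + (1 - l_L - l_R) * logistic(p0 + (1 + beta_e e)(beta0 + beta_delta' Delta))`
#' with `p0 = qlogis(f_R)`, evidence vector `Delta` given by the spatial
#' bins, the cue-order design, or absent, and post-error slope modulation
#' `e` (+1 after an error, -1 otherwise). Lapses depend on the previous
#' trial through `l_R = (1 - cos(b0R + beta_h' h)) / 2`,
#' `l_L = (1 - cos(b0L - beta_h' h)) / 2` with
#' `h = (prev choice, prev outcome, interaction)` coded +/-1 and the cosine
#' arguments box-limited to \[-pi/2, pi/2\] so lapses stay in \[0, 0.5\].
#' When every free parameter is zero, `p_R = f_R` on every trial.
#'
#' Fitting maximizes the (optionally L1-penalized) log-likelihood; trials
#' without one trial of history are dropped. Non-convergence triggers
#' random multi-start retries before the fit is flagged.
#'
#' @param trials Trial tibble.
#' @param evidence_form "spatial_bins", "cue_order", or "none".
#' @param l1_weight Nonnegative L1 penalty on all free parameters (applied
#'   through a smoothed absolute value; 0 disables).
#' @param edges Spatial bin edges for the spatial form.
#' @param cue_design Optional prebuilt [build_cue_order_design()] (reused,
#'   e.g., from a training fold).
#' @param n_starts Additional random starts after the zero start.
#' @return An object of class `history_fit`: `coefficients` (named),
#'   `f_r`, `loglik`, `converged`, `n_trials`, plus the evidence design
#'   metadata needed by `predict()`.
#' @export
fit_history_model <- function(trials,
                              evidence_form = c("spatial_bins", "cue_order", "none"),
                              l1_weight = 0, edges = spatial_bin_edges(),
                              cue_design = NULL, n_starts = 2) {
  evidence_form <- match.arg(evidence_form)
  des <- history_design(trials, evidence_form, edges, cue_design)
  keep <- des$has_hist
  X <- des$X[keep, , drop = FALSE]
  h <- des$h[keep, , drop = FALSE]
  e <- des$e[keep]
  y <- des$y[keep]
  if (length(y) < 50) abort("too few trials with history to fit")
  f_r <- mean(y)
  p0 <- qlogis(clamp(f_r, 1e-6, 1 - 1e-6))
  D <- ncol(X)
  npar <- D + 7
  sabs <- function(x) sqrt(x^2 + 1e-8)
  nll <- function(par) {
    p <- clamp(history_p_right_vec(par, p0, X, h, e), 1e-10, 1 - 1e-10)
    -sum(y * log(p) + (1 - y) * log(1 - p)) + l1_weight * sum(sabs(par))
  }
  nll_grad <- function(par) {
    beta0 <- par[1]
    beta_delta <- if (D > 0) par[1 + seq_len(D)] else numeric(0)
    beta_e <- par[D + 2]
    beta0_r <- par[D + 3]
    beta0_l <- par[D + 4]
    beta_h <- par[D + 4 + 1:3]
    drive <- beta0 + if (D > 0) drop(X %*% beta_delta) else 0
    mod <- 1 + beta_e * e
    cc <- plogis(p0 + mod * drive)
    hb <- drop(h %*% beta_h)
    a_r <- beta0_r + hb
    a_l <- beta0_l - hb
    l_r <- 0.5 * (1 - cos(lapse_arg(a_r)))
    l_l <- 0.5 * (1 - cos(lapse_arg(a_l)))
    p <- clamp(l_l + (1 - l_l - l_r) * cc, 1e-10, 1 - 1e-10)
    dp <- (p - y) / (p * (1 - p)) # d nll / dp
    dc <- dp * (1 - l_l - l_r) * cc * (1 - cc)
    # lapse derivatives through the smooth saturation
    dlr <- dp * (-cc) * 0.5 * sin(lapse_arg(a_r)) / cosh(2 * a_r / pi)^2
    dll <- dp * (1 - cc) * 0.5 * sin(lapse_arg(a_l)) / cosh(2 * a_l / pi)^2
    g <- numeric(length(par))
    g[1] <- sum(dc * mod)
    if (D > 0) g[1 + seq_len(D)] <- drop(crossprod(X, dc * mod))
    g[D + 2] <- sum(dc * e * drive)
    g[D + 3] <- sum(dlr)
    g[D + 4] <- sum(dll)
    g[D + 4 + 1:3] <- drop(crossprod(h, dlr - dll))
    g + l1_weight * par / sabs(par)
  }
  best <- NULL
  # the cosine lapse transform is stationary at exactly zero in its five
  # parameters, so displaced deterministic starts are included alongside
  # the null start; box bounds keep the line searches out of the saturated
  # region of the smooth clamp
  lapse_start <- rep(0, npar)
  lapse_start[D + 3:4] <- 0.4
  starts <- c(list(rep(0, npar), rep(0.1, npar), lapse_start),
              lapply(seq_len(n_starts), function(i) rnorm(npar, 0, 0.3)))
  lower <- c(-5, rep(-10, D), -5, rep(-3, 5))
  upper <- -lower
  for (s in starts) {
    o <- tryCatch(optim(clamp(s, lower, upper), nll, gr = nll_grad,
                        method = "L-BFGS-B", lower = lower, upper = upper,
                        control = list(maxit = 1000, factr = 1e3)),
                  error = function(err) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) abort("history-model fit failed from every start")
  # the even cosine makes jointly negating (beta0_r, beta0_l, beta_h) an
  # exact symmetry; canonicalize to a nonnegative baseline-lapse sum
  if (best$par[D + 3] + best$par[D + 4] < 0) {
    best$par[D + 3:7] <- -best$par[D + 3:7]
  }
  converged <- best$convergence == 0
  if (!converged) warn("history-model fit flagged: optimizer did not report convergence")
  names(best$par) <- c("beta0",
                       if (D > 0) colnames(X) else character(0),
                       "beta_e", "beta0_r", "beta0_l",
                       "h_choice", "h_outcome", "h_interaction")
  structure(
    list(coefficients = best$par, f_r = f_r, loglik = -best$value,
         l1_weight = l1_weight, evidence_form = evidence_form,
         edges = edges, cue_design = des$cue_design,
         converged = converged, n_trials = length(y)),
    class = "history_fit"
  )
}

#' @export
print.history_fit <- function(x, ...) {
  cat(sprintf("History-modulated logistic fit (%s evidence, %d trials)\n",
              x$evidence_form, x$n_trials))
  cat(sprintf("  f_R = %.3f, lnL = %.1f%s\n", x$f_r, x$loglik,
              if (x$converged) "" else " [flagged]"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict right-choice probabilities from a history-model fit
#'
#' @param object A `history_fit`.
#' @param trials Trial tibble (history is attached internally; trials
#'   without history get the history terms zeroed, which reduces them to
#'   the evidence-only part of the model).
#' @param ... Unused.
#' @return Numeric vector of right-choice probabilities.
#' @export
predict.history_fit <- function(object, trials, ...) {
  des <- history_design(trials, object$evidence_form, object$edges,
                        object$cue_design)
  h <- des$h
  e <- des$e
  h[!des$has_hist, ] <- 0
  e[!des$has_hist] <- 0
  p0 <- qlogis(clamp(object$f_r, 1e-6, 1 - 1e-6))
  history_p_right_vec(unname(object$coefficients), p0, des$X, h, e)
}

#' Log-likelihood of a history-model fit on a trial set
#'
#' @param fit A `history_fit`.
#' @param trials Trial tibble.
#' @return Bernoulli log-likelihood of the observed choices.
#' @export
history_loglik <- function(fit, trials) {
  p <- clamp(predict(fit, trials), 1e-10, 1 - 1e-10)
  y <- as.numeric(trials$choice == "R")
  sum(y * log(p) + (1 - y) * log(1 - p))
}
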