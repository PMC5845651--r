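#' Jeffreys 1-sigma binomial interval
#'
#' Equal-tailed interval of the Beta(k + 1/2, n - k + 1/2) posterior at
#' 1-sigma coverage (the 0.1587 and 0.8413 quantiles).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @return A two-column tibble `lower`, `upper` (proportions).
#' @export
jeffreys_interval <- function(k, n) {
  stopifnot(all(n > 0), all(k >= 0), all(k <= n))
  p <- pnorm(c(-1, 1))
  tibble::tibble(
    lower = qbeta(p[1], k + 0.5, n - k + 0.5),
    upper = qbeta(p[2], k + 0.5, n - k + 0.5)
  )
}

#' Bin trials by evidence strength
#'
#' Groups the signed evidence `delta = #R - #L` into bins of 3 adjacent
#' values, anchored so the central bin is \{-1, 0, 1\}; the bin abscissa is
#' the trial-weighted mean delta.
#'
#' @param trials Trial tibble.
#' @return A tibble with one row per non-empty bin: `bin` (index),
#'   `delta_mean` (weighted abscissa), `n`, `n_right`, `p_right`, and the
#'   Jeffreys 1-sigma interval bounds.
#' @export
bin_delta <- function(trials) {
  stopifnot(nrow(trials) >= 1)
  ev <- trial_evidence(trials)
  ev$bin <- floor((ev$delta + 1) / 3)
  out <- dplyr::summarise(
    dplyr::group_by(ev, .data$bin),
    delta_mean = mean(.data$delta),
    n = dplyr::n(),
    n_right = sum(.data$choice == "R"),
    .groups = "drop"
  )
  out$p_right <- out$n_right / out$n
  ci <- jeffreys_interval(out$n_right, out$n)
  out$lower <- ci$lower
  out$upper <- ci$upper
  dplyr::arrange(out, .data$delta_mean)
}

#' Fit a four-parameter psychometric sigmoid
#'
#' Fits `p_R = b + a / (1 + exp(-(delta - delta0) / lambda))` to binned
#' right-choice proportions by weighted nonlinear least squares, with
#' per-bin binomial weights `n / (p (1 - p))` and bounds `b` in \[0, 0.5\],
#' `a` in \[0, 1\] so the asymptotes stay interpretable. The slope at the
#' midpoint is `a / (4 lambda)`. Data can be passed either as raw trials
#' (binned internally via [bin_delta()]) or as a pre-binned table.
#'
#' @param data Trial tibble, or a binned table with columns `delta_mean`,
#'   `p_right`, `n`.
#' @return An object of class `psychometric_fit` with elements `b`, `a`,
#'   `delta0`, `lambda`, `slope`, `converged`, `bins`, and the `nls` fit.
#'   Degenerate, step-like data yield a flagged (non-converged) fit with a
#'   large-but-finite slope rather than an error.
#' @export
fit_psychometric <- function(data) {
  bins <- if (all(c("delta_mean", "p_right", "n") %in% names(data))) {
    data
  } else {
    bin_delta(data)
  }
  if (nrow(bins) < 4 || min(bins$delta_mean) >= 0 || max(bins$delta_mean) <= 0) {
    abort("need >= 4 evidence bins spanning both signs of delta")
  }
  p_clamped <- clamp(bins$p_right, 0.025, 0.975)
  w <- bins$n / (p_clamped * (1 - p_clamped))
  start <- list(
    b = max(0.01, min(bins$p_right)), a = 0.9,
    delta0 = 0, lambda = 3
  )
  fit <- tryCatch(
    nls(p_right ~ b + a / (1 + exp(-(delta_mean - delta0) / lambda)),
        data = bins, start = start, weights = w,
        algorithm = "port",
        lower = c(b = 0, a = 0, delta0 = -15, lambda = 1e-3),
        upper = c(b = 0.5, a = 1, delta0 = 15, lambda = 50),
        control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # degenerate (e.g. step-function) data: report the steep-limit fit, flagged
    cf <- c(b = min(bins$p_right), a = diff(range(bins$p_right)),
            delta0 = 0, lambda = 1e-3)
    converged <- FALSE
    warn("psychometric fit did not converge; returning flagged steep-limit fit")
    model <- NULL
  } else {
    cf <- coef(fit)
    converged <- isTRUE(fit$convInfo$isConv) && cf[["lambda"]] > 2e-3
    if (!converged) {
      warn("psychometric fit flagged: at or near the steep-slope boundary")
    }
    model <- fit
  }
  structure(
    list(b = unname(cf[["b"]]), a = unname(cf[["a"]]),
         delta0 = unname(cf[["delta0"]]), lambda = unname(cf[["lambda"]]),
         slope = unname(cf[["a"]] / (4 * cf[["lambda"]])),
         converged = converged, bins = bins, model = model),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Psychometric sigmoid fit\n")
  cat(sprintf("  b = %.3f, a = %.3f, delta0 = %.2f, lambda = %.2f\n",
              x$b, x$a, x$delta0, x$lambda))
  cat(sprintf("  slope at midpoint: %.3f per tower (%.1f %%/tower)\n",
              x$slope, 100 * x$slope))
  if (!x$converged) cat("  [flagged: did not converge cleanly]\n")
  invisible(x)
}

#' @export
predict.psychometric_fit <- function(object, delta, ...) {
  object$b + object$a / (1 + exp(-(delta - object$delta0) / object$lambda))
}

#' Lapse rate on easy trials
#'
#' The average error rate, in percent, over trials with |#R - #L| >= 10,
#' with its Jeffreys 1-sigma interval.
#'
#' @param trials Trial tibble.
#' @param min_abs_delta Easy-trial threshold on |delta|.
#' @return A one-row tibble: `lapse_percent`, `lower`, `upper`,
#'   `n_qualifying`. Errors if no trial qualifies.
#' @export
lapse_rate <- function(trials, min_abs_delta = 10) {
  ev <- trial_evidence(trials)
  easy <- ev[abs(ev$delta) >= min_abs_delta, , drop = FALSE]
  if (nrow(easy) == 0) abort("no trials with |delta| at or above the easy threshold")
  k <- sum(easy$outcome == "error")
  n <- nrow(easy)
  ci <- jeffreys_interval(k, n)
  tibble::tibble(lapse_percent = 100 * k / n,
                 lower = 100 * ci$lower, upper = 100 * ci$upper,
                 n_qualifying = n)
}
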