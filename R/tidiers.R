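#' Tidy methods for fitted objects
#'
#' Broom-style one-row-per-term summaries.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("b", "a", "delta0", "lambda", "slope"),
    estimate = c(x$b, x$a, x$delta0, x$lambda, x$slope)
  )
}

#' @rdname tidiers
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, lapse_low = x$b, lapse_high = 1 - x$b - x$a,
                 converged = x$converged, n_bins = nrow(x$bins),
                 n_trials = sum(x$bins$n))
}

#' @rdname tidiers
#' @export
tidy.spatial_logistic_fit <- function(x, ...) x$coefficients

#' @rdname tidiers
#' @export
glance.spatial_logistic_fit <- function(x, ...) {
  tibble::tibble(n_trials = x$n_trials, n_boot = x$n_boot,
                 separated = x$separated)
}

#' @rdname tidiers
#' @export
tidy.history_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidiers
#' @export
glance.history_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, f_r = x$f_r, n_trials = x$n_trials,
                 evidence_form = x$evidence_form, l1_weight = x$l1_weight,
                 converged = x$converged)
}

#' @rdname tidiers
#' @export
tidy.ddm_fit <- function(x, ...) {
  p <- unlist(unclass(x$params))
  tibble::tibble(term = names(p), estimate = unname(p),
                 free = names(p) %in% x$free)
}

#' @rdname tidiers
#' @export
glance.ddm_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_trials = x$n_trials,
                 converged = x$converged, dy_max = x$dy_max,
                 n_grid = x$n_grid)
}

#' @rdname tidiers
#' @export
tidy.sdt_fit <- function(x, ...) {
  if (x$form == "full") {
    tibble::tibble(term = paste0("sigma_", x$sigmas$count),
                   estimate = x$sigmas$sigma)
  } else {
    tibble::tibble(term = c("beta0", "beta1"), estimate = x$par)
  }
}

#' @rdname tidiers
#' @export
glance.sdt_fit <- function(x, ...) {
  tibble::tibble(form = x$form, loglik = x$loglik, n_trials = x$n_trials,
                 converged = x$converged, floored = x$floored)
}

#' @rdname tidiers
#' @export
tidy.model_evaluation <- function(x, ...) x$summary

#' @rdname tidiers
#' @export
glance.model_evaluation <- function(x, ...) {
  tibble::tibble(n_models = nrow(x$summary),
                 n_runs = x$scheme$n_runs, n_folds = x$scheme$n_folds)
}
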