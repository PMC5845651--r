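#' Model information index (bits/trial)
#'
#' Trial-averaged excess log-likelihood of a model over the trivial
#' constant-probability reference, converted to base 2:
#' `MI = (lnL - lnL0) / (n * ln 2)`.
#'
#' @param loglik Model log-likelihood on the evaluation set.
#' @param loglik0 Reference log-likelihood (constant right-choice
#'   probability `f_R`).
#' @param n Number of evaluation trials.
#' @return MI in bits per trial.
#' @export
model_information <- function(loglik, loglik0, n) {
  stopifnot(n > 0)
  (loglik - loglik0) / (n * log(2))
}

#' Cross-validation scheme
#'
#' Pre-draws fold assignments for `n_runs` runs of `n_folds`-fold
#' cross-validation over `n_trials` trials, so every model is evaluated on
#' bit-identical subsamples. Trials are assigned to folds independently of
#' session structure: the choice models treat trials as conditionally
#' independent given their explicit history regressors, which are computed
#' before splitting.
#'
#' @param n_trials Number of trials.
#' @param n_runs Number of runs.
#' @param n_folds Folds per run.
#' @return A `cv_scheme`: list with `folds`, an `n_runs x n_trials`
#'   integer matrix of fold labels.
#' @export
cv_scheme <- function(n_trials, n_runs = 70, n_folds = 3) {
  folds <- matrix(0L, n_runs, n_trials)
  for (r in seq_len(n_runs)) {
    folds[r, ] <- sample(rep_len(seq_len(n_folds), n_trials))
  }
  structure(list(folds = folds, n_runs = n_runs, n_folds = n_folds,
                 n_trials = n_trials),
            class = "cv_scheme")
}

#' Behavioral model interface for cross-validation
#'
#' Wraps a fit function and a predict function into the interface
#' [crossval_evaluate()] expects: `fit(train_trials)` returns any object,
#' and `predict(object, test_trials)` returns per-trial right-choice
#' probabilities.
#'
#' @param name Model label.
#' @param fit Function of a trial tibble returning a fitted object.
#' @param predict Function (fitted object, trial tibble) returning
#'   right-choice probabilities.
#' @return A `cv_model`.
#' @export
cv_model <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "cv_model")
}

#' @describeIn cv_model The trivial constant-probability model (its MI is
#'   identically zero up to train/test sampling noise).
#' @export
cv_model_constant <- function() {
  cv_model("constant",
           fit = function(train) mean(train$choice == "R"),
           predict = function(obj, test) rep(obj, nrow(test)))
}

#' @describeIn cv_model History-modulated logistic model (see
#'   [fit_history_model()]).
#' @param evidence_form Evidence parameterization passed through.
#' @param l1_weight L1 penalty passed through.
#' @export
cv_model_history <- function(evidence_form = "spatial_bins", l1_weight = 0) {
  cv_model(
    paste0("history_", evidence_form),
    fit = function(train) fit_history_model(train, evidence_form,
                                            l1_weight = l1_weight,
                                            n_starts = 0),
    predict = function(obj, test) predict(obj, test)
  )
}

#' @describeIn cv_model Tower-sampling strategy model with side lapses
#'   estimated on the training set (see [strategy_spec()]).
#' @param kind,k Strategy parameters passed through.
#' @export
cv_model_strategy <- function(kind = "k_random", k = 1) {
  cv_model(
    paste0(kind, if (kind == "k_random") k else ""),
    fit = function(train) {
      lp <- tryCatch(estimate_side_lapses(train),
                     error = function(e) list(lapse_r = 0, lapse_l = 0))
      strategy_spec(kind, k = k,
                    lapse_r = min(lp$lapse_r, 0.49),
                    lapse_l = min(lp$lapse_l, 0.49))
    },
    predict = function(obj, test) {
      vapply(seq_len(nrow(test)), function(i) {
        strategy_predict(obj, test$towers_left[[i]], test$towers_right[[i]])
      }, numeric(1))
    }
  )
}

bernoulli_loglik <- function(y, p) {
  p <- clamp(p, 1e-10, 1 - 1e-10)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Cross-validated model evaluation and comparison
#'
#' For every run and fold, each model is fit on the training 2/3 of trials
#' and its Bernoulli log-likelihood evaluated on the held-out 1/3; MI is
#' computed against the constant-`f_R` reference with `f_R` taken from the
#' training fold (no leakage). Every model sees identical fold
#' assignments. The summary reports the median MI across all
#' run-by-fold evaluations; pairwise p-values are the proportion of
#' evaluations in which one model underperforms the other (ties counted
#' half to each).
#'
#' A model failing on a fold excludes that fold for all models (paired
#' comparisons stay paired).
#'
#' @param models List of [cv_model()] objects.
#' @param trials Trial tibble.
#' @param scheme A [cv_scheme()]; defaults to 70 runs of 3-fold.
#' @return An object of class `model_evaluation`: `runs` (long tibble of
#'   per-fold MI per model), `summary` (median MI per model), and
#'   `pairwise` (p-values).
#' @export
crossval_evaluate <- function(models, trials, scheme = NULL) {
  if (is.null(scheme)) scheme <- cv_scheme(nrow(trials))
  stopifnot(scheme$n_trials == nrow(trials))
  y <- as.numeric(trials$choice == "R")
  model_names <- vapply(models, `[[`, character(1), "name")
  rows <- list()
  for (r in seq_len(scheme$n_runs)) {
    fold_of <- scheme$folds[r, ]
    for (f in seq_len(scheme$n_folds)) {
      test_idx <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      train <- trials[train_idx, , drop = FALSE]
      test <- trials[test_idx, , drop = FALSE]
      f_r <- clamp(mean(y[train_idx]), 1e-6, 1 - 1e-6)
      ll0 <- bernoulli_loglik(y[test_idx], rep(f_r, length(test_idx)))
      mi <- vapply(models, function(m) {
        # wrap the fit so a legitimate NULL fit object is not a failure
        obj <- tryCatch(list(fit = m$fit(train)), error = function(e) NULL)
        if (is.null(obj)) return(NA_real_)
        p <- tryCatch(m$predict(obj$fit, test), error = function(e) NULL)
        if (is.null(p) || anyNA(p)) return(NA_real_)
        model_information(bernoulli_loglik(y[test_idx], p), ll0,
                          length(test_idx))
      }, numeric(1))
      if (anyNA(mi)) next # paired-comparison integrity: drop whole fold
      rows[[length(rows) + 1]] <- tibble::tibble(
        run = r, fold = f, model = model_names, mi = mi
      )
    }
  }
  runs <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(runs, .data$model),
    median_mi = median(.data$mi),
    mean_mi = mean(.data$mi),
    n_evaluations = dplyr::n(),
    .groups = "drop"
  )
  pairwise <- list()
  for (i in seq_along(model_names)) {
    for (j in seq_along(model_names)) {
      if (i == j) next
      a <- runs$mi[runs$model == model_names[i]]
      b <- runs$mi[runs$model == model_names[j]]
      pairwise[[length(pairwise) + 1]] <- tibble::tibble(
        model = model_names[i], against = model_names[j],
        p_underperforms = mean(a < b) + 0.5 * mean(a == b)
      )
    }
  }
  structure(
    list(runs = runs, summary = summary,
         pairwise = dplyr::bind_rows(pairwise), scheme = scheme),
    class = "model_evaluation"
  )
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat("Cross-validated model comparison (bits/trial)\n")
  print(x$summary)
  invisible(x)
}

#' False-discovery-rate correction
#'
#' Ranks p-values in ascending order and flags the i-th ranked value as
#' significant when `P_(i) <= alpha * i / n`. The default applies this
#' per-rank rule literally; `stepup = TRUE` additionally propagates
#' significance down from the largest flagged rank (the conventional
#' step-up sweep).
#'
#' @param pvals Numeric vector of p-values.
#' @param alpha Target false-discovery rate.
#' @param stepup Use the step-up sweep instead of the literal per-rank
#'   rule.
#' @return Logical vector (in the original order) of significance flags.
#' @export
bh_fdr <- function(pvals, alpha = 0.05, stepup = FALSE) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  n <- length(pvals)
  ord <- order(pvals)
  flags <- pvals[ord] <= alpha * seq_len(n) / n
  if (stepup && any(flags)) {
    flags[seq_len(max(which(flags)))] <- TRUE
  }
  out <- logical(n)
  out[ord] <- flags
  out
}
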