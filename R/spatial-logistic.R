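#' Spatial evidence bins
#'
#' The cue region is divided into 5 equal segments spanning 10-200 cm
#' (towers appear by proximity, so the earliest possible position is
#' 10 cm). Bins are half-open `[lo, hi)` except the last, which is closed,
#' so a tower exactly at 200 cm falls in bin 5.
#'
#' @param n_bins Number of segments.
#' @param lo,hi Span of the binned region, cm.
#' @return Vector of bin edges, length `n_bins + 1`.
#' @export
spatial_bin_edges <- function(n_bins = 5, lo = 10, hi = 200) {
  seq(lo, hi, length.out = n_bins + 1)
}

#' @describeIn spatial_bin_edges Net evidence (#R - #L) per spatial bin for
#'   one trial.
#' @param towers_left,towers_right Tower positions, cm.
#' @param edges Bin edges from `spatial_bin_edges()`.
#' @export
spatial_bin_evidence <- function(towers_left, towers_right,
                                 edges = spatial_bin_edges()) {
  bin_of <- function(pos) {
    if (length(pos) == 0) return(integer(0))
    b <- findInterval(pos, edges, rightmost.closed = TRUE)
    b[b < 1] <- 1L
    b[b > length(edges) - 1] <- length(edges) - 1L
    b
  }
  n <- length(edges) - 1
  r <- tabulate(bin_of(towers_right), nbins = n)
  l <- tabulate(bin_of(towers_left), nbins = n)
  r - l
}

spatial_design <- function(trials, edges = spatial_bin_edges()) {
  X <- t(vapply(seq_len(nrow(trials)),
                function(i) spatial_bin_evidence(trials$towers_left[[i]],
                                                 trials$towers_right[[i]],
                                                 edges),
                numeric(length(edges) - 1)))
  colnames(X) <- paste0("delta_bin", seq_len(ncol(X)))
  X
}

#' Spatial-bin logistic regression of choice on evidence
#'
#' Fits the probability of a right choice as a logistic function of the net
#' evidence (#R - #L) in each of 5 spatial segments of the cue region, by
#' unregularized maximum likelihood. Coefficient standard deviations come
#' from refitting on `n_boot` bootstrap resamples of the trials. On
#' complete separation the fit is retried with a tiny ridge penalty and
#' flagged.
#'
#' @param trials Trial tibble.
#' @param edges Spatial bin edges.
#' @param n_boot Bootstrap resamples for coefficient errors (0 to skip).
#' @return An object of class `spatial_logistic_fit`: `coefficients` tibble
#'   (term, estimate, boot sd), the bin edges, and flags.
#' @export
fit_spatial_logistic <- function(trials, edges = spatial_bin_edges(),
                                 n_boot = 200) {
  if (nrow(trials) < 500) {
    warn("fewer than 500 trials: spatial logistic weights will be noisy")
  }
  X <- spatial_design(trials, edges)
  y <- as.numeric(trials$choice == "R")
  fit_once <- function(X, y) {
    df <- data.frame(y = y, X)
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    sep <- !fit$converged || any(abs(coef(fit)) > 15)
    if (sep) {
      # ridge fallback via glmnet-free iterative augmentation: add weak
      # pseudo-observations pulling coefficients toward zero
      pen <- rbind(diag(ncol(X)) * 1e3, -diag(ncol(X)) * 1e3)
      colnames(pen) <- colnames(X)
      df2 <- rbind(df, data.frame(y = rep(c(1, 0), each = ncol(X)), pen))
      w <- c(rep(1, nrow(df)), rep(1e-6, 2 * ncol(X)))
      fit <- suppressWarnings(glm(y ~ ., data = df2, family = binomial(),
                                  weights = w))
    }
    list(coef = coef(fit), separated = sep)
  }
  base <- fit_once(X, y)
  if (base$separated) warn("complete separation: regularized refit used")
  boot_sd <- rep(NA_real_, length(base$coef))
  if (n_boot > 0) {
    bc <- matrix(NA_real_, n_boot, length(base$coef))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(X), replace = TRUE)
      bc[b, ] <- fit_once(X[idx, , drop = FALSE], y[idx])$coef
    }
    boot_sd <- apply(bc, 2, sd)
  }
  structure(
    list(
      coefficients = tibble::tibble(
        term = c("bias", colnames(X)),
        estimate = unname(base$coef),
        sd = boot_sd
      ),
      edges = edges, n_trials = nrow(trials),
      separated = base$separated, n_boot = n_boot
    ),
    class = "spatial_logistic_fit"
  )
}

#' @export
print.spatial_logistic_fit <- function(x, ...) {
  cat(sprintf("Spatial-bin logistic fit (%d trials, %d bootstrap resamples)\n",
              x$n_trials, x$n_boot))
  print(x$coefficients)
  invisible(x)
}

#' Weight decay ratio and its shuffle test
#'
#' The decay ratio is the mean of the last two spatial weights over the
#' mean of the first two: values below 1 indicate primacy (early evidence
#' weighted more), 1 indicates spatially even accumulation. Its null
#' distribution is built by shuffling the per-trial bin identities (the
#' evidence design columns are permuted independently per trial) and
#' refitting `n_shuffle` times; the p-value is the fraction of null ratios
#' smaller than the observed one.
#'
#' @param fit A `spatial_logistic_fit`.
#' @param trials The trials the fit was computed on (needed for the
#'   shuffle refits; omit to skip the test).
#' @param n_shuffle Number of shuffle refits.
#' @return A list with `ratio`, `p_value` (NA when `trials` is missing),
#'   and the vector of `null_ratios`.
#' @export
weight_decay_ratio <- function(fit, trials = NULL, n_shuffle = 200) {
  stopifnot(inherits(fit, "spatial_logistic_fit"))
  beta <- fit$coefficients$estimate[-1]
  n <- length(beta)
  early <- mean(beta[1:2])
  late <- mean(beta[(n - 1):n])
  if (early <= 0) {
    warn("mean early weight is not positive; decay ratio undefined")
    return(list(ratio = NA_real_, p_value = NA_real_, null_ratios = numeric(0)))
  }
  ratio <- late / early
  if (is.null(trials)) {
    return(list(ratio = ratio, p_value = NA_real_, null_ratios = numeric(0)))
  }
  X <- spatial_design(trials, fit$edges)
  y <- as.numeric(trials$choice == "R")
  null_ratios <- rep(NA_real_, n_shuffle)
  for (s in seq_len(n_shuffle)) {
    Xs <- t(apply(X, 1, sample))
    colnames(Xs) <- colnames(X)
    cf <- suppressWarnings(
      coef(glm(y ~ ., data = data.frame(y = y, Xs), family = binomial()))
    )[-1]
    e <- mean(cf[1:2])
    if (e > 0) null_ratios[s] <- mean(cf[(n - 1):n]) / e
  }
  ok <- !is.na(null_ratios)
  list(ratio = ratio,
       p_value = mean(null_ratios[ok] < ratio),
       null_ratios = null_ratios[ok])
}

#' Minority-cue position profile for correct vs error trials
#'
#' For each spatial bin, the percentage of trials containing at least one
#' minority cue (a tower on the non-rewarded side) in that bin, computed
#' separately for correct and error trials per mouse, averaged across mice,
#' with the correct-minus-error difference curve and its SEM.
#'
#' @param trials Trial tibble.
#' @param edges Spatial bin edges.
#' @return A list of tibbles: `per_mouse`, `average` (per bin and outcome),
#'   and `difference` (error minus correct, per bin, with SEM across mice).
#' @export
minority_cue_profile <- function(trials, edges = spatial_bin_edges()) {
  n_bins <- length(edges) - 1
  has_minority <- function(i) {
    minority <- if (trials$rewarded_side[i] == "R") {
      trials$towers_left[[i]]
    } else {
      trials$towers_right[[i]]
    }
    counts <- tabulate(
      findInterval(minority, edges, rightmost.closed = TRUE),
      nbins = n_bins
    )
    counts > 0
  }
  flags <- t(vapply(seq_len(nrow(trials)), has_minority, logical(n_bins)))
  long <- tibble::tibble(
    mouse_id = rep(trials$mouse_id, n_bins),
    outcome = rep(trials$outcome, n_bins),
    bin = rep(seq_len(n_bins), each = nrow(trials)),
    present = as.vector(flags)
  )
  per_mouse <- dplyr::summarise(
    dplyr::group_by(long, .data$mouse_id, .data$outcome, .data$bin),
    percent = 100 * mean(.data$present), n = dplyr::n(), .groups = "drop"
  )
  for (oc in c("correct", "error")) {
    if (!any(per_mouse$outcome == oc)) warn(paste0("no ", oc, " trials present"))
  }
  average <- dplyr::summarise(
    dplyr::group_by(per_mouse, .data$outcome, .data$bin),
    percent = mean(.data$percent),
    sem = sd(.data$percent) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(per_mouse[, c("mouse_id", "outcome", "bin", "percent")],
                             names_from = "outcome", values_from = "percent")
  if (all(c("error", "correct") %in% names(wide))) {
    wide$difference <- wide$error - wide$correct
    difference <- dplyr::summarise(
      dplyr::group_by(wide, .data$bin),
      difference = mean(.data$difference, na.rm = TRUE),
      sem = sd(.data$difference, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$difference))),
      .groups = "drop"
    )
  } else {
    difference <- tibble::tibble(bin = integer(), difference = numeric(),
                                 sem = numeric())
  }
  list(per_mouse = per_mouse, average = average, difference = difference,
       edges = edges)
}
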