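#' Alternative tower-sampling strategy models
#'
#' Simple non-accumulation strategies: choose by `k` randomly sampled
#' towers (hypergeometric majority; `k = 1` reduces to #R / (#R + #L)), by
#' the first tower's side, or by the last tower's side. The strategy
#' probability `p_m` is then mixed with experimentally measured side
#' lapses: `p_R = l_R + (1 - l_R - l_L) * p_m`.
#'
#' @param kind One of "k_random", "first_tower", "last_tower".
#' @param k Number of sampled towers (odd; clipped to the trial's total
#'   when larger).
#' @param lapse_r,lapse_l Side lapse rates (see [estimate_side_lapses()]).
#' @return A `strategy_spec` object.
#' @export
strategy_spec <- function(kind = c("k_random", "first_tower", "last_tower"),
                          k = 1, lapse_r = 0, lapse_l = 0) {
  kind <- match.arg(kind)
  stopifnot(k >= 1, lapse_r >= 0, lapse_l >= 0, lapse_r + lapse_l < 1)
  structure(list(kind = kind, k = k, lapse_r = lapse_r, lapse_l = lapse_l),
            class = "strategy_spec")
}

#' Right-choice probability of a strategy model on one trial
#'
#' For `k_random`, the probability that the majority of `k` towers drawn
#' without replacement is on the right, from the hypergeometric
#' distribution; an even split (possible only for even `k`) contributes
#' half. Trials with zero towers get `p_m = 0.5` by convention.
#'
#' @param spec A [strategy_spec()].
#' @param towers_left,towers_right Tower positions, cm.
#' @return The lapse-modulated probability of a right choice.
#' @export
strategy_predict <- function(spec, towers_left, towers_right) {
  stopifnot(inherits(spec, "strategy_spec"))
  n_r <- length(towers_right)
  n_l <- length(towers_left)
  total <- n_r + n_l
  p_m <- if (total == 0) {
    0.5
  } else if (spec$kind == "k_random") {
    k <- min(spec$k, total)
    # k_R ~ Hypergeometric(total, n_r, k); majority means k_R > k/2
    p <- phyper(floor(k / 2), n_r, n_l, k, lower.tail = FALSE)
    if (k %% 2 == 0) p <- p + 0.5 * dhyper(k / 2, n_r, n_l, k)
    p
  } else if (spec$kind == "first_tower") {
    first_side_right(towers_left, towers_right, which = "first")
  } else {
    first_side_right(towers_left, towers_right, which = "last")
  }
  spec$lapse_r + (1 - spec$lapse_r - spec$lapse_l) * p_m
}

# Indicator (0/1) that the first or last pooled tower is on the right;
# cross-side position ties break right-before-left.
first_side_right <- function(towers_left, towers_right, which) {
  pos <- c(towers_right, towers_left)
  side_r <- c(rep(TRUE, length(towers_right)), rep(FALSE, length(towers_left)))
  ord <- order(pos, !side_r) # ties: right first
  pick <- if (which == "first") ord[1] else ord[length(ord)]
  as.numeric(side_r[pick])
}

#' Side lapse rates from single-sided trials
#'
#' On trials with towers on one side only, every strategy model predicts
#' the majority side with certainty, so errors there measure the lapse
#' directly: `l_R` is the error fraction on only-left-tower trials (chose
#' right) and `l_L` the error fraction on only-right-tower trials.
#'
#' @param trials Trial tibble.
#' @return A list with `lapse_r`, `lapse_l`, and the qualifying trial
#'   counts. Errors when either side has no single-sided trials; warns when
#'   the estimates sum to ~1 (chance-level agent, boundary of
#'   identifiability).
#' @export
estimate_side_lapses <- function(trials) {
  ev <- trial_evidence(trials)
  only_left <- ev[ev$n_left > 0 & ev$n_right == 0, , drop = FALSE]
  only_right <- ev[ev$n_right > 0 & ev$n_left == 0, , drop = FALSE]
  if (nrow(only_left) == 0 || nrow(only_right) == 0) {
    abort("need single-sided trials on both sides to estimate lapses")
  }
  l_r <- mean(only_left$choice == "R")
  l_l <- mean(only_right$choice == "L")
  if (l_r + l_l >= 0.9) {
    warn("lapse_r + lapse_l near 1: agent is at or near chance on easy trials")
  }
  list(lapse_r = l_r, lapse_l = l_l,
       n_only_left = nrow(only_left), n_only_right = nrow(only_right))
}

#' Alternation bias
#'
#' The percentage of trials on which the animal chose the arm opposite its
#' choice `lag` trials back, conditioned on the earlier trial's outcome,
#' minus the overall (unconditioned) alternation percentage at that lag.
#' Positive values indicate alternation, negative perseveration. With
#' `run_length > 1` the conditioning trial t0 must terminate a run of that
#' many identical choices with identical outcomes. Requires intact
#' consecutive-trial structure (select with `require_history_trials` and
#' opto-session exclusion first); the lag is counted within session.
#'
#' @param trials Trial tibble.
#' @param condition Outcome of the reference trial t0: "post_reward" or
#'   "post_error".
#' @param lag How many trials after t0 the probed choice occurs (1-5 in
#'   typical use).
#' @param run_length Length of the identical-choice, identical-outcome run
#'   ending at t0 (1 = no run requirement).
#' @return A one-row tibble: `bias_percent`, conditioned and overall
#'   alternation percentages, and the trial count.
#' @export
alternation_bias <- function(trials, condition = c("post_reward", "post_error"),
                             lag = 1, run_length = 1) {
  condition <- match.arg(condition)
  stopifnot(lag >= 1, run_length >= 1)
  want_outcome <- if (condition == "post_reward") "correct" else "error"
  sessions <- dplyr::group_split(
    dplyr::group_by(trials, .data$mouse_id, .data$session_id)
  )
  alt_all <- logical(0)
  alt_cond <- logical(0)
  for (g in sessions) {
    g <- g[order(g$trial_index), , drop = FALSE]
    if (any(diff(g$trial_index) != 1)) {
      abort("non-consecutive trials within a session: apply history-preserving selection first")
    }
    n <- nrow(g)
    if (n <= lag) next
    t0 <- seq_len(n - lag)
    probe <- t0 + lag
    alternated <- g$choice[probe] != g$choice[t0]
    alt_all <- c(alt_all, alternated)
    cond_ok <- g$outcome[t0] == want_outcome
    if (run_length > 1) {
      for (j in seq_along(t0)) {
        i0 <- t0[j]
        if (i0 < run_length) {
          cond_ok[j] <- FALSE
        } else {
          run <- (i0 - run_length + 1):i0
          cond_ok[j] <- cond_ok[j] &&
            all(g$choice[run] == g$choice[i0]) &&
            all(g$outcome[run] == want_outcome)
        }
      }
    }
    alt_cond <- c(alt_cond, alternated[cond_ok])
  }
  tibble::tibble(
    condition = condition, lag = lag, run_length = run_length,
    bias_percent = 100 * (mean(alt_cond) - mean(alt_all)),
    conditioned_percent = 100 * mean(alt_cond),
    overall_percent = 100 * mean(alt_all),
    n_conditioned = length(alt_cond)
  )
}

#' Psychometric fit excluding perseveration bouts
#'
#' Removes every trial inside a run of `run_len` or more identical choices
#' (within session) and refits the psychometric curve.
#'
#' @param trials Trial tibble.
#' @param run_len Minimum identical-choice run length defining a bout.
#' @return A `psychometric_fit` (see [fit_psychometric()]) on the surviving
#'   trials, with the number removed attached as `n_removed`.
#' @export
psychometric_excluding_perseveration <- function(trials, run_len = 3) {
  stopifnot(run_len >= 1)
  sessions <- dplyr::group_split(
    dplyr::group_by(trials, .data$mouse_id, .data$session_id)
  )
  kept <- list()
  removed <- 0L
  for (g in sessions) {
    g <- g[order(g$trial_index), , drop = FALSE]
    r <- rle(g$choice)
    in_bout <- rep(r$lengths >= run_len, r$lengths)
    removed <- removed + sum(in_bout)
    kept[[length(kept) + 1]] <- g[!in_bout, , drop = FALSE]
  }
  out <- dplyr::bind_rows(kept)
  if (nrow(out) == 0) abort("no trials survive perseveration-bout exclusion")
  fit <- fit_psychometric(out)
  fit$n_removed <- removed
  fit
}

#' Linearity test of the psychometric at fixed total tower count
#'
#' At a fixed total #R + #L, a one-random-tower chooser predicts a
#' right-choice probability exactly linear in the evidence:
#' `p = #R / (#R + #L)` (lapse-modulated when side lapses are supplied).
#' The statistic is the sum over delta levels of squared deviations between
#' the observed right-choice fraction and the line, weighted by trial
#' count; its null distribution comes from simulating choices from the
#' line model at the observed per-level trial counts.
#'
#' @param trials Trial tibble.
#' @param total Fixed total tower count selecting the analyzed trials.
#' @param n_null Null simulations.
#' @param lapses Optional list with `lapse_r`, `lapse_l` applied to the
#'   line model (e.g. from [estimate_side_lapses()]).
#' @param min_trials Minimum qualifying trials.
#' @return A list with `p_value`, `statistic`, the per-level table, and the
#'   null statistics.
#' @export
fixed_total_linearity_test <- function(trials, total = 12, n_null = 1000,
                                       lapses = NULL, min_trials = 200) {
  ev <- trial_evidence(trials)
  d <- ev[ev$n_total == total, , drop = FALSE]
  if (nrow(d) < min_trials) {
    abort(sprintf("only %d trials at total = %d (need >= %d)",
                  nrow(d), total, min_trials))
  }
  l_r <- if (is.null(lapses)) 0 else lapses$lapse_r
  l_l <- if (is.null(lapses)) 0 else lapses$lapse_l
  levels <- dplyr::summarise(
    dplyr::group_by(d, .data$delta),
    n = dplyr::n(),
    n_right = sum(.data$choice == "R"),
    .groups = "drop"
  )
  levels$p_observed <- levels$n_right / levels$n
  n_r_side <- (total + levels$delta) / 2
  levels$p_line <- l_r + (1 - l_r - l_l) * n_r_side / total
  stat <- function(p_hat) sum(levels$n * (p_hat - levels$p_line)^2)
  observed <- stat(levels$p_observed)
  null_stats <- vapply(seq_len(n_null), function(i) {
    stat(rbinom(nrow(levels), levels$n, levels$p_line) / levels$n)
  }, numeric(1))
  list(
    p_value = mean(null_stats >= observed),
    statistic = observed,
    levels = levels,
    null_statistics = null_stats
  )
}
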