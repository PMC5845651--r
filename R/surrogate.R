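#' Surrogate test for top-block performance selection
#'
#' Selecting each animal's best blocks trivially improves performance
#' indicators even under a static psychometric curve. This test asks
#' whether the observed improvement in slope and lapse from keeping the top
#' 10% of blocks exceeds what static resampling produces: for each of
#' `n_surrogates` datasets, choices are redrawn from the mouse's fitted
#' static curve at the experienced evidence values, the top blocks are
#' re-selected (mice kept only if at least `min_trials` trials remain), and
#' the slope/lapse improvements recomputed. Per-mouse p-values are the
#' fraction of surrogates whose improvement reaches the observed one, and
#' the population comparison is a one-sided paired signed-rank test of
#' observed vs mean-surrogate improvement.
#'
#' Block ranking ties are broken by block length, then block index.
#'
#' @param trials Trial tibble (several mice supported).
#' @param n_surrogates Number of surrogate datasets.
#' @param top_fraction Fraction of blocks kept.
#' @param min_trials Minimum trials remaining after selection for a mouse
#'   to be included.
#' @return A list with `per_mouse` (observed and surrogate improvements and
#'   p-values per mouse), `population` (one-sided signed-rank p for slope
#'   and lapse), and `excluded_mice`.
#' @export
surrogate_top_block_test <- function(trials, n_surrogates = 200,
                                     top_fraction = 0.10, min_trials = 300) {
  ev <- trial_evidence(trials)
  mice <- unique(ev$mouse_id)
  per_mouse <- list()
  excluded <- character(0)

  block_key <- function(d) paste(d$session_id, d$block_id)

  top_block_trials <- function(d) {
    perf <- dplyr::summarise(
      dplyr::group_by(d, .data$session_id, .data$block_id),
      p = mean(.data$outcome == "correct"),
      len = dplyr::n(), .groups = "drop"
    )
    perf <- perf[order(-perf$p, -perf$len, perf$session_id, perf$block_id), ]
    n_top <- max(1L, floor(top_fraction * nrow(perf)))
    keep <- head(perf, n_top)
    d[block_key(d) %in% paste(keep$session_id, keep$block_id), , drop = FALSE]
  }

  metrics <- function(d) {
    fit <- suppressWarnings(fit_psychometric(d))
    c(slope = fit$slope, lapse = lapse_rate(d)$lapse_percent)
  }

  for (m in mice) {
    d <- ev[ev$mouse_id == m, , drop = FALSE]
    static <- suppressWarnings(fit_psychometric(d))
    top_obs <- top_block_trials(d)
    if (nrow(top_obs) < min_trials) {
      excluded <- c(excluded, m)
      next
    }
    obs_full <- metrics(d)
    obs_top <- metrics(top_obs)
    obs_improve <- c(slope = obs_top[["slope"]] - obs_full[["slope"]],
                     lapse = obs_full[["lapse"]] - obs_top[["lapse"]])

    sur <- matrix(NA_real_, n_surrogates, 2,
                  dimnames = list(NULL, c("slope", "lapse")))
    p_static <- predict(static, d$delta)
    for (k in seq_len(n_surrogates)) {
      s <- d
      s$choice <- ifelse(runif(nrow(s)) < p_static, "R", "L")
      s$outcome <- ifelse(s$choice == s$rewarded_side, "correct", "error")
      s_top <- top_block_trials(s)
      if (nrow(s_top) < min_trials) next
      sf <- metrics(s)
      st <- metrics(s_top)
      sur[k, ] <- c(st[["slope"]] - sf[["slope"]], sf[["lapse"]] - st[["lapse"]])
    }
    ok <- complete.cases(sur)
    per_mouse[[m]] <- tibble::tibble(
      mouse_id = m,
      observed_slope_improvement = obs_improve[["slope"]],
      observed_lapse_improvement = obs_improve[["lapse"]],
      surrogate_slope_improvement = mean(sur[ok, "slope"]),
      surrogate_lapse_improvement = mean(sur[ok, "lapse"]),
      p_slope = mean(sur[ok, "slope"] >= obs_improve[["slope"]]),
      p_lapse = mean(sur[ok, "lapse"] >= obs_improve[["lapse"]]),
      n_surrogates_used = sum(ok)
    )
  }
  per_mouse <- dplyr::bind_rows(per_mouse)
  population <- if (nrow(per_mouse) >= 2) {
    tibble::tibble(
      metric = c("slope", "lapse"),
      p_value = c(
        stats::wilcox.test(per_mouse$observed_slope_improvement,
                           per_mouse$surrogate_slope_improvement,
                           paired = TRUE, alternative = "greater",
                           exact = FALSE)$p.value,
        stats::wilcox.test(per_mouse$observed_lapse_improvement,
                           per_mouse$surrogate_lapse_improvement,
                           paired = TRUE, alternative = "greater",
                           exact = FALSE)$p.value
      )
    )
  } else {
    tibble::tibble(metric = character(), p_value = numeric())
  }
  list(per_mouse = per_mouse, population = population,
       excluded_mice = excluded)
}
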