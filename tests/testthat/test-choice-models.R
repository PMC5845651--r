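test_that("hypergeometric strategy matches exhaustive enumeration exactly", {
  enumerate_p <- function(n_r, n_l, k) {
    # brute force over all C(n_r + n_l, k) draws
    sides <- c(rep(1, n_r), rep(0, n_l))
    draws <- utils::combn(length(sides), k)
    wins <- apply(draws, 2, function(ix) {
      kr <- sum(sides[ix])
      if (2 * kr > k) 1 else if (2 * kr == k) 0.5 else 0
    })
    mean(wins)
  }
  for (total in 2:10) {
    for (n_r in 0:total) {
      n_l <- total - n_r
      for (k in c(1, 3, 5, 7)) {
        if (k > total) next
        spec <- strategy_spec("k_random", k = k)
        got <- strategy_predict(spec,
                                towers_left = seq_len(n_l) * 15,
                                towers_right = seq_len(n_r) * 15 + 1)
        expect_equal(got, enumerate_p(n_r, n_l, k), tolerance = 1e-12)
      }
    }
  }
})

test_that("strategy edge cases follow the documented conventions", {
  # k = 3 with #R = 3, #L = 1: at most one left tower can be drawn
  expect_equal(strategy_predict(strategy_spec("k_random", 3),
                                c(20), c(40, 60, 80)), 1)
  # lapse modulation: k=1, #R=3, #L=1, l_R=0.1, l_L=0.2
  expect_equal(strategy_predict(strategy_spec("k_random", 1, 0.1, 0.2),
                                c(20), c(40, 60, 80)),
               0.1 + 0.7 * 0.75)
  # k = total: full information
  expect_equal(strategy_predict(strategy_spec("k_random", 5),
                                c(20, 40), c(60, 80, 100)), 1)
  # k clipped to the total
  expect_equal(strategy_predict(strategy_spec("k_random", 7),
                                c(20), c(40, 60)), 1)
  # zero towers
  expect_equal(strategy_predict(strategy_spec("k_random", 1),
                                numeric(0), numeric(0)), 0.5)
  # first/last tower indicators
  expect_equal(strategy_predict(strategy_spec("first_tower"), c(30), c(20, 50)), 1)
  expect_equal(strategy_predict(strategy_spec("last_tower"), c(60), c(20, 50)), 0)
})

test_that("side lapses are counted from single-sided trials", {
  n <- 200
  trials <- tibble::tibble(
    mouse_id = "m", session_id = 1L, block_id = 1L, maze_level = 11L,
    trial_index = seq_len(n),
    towers_left = c(replicate(100, c(30, 60), simplify = FALSE),
                    replicate(100, numeric(0), simplify = FALSE)),
    towers_right = c(replicate(100, numeric(0), simplify = FALSE),
                     replicate(100, c(30, 60), simplify = FALSE)),
    rewarded_side = rep(c("L", "R"), each = 100),
    choice = c(rep(c("R", "L"), c(12, 88)), rep(c("L", "R"), c(7, 93))),
    outcome = NA_character_, excess_travel_fraction = 1,
    timed_out = FALSE, aborted = FALSE, opto = FALSE
  )
  trials$outcome <- ifelse(trials$choice == trials$rewarded_side,
                           "correct", "error")
  lp <- estimate_side_lapses(trials)
  expect_equal(lp$lapse_r, 0.12)
  expect_equal(lp$lapse_l, 0.07)
  perfect <- trials
  perfect$choice <- perfect$rewarded_side
  perfect$outcome <- "correct"
  lp0 <- estimate_side_lapses(perfect)
  expect_equal(c(lp0$lapse_r, lp0$lapse_l), c(0, 0))
  expect_error(estimate_side_lapses(trials[1:100, ]), "single-sided")
})

test_that("alternation bias is near zero for history-blind agents on open-loop stimuli", {
  # fair-coin rewarded sides (no debiaser feedback), stimulus-only chooser
  withr::with_seed(50, {
    trials <- simulate_stimuli(3000)
    agent <- agent_k_tower(1)
    for (i in seq_len(nrow(trials))) {
      trials$choice[i] <- agent_choice(agent, trials$towers_left[[i]],
                                       trials$towers_right[[i]])$choice
    }
    trials$outcome <- ifelse(trials$choice == trials$rewarded_side,
                             "correct", "error")
  })
  b <- alternation_bias(trials, "post_reward", lag = 1)
  expect_lt(abs(b$bias_percent), 3 * 100 * sqrt(0.25 / b$n_conditioned) + 1)
})

test_that("alternation bias matches the analytic mixture for a known alternator", {
  # agent alternates with p=0.8 after reward, p=0.5 after error
  withr::with_seed(51, {
    n <- 6000
    choice <- character(n)
    outcome <- character(n)
    rewarded <- sample(c("L", "R"), n, replace = TRUE)
    choice[1] <- "R"
    outcome[1] <- ifelse(choice[1] == rewarded[1], "correct", "error")
    for (i in 2:n) {
      p_alt <- if (outcome[i - 1] == "correct") 0.8 else 0.5
      choice[i] <- if (runif(1) < p_alt) {
        if (choice[i - 1] == "R") "L" else "R"
      } else {
        choice[i - 1]
      }
      outcome[i] <- ifelse(choice[i] == rewarded[i], "correct", "error")
    }
    trials <- tibble::tibble(
      mouse_id = "m", session_id = 1L, block_id = 1L, maze_level = 11L,
      trial_index = seq_len(n),
      towers_left = replicate(n, numeric(0), simplify = FALSE),
      towers_right = replicate(n, c(50), simplify = FALSE),
      rewarded_side = rewarded, choice = choice, outcome = outcome,
      excess_travel_fraction = 1, timed_out = FALSE, aborted = FALSE,
      opto = FALSE
    )
  })
  w_r <- mean(trials$outcome[-n] == "correct")
  overall <- w_r * 0.8 + (1 - w_r) * 0.5
  post_rew <- alternation_bias(trials, "post_reward", 1)
  post_err <- alternation_bias(trials, "post_error", 1)
  expect_equal(post_rew$bias_percent, 100 * (0.8 - overall), tolerance = 2.5)
  expect_equal(post_err$bias_percent, 100 * (0.5 - overall), tolerance = 2.5)
  expect_gt(post_rew$bias_percent, 0)
  expect_lt(post_err$bias_percent, 0)
})

test_that("perseverating agents show growing negative bias with run length", {
  # repeat after error with high probability
  withr::with_seed(52, {
    n <- 8000
    choice <- character(n)
    rewarded <- sample(c("L", "R"), n, replace = TRUE)
    choice[1] <- "L"
    for (i in 2:n) {
      prev_err <- choice[i - 1] != rewarded[i - 1]
      p_repeat <- if (prev_err) 0.85 else 0.5
      choice[i] <- if (runif(1) < p_repeat) choice[i - 1] else
        setdiff(c("L", "R"), choice[i - 1])
    }
    trials <- tibble::tibble(
      mouse_id = "m", session_id = 1L, block_id = 1L, maze_level = 11L,
      trial_index = seq_len(n),
      towers_left = replicate(n, numeric(0), simplify = FALSE),
      towers_right = replicate(n, c(50), simplify = FALSE),
      rewarded_side = rewarded, choice = choice,
      outcome = ifelse(choice == rewarded, "correct", "error"),
      excess_travel_fraction = 1, timed_out = FALSE, aborted = FALSE,
      opto = FALSE
    )
  })
  b1 <- alternation_bias(trials, "post_error", 1, run_length = 1)
  b3 <- alternation_bias(trials, "post_error", 1, run_length = 3)
  expect_lt(b1$bias_percent, 0)
  expect_lt(b3$bias_percent, b1$bias_percent)
})

test_that("perseveration-bout exclusion steepens a contaminated psychometric", {
  withr::with_seed(53, {
    clean <- flat_agent_trials(4000, w = 0.6)
    contaminated <- clean
    # plant perseveration bouts: stretches of identical choices
    i <- 1
    while (i < nrow(contaminated) - 30) {
      if (runif(1) < 0.04) {
        len <- sample(4:8, 1)
        side <- sample(c("L", "R"), 1)
        contaminated$choice[i:(i + len)] <- side
        i <- i + len
      }
      i <- i + 1
    }
    contaminated$outcome <- ifelse(contaminated$choice == contaminated$rewarded_side,
                                   "correct", "error")
  })
  raw <- fit_psychometric(contaminated)
  cleaned <- psychometric_excluding_perseveration(contaminated, run_len = 4)
  expect_gt(cleaned$slope, raw$slope)
  expect_gt(cleaned$n_removed, 0)
  expect_error(psychometric_excluding_perseveration(contaminated, run_len = 1),
               "no trials")
})

test_that("zeroed history model reproduces f_R on every trial", {
  trials <- attach_history(flat_agent_trials(1000))
  fit <- structure(
    list(coefficients = stats::setNames(rep(0, 12),
                                        c("beta0", paste0("delta_bin", 1:5),
                                          "beta_e", "beta0_r", "beta0_l",
                                          "h_choice", "h_outcome",
                                          "h_interaction")),
         f_r = 0.37, evidence_form = "spatial_bins",
         edges = spatial_bin_edges(), cue_design = NULL),
    class = "history_fit"
  )
  expect_equal(predict(fit, trials), rep(0.37, nrow(trials)))
})

test_that("history-model likelihood is invariant under the mirror transform", {
  trials <- flat_agent_trials(1500)
  fit <- structure(
    list(coefficients = c(beta0 = 0.3, delta_bin1 = 0.5, delta_bin2 = 0.4,
                          delta_bin3 = 0.35, delta_bin4 = 0.3,
                          delta_bin5 = 0.25, beta_e = 0.15, beta0_r = 0.4,
                          beta0_l = 0.2, h_choice = 0.2, h_outcome = -0.1,
                          h_interaction = 0.05),
         f_r = 0.5, evidence_form = "spatial_bins",
         edges = spatial_bin_edges(), cue_design = NULL),
    class = "history_fit"
  )
  mirror <- trials
  mirror$towers_left <- trials$towers_right
  mirror$towers_right <- trials$towers_left
  mirror$choice <- ifelse(trials$choice == "R", "L", "R")
  mirror$rewarded_side <- ifelse(trials$rewarded_side == "R", "L", "R")
  mirror$outcome <- trials$outcome
  mfit <- fit
  cf <- fit$coefficients
  mfit$coefficients[c("beta0", "h_choice", "h_interaction")] <-
    -cf[c("beta0", "h_choice", "h_interaction")]
  mfit$coefficients["beta0_r"] <- -cf["beta0_l"]
  mfit$coefficients["beta0_l"] <- -cf["beta0_r"]
  expect_equal(history_loglik(mfit, mirror), history_loglik(fit, trials),
               tolerance = 1e-12)
})

test_that("history-model parameters are recovered from a generating agent", {
  truth <- list(beta_delta = rep(0.45, 5), beta_e = -0.3,
                beta0_r = 0.5, beta0_l = 0.5, beta_h = c(0.25, -0.15, 0))
  withr::with_seed(54, {
    sim <- simulate_dataset(
      agent_logistic_history(beta_delta = truth$beta_delta,
                             beta_e = truth$beta_e,
                             beta0_r = truth$beta0_r, beta0_l = truth$beta0_l,
                             beta_h = truth$beta_h),
      n_sessions = 16, trials_per_session = 500, warmup = FALSE,
      excess_travel_rate = 0
    )
    fit <- fit_history_model(sim$trials, "spatial_bins", n_starts = 1)
  })
  cf <- fit$coefficients
  expect_equal(unname(cf[paste0("delta_bin", 1:5)]), truth$beta_delta,
               tolerance = 0.35)
  expect_equal(unname(cf["h_choice"]), truth$beta_h[1], tolerance = 0.15)
  expect_equal(unname(cf["h_outcome"]), truth$beta_h[2], tolerance = 0.15)
  expect_lt(abs(cf["beta_e"] - truth$beta_e), 0.25)
  # lapse levels implied by the baselines
  expect_equal(0.5 * (1 - cos(cf[["beta0_r"]])), 0.5 * (1 - cos(0.5)),
               tolerance = 0.08)
})

test_that("L1 penalty shrinks history weights on history-free data", {
  trials <- flat_agent_trials(3000)
  norms <- vapply(c(0, 5, 50), function(w) {
    withr::with_seed(55, {
      f <- fit_history_model(trials, "none", l1_weight = w, n_starts = 0)
    })
    sum(abs(f$coefficients[c("h_choice", "h_outcome", "h_interaction")]))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("cue-order design ranks, downsamples, normalizes, and breaks ties", {
  trials <- tiny_trials()
  trials$towers_right[[1]] <- c(20, 50)
  trials$towers_left[[1]] <- c(30)
  design <- list(D = 2L,
                 normalization = tibble::tibble(n_total = 3,
                                                mean_abs_delta = 1, n = 1),
                 fallback = 1)
  class(design) <- "cue_order_design"
  X <- cue_order_evidence(design, trials[1, ])
  # ranks: R@20, L@30, R@50 -> first triplet #R - #L = 1; no second triplet
  expect_equal(unname(X[1, ]), c(1, 0))

  # cross-side tie at the same position: right ranks first
  trials$towers_right[[2]] <- c(40, 90, 120, 150)
  trials$towers_left[[2]] <- c(40, 60)
  design$normalization <- tibble::tibble(n_total = 6, mean_abs_delta = 4,
                                         n = 1)
  X2 <- cue_order_evidence(design, trials[2, ])
  # ranks: R@40, L@40, L@60 | R@90, R@120, R@150 -> (-1+1... ) = (1-2+... )
  expect_equal(unname(X2[1, ]), c(-1, 3) / sqrt(4))

  # dimensionality rule: >= 50 trials must inform the last coordinate
  withr::with_seed(56, {
    counts <- c(rep(6, 60), rep(9, 40))
    many <- tibble::tibble(
      mouse_id = "m", session_id = 1L, block_id = 1L, maze_level = 11L,
      trial_index = seq_along(counts),
      towers_left = lapply(counts, function(k) numeric(0)),
      towers_right = lapply(counts, function(k) seq(10, by = 12, length.out = k)),
      rewarded_side = "R", choice = "R", outcome = "correct",
      excess_travel_fraction = 1, timed_out = FALSE, aborted = FALSE,
      opto = FALSE
    )
  })
  d <- build_cue_order_design(many)
  expect_equal(d$D, 2L)
})

test_that("fixed-total linearity test is calibrated and has power", {
  mk_fixed <- function(n, total, p_fun, seed) {
    withr::with_seed(seed, {
      n_r <- sample(0:total, n, replace = TRUE)
      trials <- tibble::tibble(
        mouse_id = "m", session_id = 1L, block_id = 1L, maze_level = 11L,
        trial_index = seq_len(n),
        towers_left = lapply(total - n_r, function(k) {
          if (k == 0) numeric(0) else seq(10, by = 12, length.out = k)
        }),
        towers_right = lapply(n_r, function(k) {
          if (k == 0) numeric(0) else seq(11, by = 12, length.out = k)
        }),
        rewarded_side = ifelse(n_r * 2 > total, "R", "L"),
        choice = ifelse(runif(n) < p_fun(n_r), "R", "L"),
        outcome = NA_character_, excess_travel_fraction = 1,
        timed_out = FALSE, aborted = FALSE, opto = FALSE
      )
      trials$outcome <- ifelse(trials$choice == trials$rewarded_side,
                               "correct", "error")
      trials
    })
  }
  total <- 12
  # data truly from the line model: p-value should not be extreme
  line <- mk_fixed(2000, total, function(n_r) n_r / total, seed = 57)
  withr::with_seed(58, p_line <- fixed_total_linearity_test(line, total)$p_value)
  expect_gt(p_line, 0.01)
  # steep sigmoid data departs from the line detectably
  steep <- mk_fixed(2000, total, function(n_r) plogis((n_r - total / 2) / 0.8),
                    seed = 59)
  withr::with_seed(60, p_steep <- fixed_total_linearity_test(steep, total)$p_value)
  expect_lt(p_steep, 0.01)
  # single-sided trials predict 0 or 1 before lapse modulation
  lev <- fixed_total_linearity_test(line, total, n_null = 10)$levels
  expect_equal(lev$p_line[lev$delta == total], 1)
  expect_equal(lev$p_line[lev$delta == -total], 0)
  expect_error(fixed_total_linearity_test(line[1:50, ], total), "need >= ")
})
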