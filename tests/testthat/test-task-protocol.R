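test_that("tower draws respect the packing cap and refractory spacing", {
  cfg <- maze_config()
  expect_equal(max_towers_per_side(cfg), 16) # 1 + floor((200-10)/12)
  withr::with_seed(11, {
    draws <- replicate(3000, draw_towers(cfg, "R"), simplify = FALSE)
    sides <- c(lapply(draws, `[[`, "towers_left"),
               lapply(draws, `[[`, "towers_right"))
    expect_lte(max(lengths(sides)), 16)
    gaps_ok <- vapply(sides, function(p) {
      length(p) < 2 || min(diff(p)) >= 12 - 1e-9
    }, logical(1))
    expect_true(all(gaps_ok))
    in_range <- vapply(sides, function(p) {
      length(p) == 0 || (min(p) >= 10 && max(p) <= 200)
    }, logical(1))
    expect_true(all(in_range))
  })
})

test_that("count stage matches the Poisson means raw and the exact conditional law after the majority redraw", {
  cfg <- maze_config()
  withr::with_seed(12, {
    raw <- t(replicate(20000, draw_tower_counts(cfg, conditioned = FALSE)))
    # unconditioned draws: nominal means, 2 SE band
    expect_lt(abs(mean(raw[, 1]) - 7.7), 2 * sqrt(7.7 / 20000))
    expect_lt(abs(mean(raw[, 2]) - 2.3), 2 * sqrt(2.3 / 20000))
    cond <- t(replicate(20000, draw_tower_counts(cfg)))
  })
  # exact conditional expectations from the truncated-Poisson law
  # (independent dpois oracle): E[rew | rew > min] = 7.9290, E[min | .] = 2.1802
  expect_lt(abs(mean(cond[, 1]) - 7.9290), 3 * sd(cond[, 1]) / sqrt(20000))
  expect_lt(abs(mean(cond[, 2]) - 2.1802), 3 * sd(cond[, 2]) / sqrt(20000))
  expect_true(all(cond[, 1] > cond[, 2]))
})

test_that("zero minority mean yields an always-empty minority side", {
  cfg <- maze_config(mean_towers_minority = 0)
  withr::with_seed(13, {
    d <- replicate(200, draw_towers(cfg, "R"), simplify = FALSE)
  })
  expect_true(all(lengths(lapply(d, `[[`, "towers_left")) == 0))
})

test_that("gap-transform placement matches rejection sampling in distribution", {
  cfg <- maze_config()
  reject_place <- function(n) {
    repeat {
      p <- sort(runif(n, 10, 200))
      if (n < 2 || min(diff(p)) >= 12) return(p)
    }
  }
  withr::with_seed(14, {
    for (n in c(2, 4)) {
      mine <- replicate(4000, accumtowers:::place_towers(n, cfg))
      ref <- replicate(4000, reject_place(n))
      # compare first-position and minimum-gap distributions
      expect_gt(stats::ks.test(mine[1, ], ref[1, ])$p.value, 0.001)
      expect_gt(stats::ks.test(apply(mine, 2, function(p) min(diff(p))),
                               apply(ref, 2, function(p) min(diff(p))))$p.value,
                0.001)
    }
  })
})

test_that("debiaser reproduces the capped worked examples", {
  # all recent right trials errors, left trials correct: caps bind
  d <- new_debiaser()
  for (i in 1:40) {
    d <- debias_update(d, "R", TRUE)
    d <- debias_update(d, "L", FALSE)
  }
  expect_equal(debias_p_right(d), 0.7225 / (0.7225 + 0.0225), tolerance = 1e-9)

  # within-cap case: verify p_R = e_R / (e_R + e_L) against an independent
  # arithmetic oracle (half-Gaussian weights recomputed from scratch)
  r_errors <- rep(FALSE, 40); r_errors[seq(3, 39, by = 4)] <- TRUE # ~25%
  l_errors <- rep(FALSE, 40); l_errors[9] <- TRUE                  # ~4%
  d2 <- new_debiaser()
  for (i in 40:1) { # oldest first, so index 1 is newest in state
    d2 <- debias_update(d2, "R", r_errors[i])
    d2 <- debias_update(d2, "L", l_errors[i])
  }
  w <- exp(-(0:39)^2 / (2 * 20^2))
  cap2 <- function(e) min(max(sqrt(e), 0.15), 0.85)^2
  e_r <- cap2(sum(w * r_errors) / sum(w))
  e_l <- cap2(sum(w * l_errors) / sum(w))
  expect_equal(debias_p_right(d2), e_r / (e_r + e_l), tolerance = 1e-12)
  expect_equal(e_r / (e_r + e_l), 0.862, tolerance = 0.02) # worked-example regime

  # symmetry: equal error histories give exactly 0.5
  d3 <- new_debiaser()
  for (i in 1:20) {
    d3 <- debias_update(d3, "R", i %% 2 == 0)
    d3 <- debias_update(d3, "L", i %% 2 == 0)
  }
  expect_equal(debias_p_right(d3), 0.5)
})

test_that("debiaser is exactly side-symmetric under history mirroring", {
  withr::with_seed(15, {
    d <- new_debiaser()
    m <- new_debiaser()
    for (i in 1:120) {
      side <- sample(c("L", "R"), 1)
      err <- runif(1) < 0.3
      d <- debias_update(d, side, err)
      m <- debias_update(m, if (side == "R") "L" else "R", err)
    }
  })
  expect_equal(debias_p_right(d), 1 - debias_p_right(m), tolerance = 1e-12)
  expect_equal(draw_side_probability(d),
               1 - draw_side_probability(m), tolerance = 1e-12)
})

test_that("pseudo-random side draw follows the stated prescription", {
  prescription <- function(p_r, f_hat) {
    if (is.na(f_hat) || f_hat == p_r) return(p_r)
    if (f_hat > p_r) 0.5 * p_r else 0.5 * (1 + p_r)
  }
  expect_equal(prescription(0.6, 0.7), 0.30)
  expect_equal(prescription(0.6, 0.5), 0.80)
  expect_equal(prescription(0.6, 0.6), 0.60)
  # the package function agrees on a cold-start state (p_R = 0.5, no history)
  expect_equal(draw_side_probability(new_debiaser()), 0.5)
})

test_that("an unbiased agent sees a near-balanced side sequence", {
  withr::with_seed(16, {
    sim <- simulate_dataset(agent_constant(0.5), n_sessions = 4,
                            trials_per_session = 500, warmup = FALSE)
  })
  f_r <- mean(sim$trials$rewarded_side == "R")
  expect_lt(abs(f_r - 0.5), 2 / sqrt(4 * nrow(sim$trials))) # debiased: tighter than iid
})

test_that("debiasing raises the frequency of a biased agent's unfavored side", {
  # agent that mostly goes right: right trials mostly correct, left mostly
  # wrong, so the debiaser should over-draw left-rewarded trials
  withr::with_seed(17, {
    sim <- simulate_dataset(agent_constant(0.9), n_sessions = 2,
                            trials_per_session = 500, warmup = FALSE)
  })
  expect_gt(mean(sim$trials$rewarded_side == "L"), 0.55)
})

test_that("shaping state machine follows the warm-up and easy-block rules", {
  st <- new_protocol()
  # 14 warm-up trials, one error per side: accuracy 12/14 = 0.857 >= 0.85,
  # side bias 0 <= 0.10, all good-quality -> advance at the 14th trial
  outcomes <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                TRUE, TRUE, TRUE, TRUE)
  sides <- rep(c("L", "R"), 7)
  for (i in seq_along(outcomes)) {
    expect_equal(st$phase, "warmup")
    st <- protocol_step(st, outcomes[i], sides[i], good = TRUE)
  }
  expect_equal(st$phase, "main")

  # hold accuracy at 50%: easy block entered at the first full window < 55%,
  # exits after exactly 10 trials
  trace <- character(0)
  for (i in 1:60) {
    trace <- c(trace, st$phase)
    st <- protocol_step(st, i %% 2 == 0, "R", good = TRUE)
  }
  first_easy <- which(trace == "easy_block")[1]
  expect_equal(first_easy, 41) # window fills at trial 40, mean 0.5 < 0.55
  expect_equal(sum(trace[first_easy:(first_easy + 9)] == "easy_block"), 10)
  expect_equal(trace[first_easy + 10], "main")
})

test_that("full-session phase sequence matches an independent hand trace", {
  # step-function agent: correct for 50 trials, then at chance for 60,
  # then perfect again; trace the machine by hand alongside
  correct_seq <- c(rep(TRUE, 50), rep(c(TRUE, FALSE), 30), rep(TRUE, 40))
  sides <- rep(c("L", "R"), length.out = length(correct_seq))
  st <- new_protocol()
  phases <- character(0)
  for (i in seq_along(correct_seq)) {
    phases <- c(phases, st$phase)
    st <- protocol_step(st, correct_seq[i], sides[i], TRUE)
  }
  # hand trace: warmup satisfied at trial 10 (all correct, balanced)
  expect_true(all(phases[1:10] == "warmup"))
  expect_true(all(phases[11:50] == "main"))
  # chance streak starts at 51; the 40-trial window dips below 0.55 once
  # enough errors accumulate; every easy block lasts exactly 10
  r <- rle(phases)
  expect_true(all(r$lengths[r$values == "easy_block"] == 10))
  expect_gte(sum(r$values == "easy_block"), 1)
})

test_that("view-angle controller matches its exponential gain law", {
  expect_equal(view_angle_controller(0, 1, 0.01), 0)
  expect_equal(view_angle_controller(0, 0, 0.01), 0)
  # |Theta| = 0.5: rate = exp(1.4 * 0.5^1.2) - 1
  dx <- -0.5 * tan(0.5) # arranges atan2(-dx, 0.5) = +0.5 with dy = 0.5
  expect_equal(view_angle_controller(dx, 0.5, 1),
               exp(1.4 * 0.5^1.2) - 1, tolerance = 1e-9)
  # large displacement angles cap at pi rad/s
  expect_equal(abs(view_angle_controller(10, -0.1, 1)), pi)
  expect_error(view_angle_controller(1, 1, 0), "positive")
})
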