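# Shared fixtures, generated in code with fixed seeds and cached per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, seed, fn) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, withr::with_seed(seed, fn()), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# hand-built three-trial table exercising every column
tiny_trials <- function() {
  tibble::tibble(
    mouse_id = "m1",
    session_id = 1L,
    block_id = 1L,
    maze_level = 11L,
    trial_index = 1:3,
    towers_left = list(c(25.5), numeric(0), c(40, 60.25)),
    towers_right = list(c(30, 55, 120), c(20, 80), c(100)),
    rewarded_side = c("R", "R", "L"),
    choice = c("R", "L", "L"),
    outcome = c("correct", "error", "correct"),
    excess_travel_fraction = c(1.02, 1.05, 1.01),
    timed_out = FALSE,
    aborted = FALSE,
    opto = FALSE
  )
}

# dataset from the evidence-driven history-free logistic agent
flat_agent_trials <- function(n = 4000, w = 0.5) {
  fixture(paste0("flat", n, "_", w * 100), 101, function() {
    sim <- simulate_dataset(
      agent_logistic_history(beta_delta = rep(w, 5)),
      n_sessions = ceiling(n / 500), trials_per_session = 500,
      warmup = FALSE, excess_travel_rate = 0
    )
    sim$trials[seq_len(n), ]
  })
}

# dataset from the one-random-tower chooser
k1_trials <- function(n = 3000) {
  fixture(paste0("k1_", n), 202, function() {
    sim <- simulate_dataset(agent_k_tower(1), n_sessions = ceiling(n / 500),
                            trials_per_session = 500, warmup = FALSE,
                            excess_travel_rate = 0)
    sim$trials[seq_len(n), ]
  })
}

# quick accuracy helper
accuracy <- function(trials) mean(trials$outcome == "correct")
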