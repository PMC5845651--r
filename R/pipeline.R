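#' Run the full simulate-and-analyze pipeline
#'
#' Orchestrates the standard workflow end to end: simulate sessions with a
#' chosen agent, apply trial selection, fit the psychometric curve and
#' lapse rate, the spatial-bin logistic regression with its weight-decay
#' ratio, the history model, and (optionally) run cross-validated model
#' comparison and the kinematics analyses. Every table is written as CSV
#' and a run manifest (seed, configuration, stage outputs, package
#' version) as JSON; rerunning with the same seed reproduces every output.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed; each stage consumes a deterministic substream.
#' @param agent Agent generating the behavior.
#' @param n_sessions,trials_per_session Dataset size.
#' @param config A [maze_config()].
#' @param criteria A [selection_criteria()].
#' @param trajectories Simulate trajectories and run kinematics?
#' @param model_comparison Run a small cross-validated comparison
#'   (constant vs evidence vs evidence+history)?
#' @param cv_runs Cross-validation runs (3 folds each).
#' @return A list with every stage result, invisibly; side effect: files
#'   under `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         agent = agent_logistic_history(beta_delta = rep(0.35, 5),
                                                        beta0_r = 0.55,
                                                        beta0_l = 0.55,
                                                        beta_h = c(0.12, -0.08, 0.02)),
                         n_sessions = 8, trials_per_session = 250,
                         config = maze_config(),
                         criteria = selection_criteria(min_trials_per_mouse = 500),
                         trajectories = FALSE, model_comparison = FALSE,
                         cv_runs = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("accumtowers")),
                   stages = list())
  stage_seed <- function(stage) {
    # independent per-stage substreams from the root seed
    seed + match(stage, c("simulate", "select", "psychometrics",
                          "evidence", "history", "comparison",
                          "kinematics")) * 10007L
  }

  set.seed(stage_seed("simulate"))
  sim <- simulate_dataset(agent, n_sessions, trials_per_session, config,
                          trajectories = trajectories)
  write_session_log(sim$trials, file.path(out_dir, "session_log.jsonl"))
  utils::write.csv(sim$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  if (trajectories) {
    write_trajectories(sim$trajectories, file.path(out_dir, "trajectories.csv"))
  }
  manifest$stages$simulate <- list(n_trials = nrow(sim$trials))

  set.seed(stage_seed("select"))
  sel <- select_trials(sim$trials, criteria)
  utils::write.csv(sel$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  manifest$stages$select <- list(n_kept = nrow(sel$trials))

  set.seed(stage_seed("psychometrics"))
  psych <- fit_psychometric(sel$trials)
  lapse <- lapse_rate(sel$trials)
  utils::write.csv(psych$bins, file.path(out_dir, "psychometric_bins.csv"),
                   row.names = FALSE)
  utils::write.csv(tidy(psych), file.path(out_dir, "psychometric_fit.csv"),
                   row.names = FALSE)
  manifest$stages$psychometrics <- list(slope = psych$slope,
                                        lapse_percent = lapse$lapse_percent)

  set.seed(stage_seed("evidence"))
  slog <- fit_spatial_logistic(sel$trials, n_boot = 50)
  decay <- weight_decay_ratio(slog, sel$trials, n_shuffle = 50)
  utils::write.csv(tidy(slog), file.path(out_dir, "spatial_weights.csv"),
                  row.names = FALSE)
  manifest$stages$evidence <- list(decay_ratio = decay$ratio,
                                   decay_p = decay$p_value)

  set.seed(stage_seed("history"))
  hist_fit <- fit_history_model(sel$trials, "spatial_bins")
  utils::write.csv(tidy(hist_fit), file.path(out_dir, "history_fit.csv"),
                   row.names = FALSE)
  manifest$stages$history <- list(loglik = hist_fit$loglik)

  comparison <- NULL
  if (model_comparison) {
    set.seed(stage_seed("comparison"))
    scheme <- cv_scheme(nrow(sel$trials), n_runs = cv_runs)
    comparison <- crossval_evaluate(
      list(cv_model_constant(), cv_model_strategy("k_random", 1),
           cv_model_history("spatial_bins")),
      sel$trials, scheme
    )
    utils::write.csv(comparison$summary,
                     file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    manifest$stages$comparison <- as.list(
      stats::setNames(comparison$summary$median_mi, comparison$summary$model)
    )
  }

  kin <- NULL
  if (trajectories) {
    set.seed(stage_seed("kinematics"))
    dec <- choice_decoder(sim$trials, sim$trajectories)
    spd <- speed_summary(sim$trajectories)
    utils::write.csv(dec, file.path(out_dir, "choice_decoder.csv"),
                     row.names = FALSE)
    utils::write.csv(spd$summary, file.path(out_dir, "speed_summary.csv"),
                     row.names = FALSE)
    kin <- list(decoder = dec, speed = spd)
    acc200 <- dec$accuracy_percent[dec$y == 200]
    manifest$stages$kinematics <- list(decoding_at_200cm = acc200)
  } else {
    manifest$stages$kinematics <- "skipped (no trajectories requested)"
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(simulation = sim, selection = sel, psychometric = psych,
                 lapse = lapse, spatial_logistic = slog, decay = decay,
                 history = hist_fit, comparison = comparison,
                 kinematics = kin, manifest = manifest))
}
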