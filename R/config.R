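# Reproducible experiment driver: YAML run configuration, seeding,
# training/evaluation/comparison commands, and logging. The thin CLI at
# inst/cli/glucontrol.R dispatches onto these functions.

#' Build or validate a run configuration
#'
#' A run configuration bundles the patient, algorithm, reward variant,
#' learner/predictor/planner settings, scenario and budgets. Unknown keys
#' are rejected; missing keys fall back to package defaults. A content
#' hash is recorded so every artifact can be traced to its configuration.
#'
#' @param x A named list, or a path to a YAML file.
#' @return An object of class `run_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  x$hash <- NULL  # reserved: recomputed below
  defaults <- list(
    algorithm = "ppo", seed = 1L, n_train_steps = 20000,
    n_eval_episodes = 100, reward_variant = "spline_v2",
    cohort = "adult", scenario = "fixed",
    aux_trigger = 5000, retrain_every = 5000,
    learner = list(), predictor = list(), planner = list(),
    patient = list(), output_dir = "runs")
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, x)
  if (!cfg$algorithm %in% c("ppo", "ppo_mpc", "ddpg", "sac", "bbi")) {
    stop("unknown algorithm: ", cfg$algorithm)
  }
  if (!cfg$reward_variant %in% c("original", "linear_v1", "spline_v2")) {
    stop("unknown reward variant: ", cfg$reward_variant)
  }
  if (!cfg$scenario %in% c("fixed", "portion", "time", "snacks")) {
    stop("unknown scenario: ", cfg$scenario)
  }
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

# deterministic short content hash of a configuration
config_hash <- function(cfg) {
  cfg$hash <- NULL
  s <- yaml::as.yaml(cfg[order(names(cfg))])
  h <- 5381
  for (cp in utf8ToInt(s)) h <- (h * 33 + cp) %% 2147483629
  sprintf("h%08x", as.integer(h))  # letter prefix keeps CSV readers from
  # sniffing all-digit hashes as numbers
}

config_objects <- function(cfg) {
  pat_args <- cfg$patient
  pat_args$cohort <- cfg$cohort
  params <- do.call(patient_params, pat_args)
  scenario <- dietary_scenarios(cfg$seed)[[cfg$scenario]]
  env <- patient_env(params = params, scenario = scenario,
                     reward = reward_spec(cfg$reward_variant))
  list(params = params, scenario = scenario, env = env,
       learner = do.call(learner_config, cfg$learner),
       predictor = do.call(predictor_config, cfg$predictor),
       planner = do.call(planner_config, cfg$planner))
}

#' Train a controller from a run configuration
#'
#' Seeds every random stream from the configured seed, trains, and writes
#' the training-curve CSV, the predictor RMSE curve, the safety-action
#' fractions and a checkpoint into the output directory.
#'
#' @param cfg A [run_config()] (or list / YAML path coercible to one).
#' @param out_dir Output directory override.
#' @return Invisibly, a list with the fitted object and file paths.
#' @export
cmd_train <- function(cfg, out_dir = NULL) {
  cfg <- run_config(unclass(cfg))
  if (is.null(out_dir)) out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (cfg$algorithm == "bbi") stop("bbi needs no training; run cmd_evaluate")
  ob <- config_objects(cfg)
  fit <- train_controller(cfg$algorithm, env = ob$env,
                          n_train_steps = cfg$n_train_steps,
                          cfg = ob$learner, predictor_cfg = ob$predictor,
                          planner_cfg = ob$planner, seed = cfg$seed,
                          aux_trigger = cfg$aux_trigger,
                          retrain_every = cfg$retrain_every)
  tag <- paste0(cfg$algorithm, "_seed", cfg$seed, "_", cfg$hash)
  curve_path <- file.path(out_dir, paste0("curve_", tag, ".csv"))
  curve <- fit$curve
  curve$config_hash <- cfg$hash
  utils::write.csv(curve, curve_path, row.names = FALSE)
  rmse_path <- file.path(out_dir, paste0("rmse_", tag, ".csv"))
  utils::write.csv(fit$rmse_curve, rmse_path, row.names = FALSE)
  ckpt_path <- file.path(out_dir, paste0("checkpoint_", tag, ".rds"))
  saveRDS(fit, ckpt_path)
  invisible(list(fit = fit, checkpoint = ckpt_path, curve = curve_path,
                 rmse = rmse_path))
}

#' Evaluate a trained controller (or the BBI baseline)
#'
#' Runs the configured dietary scenario for `n_eval_episodes` one-day
#' episodes and writes the glycemic report and the per-episode cumulative
#' rewards (for paired comparisons) as CSV.
#'
#' @param cfg A [run_config()].
#' @param checkpoint Path to a checkpoint from [cmd_train()]; not needed
#'   for `algorithm = "bbi"`.
#' @param out_dir Output directory override.
#' @param n_episodes Episode-count override (e.g. for smoke tests).
#' @return Invisibly, a list with the report and file paths.
#' @export
cmd_evaluate <- function(cfg, checkpoint = NULL, out_dir = NULL,
                         n_episodes = NULL) {
  cfg <- run_config(unclass(cfg))
  if (is.null(out_dir)) out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(n_episodes)) n_episodes <- cfg$n_eval_episodes
  ob <- config_objects(cfg)
  controller <- if (cfg$algorithm == "bbi") {
    bbi_controller()
  } else {
    if (is.null(checkpoint) || !file.exists(checkpoint)) {
      stop("checkpoint required for algorithm ", cfg$algorithm)
    }
    readRDS(checkpoint)
  }
  traces <- lapply(seq_len(n_episodes), function(e) {
    run_episode(ob$env, controller,
                seed = derive_seed(cfg$seed, paste0("eval", e)))
  })
  rep <- glycemic_report(traces)
  tag <- paste0(cfg$algorithm, "_seed", cfg$seed, "_", cfg$hash)
  rep_path <- file.path(out_dir, paste0("report_", tag, ".csv"))
  tab <- report_table(stats::setNames(list(stats::setNames(list(rep),
                                                           cfg$scenario)),
                                      cfg$algorithm))
  tab$config_hash <- cfg$hash
  utils::write.csv(tab, rep_path, row.names = FALSE)
  rew_path <- file.path(out_dir, paste0("rewards_", tag, ".csv"))
  rewards <- data.frame(
    episode = seq_len(n_episodes),
    reward = vapply(traces, function(tr) sum(tr$reward), numeric(1)),
    seed = cfg$seed, algorithm = cfg$algorithm, config_hash = cfg$hash)
  utils::write.csv(rewards, rew_path, row.names = FALSE)
  invisible(list(report = rep, report_path = rep_path,
                 rewards_path = rew_path))
}

#' Compare evaluated runs with paired t tests
#'
#' Reads the per-episode reward CSVs of two or more evaluated runs on
#' matching seeds and reports pairwise paired t tests plus a summary
#' table.
#'
#' @param reward_files Character vector of `rewards_*.csv` paths from
#'   [cmd_evaluate()] (>= 2).
#' @return A data frame with one row per method pair.
#' @export
cmd_compare <- function(reward_files) {
  stopifnot(length(reward_files) >= 2)
  runs <- lapply(reward_files, utils::read.csv)
  seeds <- vapply(runs, function(r) r$seed[1], numeric(1))
  if (length(unique(seeds)) != 1) {
    stop("runs evaluated under different seeds cannot be paired")
  }
  n <- length(runs)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- runs[[i]]$reward; b <- runs[[j]]$reward
      m <- min(length(a), length(b))
      tt <- paired_t(a[seq_len(m)], b[seq_len(m)])
      rows[[length(rows) + 1]] <- data.frame(
        method_a = runs[[i]]$algorithm[1],
        method_b = runs[[j]]$algorithm[1],
        mean_a = mean(a), mean_b = mean(b), t = tt$t, p = tt$p)
    }
  }
  do.call(rbind, rows)
}
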