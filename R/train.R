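#' Collect exploratory transitions from the virtual patient
#'
#' Runs a random exploratory policy (a mixture favouring low insulin with
#' occasional boluses, covering the action range) and records
#' (state window, action, next true glucose) triplets, e.g. to pre-train
#' the glucose predictor.
#'
#' @param n Number of transitions.
#' @param env A [patient_env()]; default patient when `NULL`.
#' @param seed Seed for episodes and the exploration draws.
#' @return A list with matrices `G`, `I` (n x k) and vectors `A`, `Y`.
#' @export
collect_transitions <- function(n, env = NULL, seed = 1L) {
  if (is.null(env)) env <- patient_env()
  k <- env$k
  G <- matrix(0, n, k); I <- matrix(0, n, k)
  A <- numeric(n); Y <- numeric(n)
  rng <- local_rng(derive_seed(seed, "explore"))
  cnt <- 0L; ep <- 0L
  while (cnt < n) {
    ep <- ep + 1L
    env_reset(env, seed = derive_seed(seed, paste0("explore_ep", ep)))
    while (!env$terminated && cnt < n) {
      w <- env$window
      a <- if (rng$runif(1) < 0.7) rng$runif(1, -1, 0) else rng$runif(1, 0, 1)
      res <- env_step(env, a)
      cnt <- cnt + 1L
      G[cnt, ] <- w$glucose; I[cnt, ] <- w$insulin
      A[cnt] <- a; Y[cnt] <- res$true_glucose
    }
  }
  list(G = G, I = I, A = A, Y = Y)
}

#' Train a closed-loop insulin controller
#'
#' The main fitting entry point. Trains one of the actor-critic learners
#' on the virtual patient; with `algo = "ppo_mpc"` the hybrid layer is
#' added: an auxiliary buffer feeds the Gaussian glucose predictor, and
#' once its held-out RMSE passes the activation gate every decision is
#' screened by MPC rollouts with the analytic safety controller as
#' fallback, while planner-selected actions fine-tune the policy through
#' the imitation loss.
#'
#' @param algo `"ppo"`, `"ppo_mpc"`, `"ddpg"` or `"sac"`.
#' @param env A [patient_env()] (default patient when `NULL`).
#' @param n_train_steps Environment interaction budget.
#' @param cfg A [learner_config()].
#' @param predictor_cfg A [predictor_config()] (hybrid only).
#' @param planner_cfg A [planner_config()] (hybrid only).
#' @param seed Run seed; fans out to env/policy/predictor/planner streams.
#' @param aux_trigger Auxiliary-buffer trigger threshold (hybrid only).
#' @param retrain_every Predictor retraining cadence in new samples.
#' @param verbose Print progress.
#' @return An object of class `glucontrol_agent` with the trained policy,
#'   predictor, gate state, and training curves (`curve`: episode
#'   cumulative rewards; `rmse_curve`; `tag_counts`).
#' @export
train_controller <- function(algo = c("ppo", "ppo_mpc", "ddpg", "sac"),
                             env = NULL, n_train_steps = 20000,
                             cfg = learner_config(),
                             predictor_cfg = predictor_config(),
                             planner_cfg = planner_config(),
                             seed = 1L, aux_trigger = 5000,
                             retrain_every = 5000, verbose = FALSE) {
  algo <- match.arg(algo)
  if (is.null(env)) env <- patient_env()
  hybrid <- algo == "ppo_mpc"
  base_algo <- if (hybrid) "ppo" else algo
  agent <- agent_init(base_algo, cfg, seed = derive_seed(seed, "policy"))
  pol_rng <- local_rng(derive_seed(seed, "policy_rng"))
  plan_rng <- local_rng(derive_seed(seed, "planner"))
  predictor <- NULL; gate <- NULL; aux <- NULL; queue <- NULL
  if (hybrid) {
    predictor <- predictor_init(predictor_cfg, k = env$k,
                                seed = derive_seed(seed, "predictor"))
    gate <- rmse_gate(predictor_cfg$rmse_threshold,
                      predictor_cfg$rmse_hysteresis)
    aux <- aux_buffer(capacity = max(20000, aux_trigger),
                      trigger_threshold = aux_trigger, k = env$k)
    queue <- queue_init(256)
  }
  on_policy <- base_algo == "ppo"
  if (!on_policy) {
    buf <- replay_init(cfg$replay_capacity, k = env$k)
    off_batch <- min(cfg$batch_size, 256)
  }
  total <- cfg$total_steps <- max(cfg$total_steps, n_train_steps)
  agent$cfg <- cfg

  step <- 0L; episode <- 0L
  curve_ep <- integer(0); curve_rew <- numeric(0); curve_step <- integer(0)
  rmse_steps <- integer(0); rmse_vals <- numeric(0)
  tag_counts <- c(rl = 0L, mpc = 0L, safety = 0L)
  next_retrain <- aux_trigger
  ep_rew <- 0

  # on-policy rollout storage
  rs <- cfg$rollout_steps
  bX <- array(0, c(rs, env$k, 2)); bu <- numeric(rs); blp <- numeric(rs)
  br <- numeric(rs); bv <- numeric(rs); bd <- logical(rs); bn <- 0L

  env_reset(env, seed = derive_seed(seed, "ep0"))
  while (step < n_train_steps) {
    w <- env$window
    if (hybrid && gate$active) {
      hs <- hybrid_step(env, agent, predictor, gate, planner_cfg,
                        rng = plan_rng, imitation_queue = queue)
      res <- hs$result; tag <- hs$tag
      a <- hs$action; u <- hs$u; lp <- hs$log_prob; v <- hs$value
    } else {
      act <- agent_act(agent, w, rng = pol_rng)
      res <- env_step(env, act$action)
      tag <- "rl"; a <- act$action; u <- act$u
      lp <- act$log_prob; v <- act$value
    }
    step <- step + 1L
    tag_counts[tag] <- tag_counts[tag] + 1L
    ep_rew <- ep_rew + res$reward
    if (hybrid) aux_add(aux, w, a, res$true_glucose)

    if (on_policy) {
      bn <- bn + 1L
      bX[bn, , ] <- windows_to_array(w)[1, , ]
      bu[bn] <- u; blp[bn] <- lp; br[bn] <- res$reward
      bv[bn] <- v; bd[bn] <- res$terminated
      if (bn == rs) {
        last_v <- if (res$terminated) 0 else agent_value(agent, env$window)
        g <- gae_advantages(br, bv, cfg$discount, cfg$gae_lambda, bd, last_v)
        batch <- list(X = bX, u = bu, log_prob = blp,
                      advantages = g$advantages, returns = g$returns)
        imitation <- NULL
        if (hybrid && length(queue$a_star) > 0) {
          imitation <- list(X = windows_to_array(queue$windows),
                            a_star = queue$a_star)
        }
        lr <- lr_at(min(step, total), cfg)
        for (e in seq_len(cfg$ppo_epochs)) {
          agent <- ppo_update(agent, batch, lr, imitation)$agent
        }
        bn <- 0L
      }
    } else {
      x_now <- windows_to_array(w)[1, , ]
      x_next <- windows_to_array(env$window)[1, , ]
      replay_add(buf, x_now, a, res$reward, x_next, res$terminated)
      if (buf$n >= 200 && step %% 2 == 0) {
        b <- replay_sample(buf, off_batch, pol_rng)
        lr <- lr_at(min(step, total), cfg)
        agent <- if (base_algo == "ddpg") ddpg_update(agent, b, lr)$agent
                 else sac_update(agent, b, lr, pol_rng)$agent
      }
    }

    if (hybrid && aux$n >= next_retrain) {
      ep <- if (predictor$trained) predictor_cfg$retrain_epochs else NULL
      predictor <- train_predictor(predictor, aux,
                                   seed = derive_seed(seed,
                                                      paste0("pt", aux$n)),
                                   epochs = ep)
      gate_update(gate, predictor$last_rmse)
      rmse_steps <- c(rmse_steps, step)
      rmse_vals <- c(rmse_vals, predictor$last_rmse)
      next_retrain <- next_retrain + retrain_every
      if (verbose) {
        message(sprintf("step %d: predictor RMSE %.2f, gate %s", step,
                        predictor$last_rmse,
                        if (gate$active) "active" else "inactive"))
      }
    }

    if (res$terminated) {
      episode <- episode + 1L
      curve_ep <- c(curve_ep, episode)
      curve_rew <- c(curve_rew, ep_rew)
      curve_step <- c(curve_step, step)
      ep_rew <- 0
      env_reset(env, seed = derive_seed(seed, paste0("ep", episode)))
      if (verbose && episode %% 10 == 0) {
        message(sprintf("step %d episode %d mean recent reward %.1f", step,
                        episode,
                        mean(utils::tail(curve_rew, 10))))
      }
    }
  }

  structure(list(
    algo = algo, agent = agent, predictor = predictor, gate = gate,
    planner_cfg = planner_cfg, cfg = cfg, seed = seed,
    env_template = list(params = env$params, scenario = env$scenario,
                        reward = env$reward_spec, risk = env$risk,
                        k = env$k, step_min = env$step_min,
                        max_steps = env$max_steps,
                        action_tau = env$action_tau),
    n_train_steps = n_train_steps,
    curve = data.frame(episode = curve_ep, step = curve_step,
                       reward = curve_rew),
    rmse_curve = data.frame(step = rmse_steps, rmse = rmse_vals),
    tag_counts = tag_counts
  ), class = "glucontrol_agent")
}

#' @export
print.glucontrol_agent <- function(x, ...) {
  cat(sprintf("<glucontrol_agent> algo=%s, trained %d steps, %d episodes\n",
              x$algo, x$n_train_steps, nrow(x$curve)))
  if (nrow(x$curve) > 0) {
    cat(sprintf("  final training reward (last 10 ep): %.1f\n",
                mean(utils::tail(x$curve$reward, 10))))
  }
  if (!is.null(x$gate)) {
    cat(sprintf("  predictor RMSE %.2f mg/dL, MPC gate %s\n",
                x$predictor$last_rmse,
                if (x$gate$active) "active" else "inactive"))
    f <- x$tag_counts / max(1, sum(x$tag_counts))
    cat(sprintf("  action provenance: rl %.2f, mpc %.2f, safety %.2f\n",
                f["rl"], f["mpc"], f["safety"]))
  }
  invisible(x)
}

#' @export
summary.glucontrol_agent <- function(object, ...) {
  print(object)
  if (nrow(object$curve) > 0) {
    cat("\nTraining-curve quartiles (episode cumulative reward):\n")
    print(stats::quantile(object$curve$reward))
  }
  invisible(object)
}

#' @export
plot.glucontrol_agent <- function(x, ...) {
  if (nrow(x$curve) == 0) stop("no training curve recorded")
  graphics::plot(x$curve$step, x$curve$reward, type = "l",
                 xlab = "environment step",
                 ylab = "episode cumulative reward",
                 main = sprintf("%s training curve", x$algo), ...)
  invisible(x)
}

#' Policy action for an observation window
#' @param object A trained `glucontrol_agent`.
#' @param window An observation window (or list of windows).
#' @param ... Unused.
#' @return Deterministic action(s) in \[-1, 1\].
#' @export
predict.glucontrol_agent <- function(object, window, ...) {
  agent_act(object$agent, window, deterministic = TRUE)$action
}

#' @export
controller_step.glucontrol_agent <- function(controller, env) {
  if (controller$algo == "ppo_mpc" && !is.null(controller$gate) &&
      controller$gate$active) {
    rng <- controller$eval_rng
    if (is.null(rng)) {
      # no persistent stream handed in: derive a fresh deterministic
      # stream per control step so rollout noise never repeats
      rng <- local_rng(derive_seed(controller$seed,
                                   paste0("eval", env$step_index,
                                          "_", env$clock)))
    }
    hs <- hybrid_step(env, controller$agent, controller$predictor,
                      controller$gate, controller$planner_cfg, rng = rng)
    hs$result
  } else {
    a <- agent_act(controller$agent, env$window,
                   deterministic = TRUE)$action
    env_step(env, a)
  }
}

#' Simulate evaluation episodes under a trained controller
#'
#' @param object A trained `glucontrol_agent`.
#' @param nsim Number of one-day episodes.
#' @param seed Base seed.
#' @param scenario Optional [meal_scenario()] override.
#' @param ... Unused.
#' @return A list of episode trace data frames (see [run_episode()]).
#' @export
simulate.glucontrol_agent <- function(object, nsim = 1, seed = NULL,
                                      scenario = NULL, ...) {
  if (is.null(seed)) seed <- object$seed
  tmpl <- object$env_template
  env <- patient_env(params = tmpl$params,
                     scenario = if (is.null(scenario)) tmpl$scenario
                                else scenario,
                     reward = tmpl$reward, risk = tmpl$risk, k = tmpl$k,
                     step_min = tmpl$step_min, max_steps = tmpl$max_steps,
                     action_tau = tmpl$action_tau)
  object$eval_rng <- local_rng(derive_seed(seed, "eval"))
  lapply(seq_len(nsim), function(e) {
    run_episode(env, object, seed = derive_seed(seed, paste0("sim", e)))
  })
}
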