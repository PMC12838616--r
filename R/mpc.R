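#' MPC planner configuration
#'
#' @param horizon Rollout depth in control steps (default 6 = 30 min).
#' @param n_rollouts Candidate trajectories per decision (default 30).
#' @param hypo_unsafe_threshold Predicted glucose below this marks a
#'   trajectory unsafe (default 54 mg/dL, strict inequality).
#' @param hyper_unsafe_threshold Optional upper marking threshold
#'   (default `NULL` = off; 250 mg/dL in the wide preset).
#' @return An object of class `planner_config`.
#' @export
planner_config <- function(horizon = 6, n_rollouts = 30,
                           hypo_unsafe_threshold = 54,
                           hyper_unsafe_threshold = NULL) {
  stopifnot(horizon >= 1, n_rollouts >= 1, hypo_unsafe_threshold > 0)
  structure(list(horizon = horizon, n_rollouts = n_rollouts,
                 hypo_unsafe_threshold = hypo_unsafe_threshold,
                 hyper_unsafe_threshold = hyper_unsafe_threshold),
            class = "planner_config")
}

#' Wide-band planner preset
#'
#' Marks trajectories unsafe outside (70, 250) mg/dL instead of the
#' default hard 54 mg/dL filter.
#' @inheritParams planner_config
#' @export
planner_config_wide <- function(horizon = 6, n_rollouts = 30) {
  planner_config(horizon, n_rollouts, hypo_unsafe_threshold = 70,
                 hyper_unsafe_threshold = 250)
}

new_trajectory <- function(actions, predicted_glucose, rewards) {
  structure(list(actions = actions, predicted_glucose = predicted_glucose,
                 rewards = rewards, safe = NA,
                 cumulative_reward = sum(rewards)),
            class = "trajectory")
}

#' Mark a trajectory's safety flag
#'
#' A trajectory is unsafe iff any predicted glucose falls strictly below
#' the hypoglycaemia threshold (or above the hyperglycaemia threshold
#' when enabled). A value of exactly 54 mg/dL is still safe.
#'
#' @param traj A `trajectory`.
#' @param cfg A [planner_config()].
#' @return The trajectory with its `safe` flag set.
#' @export
mark_safety <- function(traj, cfg = planner_config()) {
  unsafe <- any(traj$predicted_glucose < cfg$hypo_unsafe_threshold)
  if (!is.null(cfg$hyper_unsafe_threshold)) {
    unsafe <- unsafe || any(traj$predicted_glucose >
                              cfg$hyper_unsafe_threshold)
  }
  traj$safe <- !unsafe
  traj
}

#' Simulate candidate trajectories through the glucose predictor
#'
#' Rolls the policy and the one-step predictor forward for `horizon`
#' steps from the current observation window, with no environment
#' interaction. Candidate diversity comes from sampling the stochastic
#' policy; the predicted mean is recorded for safety marking while the
#' rolled-forward state uses a Gaussian sample. Rewards come from the
#' package reward function on the sampled glucose.
#'
#' @param agent The policy (an `rl_agent`).
#' @param predictor A trained [predictor_init()] object (or any object
#'   with a [predict_next()] method contract).
#' @param start_window The current observation window.
#' @param cfg A [planner_config()].
#' @param gate An [rmse_gate()]; rollouts are refused while inactive.
#' @param rng A [local_rng()] stream.
#' @param env Optional environment handle passed to truthful-mock
#'   predictors.
#' @param reward,risk Reward and risk parameter objects.
#' @return A list of `n_rollouts` marked trajectories.
#' @export
mpc_rollouts <- function(agent, predictor, start_window,
                         cfg = planner_config(), gate = NULL, rng = NULL,
                         env = NULL, reward = reward_spec(),
                         risk = risk_params()) {
  rm <- rollout_matrices(agent, predictor, start_window, cfg, gate, rng,
                         env, reward, risk)
  lapply(seq_len(cfg$n_rollouts), function(i) {
    mark_safety(new_trajectory(rm$actions[i, ], rm$pred_g[i, ],
                               rm$rewards[i, ]), cfg)
  })
}

# matrix-level rollout engine shared by mpc_rollouts and hybrid_step:
# returns n x h matrices (actions, predicted means, rewards) plus the
# start-state encoder features and policy mean when the compiled path ran
rollout_matrices <- function(agent, predictor, start_window,
                             cfg = planner_config(), gate = NULL,
                             rng = NULL, env = NULL,
                             reward = reward_spec(),
                             risk = risk_params()) {
  if (!is.null(gate) && !gate$active) {
    stop("predictor gate inactive: hybrid layer must be bypassed")
  }
  n <- cfg$n_rollouts; h <- cfg$horizon
  k <- length(start_window$glucose)
  G <- matrix(rep(start_window$glucose, each = n), n, k)
  I <- matrix(rep(start_window$insulin, each = n), n, k)
  actions <- matrix(0, n, h)
  pred_g <- matrix(0, n, h)
  rewards <- matrix(0, n, h)
  imax <- if (!is.null(env)) env$params$pump_max_rate else 5
  tau <- if (!is.null(env)) env$action_tau else 4
  truthful <- inherits(predictor, "truthful_predictor")
  if (truthful) {
    tenv <- predictor$env
    st <- matrix(rep(tenv$state, each = n), n, 3)
    tclock <- tenv$clock
    meal_done <- tenv$meal_idx_done
  }
  learned <- inherits(predictor, "glucose_predictor")
  # pre-draw all noise so the compiled and R rollout paths are identical
  draw <- function(m) if (is.null(rng)) stats::rnorm(m) else rng$rnorm(m)
  eps_act <- matrix(draw(n * h), n, h)
  eps_samp <- matrix(draw(n * h), n, h)
  if (!truthful && learned && agent$algo == "ppo" &&
      predictor$cfg$attention == "dense") {
    out <- rollout_core_cpp(start_window$glucose, start_window$insulin,
                            agent$params$enc, agent$hidden,
                            agent$params$actor,
                            agent$params$log_std[1, 1],
                            predictor$params,
                            predictor$cfg$attention_heads,
                            eps_act, eps_samp, imax, tau)
    rewards <- matrix(glucose_reward(as.vector(out$samp_g), reward, risk),
                      n, h)
    return(list(actions = out$actions, pred_g = out$pred_g,
                rewards = rewards, feat0 = matrix(out$feat0, 1),
                mu0 = out$mu0))
  }
  for (s in seq_len(h)) {
    a <- policy_sample_eps(agent, ga_array(G, I), eps_act[, s])
    if (truthful) {
      rates <- action_to_insulin(a, imax, tau)
      for (m in seq_len(if (!is.null(env)) env$step_min else 5)) {
        for (me in seq_along(tenv$meals)) {
          ev <- tenv$meals[[me]]
          if (!meal_done[me] && ev$time_of_day >= tclock &&
              ev$time_of_day < tclock + 1) {
            st[, 3] <- st[, 3] + ev$carbs
            meal_done[me] <- TRUE
          }
        }
        st <- rk4_vec(st, rates, tenv$params, 1)
        tclock <- tclock + 1
      }
      g_mean <- st[, 1]
      g_samp <- g_mean
    } else if (learned) {
      fwp <- predictor_forward(predictor, G, I, a,
                               sparse = predictor$cfg$attention ==
                                 "prob_sparse")
      g_mean <- G[, k] + fwp$delta * 50
      sdv <- sqrt(exp(fwp$logvar)) * 50
      g_samp <- pmax(1, g_mean + sdv * eps_samp[, s])
    } else {
      windows <- lapply(seq_len(n), function(i)
        list(glucose = G[i, ], insulin = I[i, ]))
      pred <- predict_next(predictor, windows, a)
      g_mean <- pred$mean
      g_samp <- pmax(1, pred$mean + sqrt(pred$variance) * eps_samp[, s])
    }
    actions[, s] <- a
    pred_g[, s] <- g_mean
    rewards[, s] <- glucose_reward(pmax(1, g_samp), reward, risk)
    G <- cbind(G[, -1, drop = FALSE], g_samp)
    I <- cbind(I[, -1, drop = FALSE], action_to_insulin(a, imax, tau))
  }
  list(actions = actions, pred_g = pred_g, rewards = rewards,
       feat0 = NULL, mu0 = NULL)
}

#' Single-trajectory rollout
#'
#' Convenience wrapper over [mpc_rollouts()] with one candidate.
#' @inheritParams mpc_rollouts
#' @return A marked `trajectory`.
#' @export
rollout <- function(agent, predictor, start_window, cfg = planner_config(),
                    gate = NULL, rng = NULL, env = NULL) {
  cfg$n_rollouts <- 1
  mpc_rollouts(agent, predictor, start_window, cfg, gate, rng, env)[[1]]
}

#' Select the best safe first-step action
#'
#' Argmax of cumulative reward over the safe trajectories; deterministic
#' tie-break by lowest trajectory index. When no trajectory is safe the
#' fallback flag is set and the caller must invoke the safety controller.
#'
#' @param trajectories A nonempty list of marked `trajectory` objects.
#' @return A list: `action` (first-step action or `NA`), `fallback`
#'   (logical), `index` (chosen trajectory), `cumulative_reward`.
#' @export
select_action <- function(trajectories) {
  if (length(trajectories) == 0) stop("no trajectories to select from")
  safe <- vapply(trajectories, `[[`, logical(1), "safe")
  if (!any(safe)) {
    return(list(action = NA_real_, fallback = TRUE, index = NA_integer_,
                cumulative_reward = NA_real_))
  }
  cum <- vapply(trajectories, `[[`, numeric(1), "cumulative_reward")
  cum[!safe] <- -Inf
  idx <- which.max(cum)  # which.max takes the first maximum: stable
  list(action = trajectories[[idx]]$actions[1], fallback = FALSE,
       index = idx, cumulative_reward = cum[idx])
}

#' Nocturnal adjustment coefficient
#'
#' 0.8 between 20:00 and 23:00, 0.6 between 0:00 and 3:00, otherwise 1.
#'
#' @param clock Minutes since midnight.
#' @return The time-of-day coefficient.
#' @export
nocturnal_coef <- function(clock) {
  clock <- clock %% 1440
  if (clock >= 1200 && clock < 1380) 0.8
  else if (clock >= 0 && clock < 180) 0.6
  else 1.0
}

#' Safety-controller insulin adjustment coefficient
#'
#' `cf = coef * (obs0 / 112.517) * (obs0 / obs1)^2`, combining the
#' deviation of the current glucose from the zero-risk value with the
#' squared short-term trend, scaled by the nocturnal coefficient. Below
#' 54 mg/dL the coefficient is forced to 0 (full insulin suspension).
#'
#' @param obs0 Current CGM glucose (mg/dL), positive.
#' @param obs1 Previous CGM glucose (mg/dL), positive.
#' @param clock Minutes since midnight (sets the nocturnal coefficient
#'   unless `coef` is given).
#' @param coef Optional explicit time-of-day coefficient in
#'   `{1, 0.8, 0.6}`.
#' @param p A [risk_params()] (supplies the zero-risk glucose anchor).
#' @return The coefficient `cf >= 0`.
#' @export
#' @examples
#' safety_coefficient(112.517, 112.517, coef = 1)   # 1
#' safety_coefficient(50, 60)                       # 0: suspension
safety_coefficient <- function(obs0, obs1, clock = 720, coef = NULL,
                               p = risk_params()) {
  if (!is.finite(obs0) || !is.finite(obs1) || obs0 <= 0 || obs1 <= 0) {
    stop("glucose observations must be positive")
  }
  if (is.null(coef)) coef <- nocturnal_coef(clock)
  stopifnot(coef %in% c(1, 0.8, 0.6))
  if (obs0 < 54) return(0)
  coef * (obs0 / zero_risk_glucose(p)) * (obs0 / obs1)^2
}

#' Apply the safety coefficient to an insulin rate
#'
#' @param rl_insulin_rate Rate proposed by the policy (U/min, >= 0).
#' @param cf Safety coefficient (>= 0).
#' @param pump_max_rate Pump ceiling (U/min).
#' @return The corrected rate, clamped to \[0, pump_max_rate\].
#' @export
apply_safety <- function(rl_insulin_rate, cf, pump_max_rate = 5) {
  stopifnot(rl_insulin_rate >= 0, cf >= 0)
  min(max(0, cf * rl_insulin_rate), pump_max_rate)
}

# invert the action transform: rate -> action in [-1, 1]
insulin_to_action <- function(rate, imax = 5, tau = 4) {
  rate <- min(max(rate, imax * exp(-2 * tau)), imax)
  1 + log(rate / imax) / tau
}

#' One hybrid control step
#'
#' Orchestrates the three-layer mechanism: while the predictor gate is
#' inactive the policy acts alone (tag `"rl"`); once active, candidate
#' trajectories are rolled out and screened, the best safe first-step
#' action is executed (tag `"mpc"`); if every trajectory is unsafe the
#' analytic safety controller corrects the policy's insulin rate (tag
#' `"safety"`). Planner- and safety-selected actions are queued as
#' imitation targets.
#'
#' @param env A [patient_env()].
#' @param agent The policy (`rl_agent`).
#' @param predictor A trained predictor.
#' @param gate An [rmse_gate()].
#' @param cfg A [planner_config()].
#' @param rng A [local_rng()] stream.
#' @param imitation_queue Optional environment queue (fields `windows`,
#'   `a_star`) receiving (state, optimal action) pairs.
#' @param imitate_safety Also queue safety-controller actions
#'   (default TRUE).
#' @return List: `result` (the `step_result`), `tag` (`"rl"`, `"mpc"` or
#'   `"safety"`), `action`, `n_safe`, `cf`.
#' @export
hybrid_step <- function(env, agent, predictor, gate, cfg = planner_config(),
                        rng = NULL, imitation_queue = NULL,
                        imitate_safety = TRUE) {
  w <- env$window
  if (is.null(gate) || !gate$active) {
    act <- agent_act(agent, w, rng = rng)
    return(list(result = env_step(env, act$action), tag = "rl",
                action = act$action, n_safe = NA_integer_, cf = NA_real_,
                u = act$u, log_prob = act$log_prob, value = act$value))
  }
  rm <- rollout_matrices(agent, predictor, w, cfg, gate, rng, env,
                         reward = env$reward_spec, risk = env$risk)
  # safety marking and best-safe selection on the rollout matrices
  # (identical semantics to mark_safety + select_action, without the
  # per-trajectory bookkeeping objects)
  g_min <- do.call(pmin, lapply(seq_len(cfg$horizon),
                                function(j) rm$pred_g[, j]))
  safe <- g_min >= cfg$hypo_unsafe_threshold
  if (!is.null(cfg$hyper_unsafe_threshold)) {
    g_max <- do.call(pmax, lapply(seq_len(cfg$horizon),
                                  function(j) rm$pred_g[, j]))
    safe <- safe & g_max <= cfg$hyper_unsafe_threshold
  }
  n_safe <- sum(safe)
  if (n_safe > 0) {
    cum <- rowSums(rm$rewards)
    cum[!safe] <- -Inf
    a <- rm$actions[which.max(cum), 1]
    tag <- "mpc"; cf <- NA_real_
    res <- env_step(env, a)
  } else {
    k <- length(w$glucose)
    cf <- safety_coefficient(w$glucose[k], w$glucose[k - 1], env$clock)
    act <- agent_act(agent, w, rng = rng)
    rate <- action_to_insulin(act$action, env$params$pump_max_rate,
                              env$action_tau)
    rate <- apply_safety(rate, cf, env$params$pump_max_rate)
    a <- insulin_to_action(rate, env$params$pump_max_rate, env$action_tau)
    tag <- "safety"
    res <- env_step_insulin(env, rate)
  }
  if (!is.null(imitation_queue) && (tag == "mpc" || imitate_safety)) {
    queue_add(imitation_queue, w, a)
  }
  # log-prob/value of the executed action under the current policy, so
  # the on-policy learner can treat the hybrid layer as its behaviour;
  # the compiled rollout already encoded the start state
  if (!is.null(rm$feat0)) {
    feat <- rm$feat0
    mu <- rm$mu0
    log_std <- agent$params$log_std[1, 1]
  } else {
    feat <- encode(enc_obj(agent), w)
    d <- policy_dist(agent, feat)
    mu <- d$mu
    log_std <- d$log_std
  }
  u_exec <- atanh(pmin(1 - 1e-7, pmax(-1 + 1e-7, a)))
  lp <- if (agent$algo == "ppo") {
    squashed_logprob(u_exec, mu, exp(log_std))
  } else NA_real_
  value <- if (agent$algo == "ppo") {
    mlp_forward(feat, agent$params$critic)$out[, 1]
  } else NA_real_
  list(result = res, tag = tag, action = a, n_safe = n_safe, cf = cf,
       u = u_exec, log_prob = lp, value = value)
}

# bounded FIFO queue of imitation pairs
queue_init <- function(capacity = 512) {
  e <- new.env(parent = emptyenv())
  e$windows <- vector("list", 0); e$a_star <- numeric(0)
  e$capacity <- capacity
  e
}

queue_add <- function(q, window, a_star) {
  q$windows[[length(q$windows) + 1]] <- window
  q$a_star <- c(q$a_star, a_star)
  if (length(q$a_star) > q$capacity) {
    drop <- seq_len(length(q$a_star) - q$capacity)
    q$windows <- q$windows[-drop]
    q$a_star <- q$a_star[-drop]
  }
  invisible(q)
}

#' Truthful predictor mock backed by the real simulator
#'
#' A drop-in replacement for the learned predictor that integrates the
#' true (noise-free) patient dynamics from the live environment state.
#' Used to isolate planner behaviour from predictor error in tests and
#' safety-dominance experiments.
#'
#' @param env The [patient_env()] whose state is branched.
#' @return An object with a [predict_next()] method.
#' @export
truthful_predictor <- function(env) {
  structure(list(env = env, trained = TRUE), class = "truthful_predictor")
}

#' @export
predict_next.truthful_predictor <- function(pred, windows, action) {
  env <- pred$env
  if (!is.null(windows$glucose)) windows <- list(windows)
  n <- length(windows)
  action <- rep_len(action, n)
  means <- numeric(n)
  snap <- env_snapshot(env)
  for (i in seq_len(n)) {
    # branch the true dynamics; disregards the window (the ODE state is
    # the live one), which is exact for depth-1 branching from now
    env_restore(env, snap)
    env$terminated <- FALSE
    st <- env$state
    rate <- action_to_insulin(action[i], env$params$pump_max_rate,
                              env$action_tau)
    clock <- env$clock
    for (m in seq_len(env$step_min)) {
      # include scheduled meals so the mock is truly truthful
      for (me in seq_along(env$meals)) {
        ev <- env$meals[[me]]
        if (!env$meal_idx_done[me] && ev$time_of_day >= clock &&
            ev$time_of_day < clock + 1) {
          st[3] <- st[3] + ev$carbs
        }
      }
      st <- ode_step(st, rate, env$params, dt = 1)
      clock <- clock + 1
    }
    means[i] <- st[1]
  }
  env_restore(env, snap)
  structure(list(mean = means, variance = rep(1e-6, n), trained = TRUE),
            class = "gaussian_prediction")
}
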