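# MPC rollout planner, trajectory safety screening, the analytic safety
# controller and the hybrid orchestration layer.

toy_traj <- function(pred_g, rewards = rep(0.5, length(pred_g)),
                     actions = rep(0, length(pred_g))) {
  glucontrol:::new_trajectory(actions, pred_g, rewards)
}

test_that("safety marking uses a strict 54 mg/dL threshold", {
  cfg <- planner_config()
  expect_true(mark_safety(toy_traj(rep(100, 6)), cfg)$safe)
  expect_false(mark_safety(toy_traj(c(100, 53, 100, 100, 100, 100)),
                           cfg)$safe)
  expect_true(mark_safety(toy_traj(c(100, 54, 100, 100, 100, 100)),
                          cfg)$safe)
  # marking is monotone: adding a violating step can only remove safety
  tr <- toy_traj(c(rep(100, 5), 40))
  expect_false(mark_safety(tr, cfg)$safe)
  # the wide preset also screens hyperglycemia
  wide <- planner_config_wide()
  expect_false(mark_safety(toy_traj(rep(260, 6)), wide)$safe)
  expect_false(mark_safety(toy_traj(rep(65, 6)), wide)$safe)
  expect_true(mark_safety(toy_traj(rep(150, 6)), wide)$safe)
})

test_that("select_action takes the best safe trajectory with stable ties", {
  trs <- lapply(c(1, 5, 3, 5, 2), function(r)
    mark_safety(toy_traj(rep(100, 6), rewards = rep(r / 6, 6),
                         actions = rep(r / 10, 6)), planner_config()))
  sel <- select_action(trs)
  expect_false(sel$fallback)
  expect_equal(sel$index, 2)  # first of the tied maxima
  expect_equal(sel$action, 0.5)
  # brute-force argmax oracle over the safe set
  cums <- vapply(trs, `[[`, numeric(1), "cumulative_reward")
  expect_equal(sel$cumulative_reward, max(cums))
  # a single safe trajectory wins regardless of reward
  trs2 <- lapply(1:30, function(i) {
    g <- if (i == 17) rep(100, 6) else rep(50, 6)
    mark_safety(toy_traj(g, rewards = rep(ifelse(i == 17, 0.01, 0.9), 6),
                         actions = rep(i / 100, 6)), planner_config())
  })
  sel2 <- select_action(trs2)
  expect_equal(sel2$index, 17)
  expect_equal(sel2$action, 0.17)
  # all unsafe: fallback flag
  trs3 <- lapply(1:5, function(i)
    mark_safety(toy_traj(rep(40, 6)), planner_config()))
  expect_true(select_action(trs3)$fallback)
  expect_error(select_action(list()), "no trajectories")
})

test_that("safety coefficient combines deviation, trend, and time of day", {
  # both ratios are 1 at the zero-risk anchor
  expect_equal(safety_coefficient(112.517, 112.517, coef = 1), 1,
               tolerance = 1e-4)
  # severe hypoglycemia: full suspension
  expect_equal(safety_coefficient(50, 60), 0)
  expect_equal(safety_coefficient(53.99, 200, coef = 1), 0)
  # worked arithmetic: 150 rising from 140
  expect_equal(safety_coefficient(150, 140, coef = 1), 1.5304,
               tolerance = 1e-3)
  # above anchor and rising -> amplify; below and falling -> attenuate
  expect_gt(safety_coefficient(150, 140, coef = 1), 1)
  expect_lt(safety_coefficient(90, 100, coef = 1), 1)
  expect_error(safety_coefficient(-1, 100), "positive")
})

test_that("nocturnal coefficient windows are applied from the clock", {
  expect_equal(nocturnal_coef(21 * 60), 0.8)
  expect_equal(nocturnal_coef(20 * 60), 0.8)
  expect_equal(nocturnal_coef(23 * 60), 1.0)
  expect_equal(nocturnal_coef(2 * 60), 0.6)
  expect_equal(nocturnal_coef(0), 0.6)
  expect_equal(nocturnal_coef(3 * 60), 1.0)
  expect_equal(nocturnal_coef(12 * 60), 1.0)
  expect_equal(safety_coefficient(150, 140, clock = 21 * 60),
               0.8 * safety_coefficient(150, 140, coef = 1),
               tolerance = 1e-12)
})

test_that("safety correction scales the insulin rate and clamps to the pump", {
  expect_equal(apply_safety(2, 0), 0)
  expect_equal(apply_safety(2, 1), 2)
  expect_equal(apply_safety(4, 2, pump_max_rate = 5), 5)
  expect_equal(glucontrol:::insulin_to_action(
    action_to_insulin(0.37), 5, 4), 0.37, tolerance = 1e-12)
})

test_that("imitation loss is the squashed-Gaussian NLL and fine-tuning raises density", {
  ag <- agent_init("ppo", learner_config(), seed = 3)
  w <- flat_window(150, 0.1)
  a_star <- -0.4
  feat <- encode(glucontrol:::enc_obj(ag), w)
  d <- glucontrol:::policy_dist(ag, feat)
  u_star <- atanh(a_star)
  ref <- -(stats::dnorm(u_star, d$mu, exp(d$log_std), log = TRUE) -
             log(1 - a_star^2))
  expect_equal(imitation_loss(ag, w, a_star), ref, tolerance = 1e-6)
  expect_error(imitation_loss(ag, w, 1.4), "a_star")
  # gradient steps increase the density of the target action
  dens <- function(agent) {
    f <- encode(glucontrol:::enc_obj(agent), w)
    dd <- glucontrol:::policy_dist(agent, f)
    stats::dnorm(u_star, dd$mu, exp(dd$log_std)) / (1 - a_star^2)
  }
  before <- dens(ag)
  ag2 <- imitation_finetune(ag, list(w), a_star, lr = 5e-3, steps = 50)
  expect_gt(dens(ag2), before)
})

test_that("rollouts honour the gate, horizon, and reward bookkeeping", {
  ag <- frozen_ppo(seed = 2)
  pr <- predictor_init(predictor_config(), seed = 3)
  pr$trained <- TRUE
  gate <- rmse_gate()
  w <- flat_window(140, 0.02)
  expect_error(mpc_rollouts(ag, pr, w, planner_config(), gate,
                            local_rng(1)), "gate inactive")
  gate_update(gate, 5)
  tr1 <- rollout(ag, pr, w, planner_config(horizon = 1), gate,
                 local_rng(1))
  expect_length(tr1$actions, 1)
  expect_length(tr1$predicted_glucose, 1)
  expect_length(tr1$rewards, 1)
  trs <- mpc_rollouts(ag, pr, w, planner_config(), gate, local_rng(2))
  expect_length(trs, 30)
  for (tr in trs[1:3]) {
    expect_equal(tr$cumulative_reward, sum(tr$rewards))
    expect_length(tr$predicted_glucose, 6)
  }
})

test_that("a deterministic policy and identity predictor collapse all rollouts", {
  ag <- frozen_ppo(seed = 5)
  mock <- make_mock_predictor(function(w, a) w$glucose[length(w$glucose)])
  gate <- rmse_gate(); gate_update(gate, 1)
  w <- flat_window(120, 0.02)
  trs <- mpc_rollouts(ag, mock, w, planner_config(), gate, local_rng(4))
  acts <- t(vapply(trs, `[[`, numeric(6), "actions"))
  gs <- t(vapply(trs, `[[`, numeric(6), "predicted_glucose"))
  expect_lt(max(apply(acts, 2, stats::sd)), 1e-6)
  expect_lt(max(apply(gs, 2, stats::sd)), 1e-3)
  expect_equal(unname(gs[1, ]), rep(120, 6), tolerance = 1e-2)
})

test_that("compiled rollouts equal the reference path draw for draw", {
  ag <- agent_init("ppo", learner_config(), seed = 6)
  pr <- predictor_init(predictor_config(), seed = 7)
  pr$trained <- TRUE
  gate <- rmse_gate(); gate_update(gate, 5)
  env <- quiet_env(); env_reset(env, 1)
  w <- env$window
  t_cpp <- mpc_rollouts(ag, pr, w, planner_config(), gate, local_rng(77),
                        env)
  pr_r <- pr
  pr_r$cfg$attention <- "prob_sparse"  # full budget: same maths, R path
  pr_r$cfg$sparse_factor <- 100
  t_r <- mpc_rollouts(ag, pr_r, w, planner_config(), gate, local_rng(77),
                      env)
  for (i in c(1, 15, 30)) {
    expect_equal(t_cpp[[i]]$actions, t_r[[i]]$actions, tolerance = 1e-10)
    expect_equal(t_cpp[[i]]$predicted_glucose, t_r[[i]]$predicted_glucose,
                 tolerance = 1e-8)
    expect_equal(t_cpp[[i]]$safe, t_r[[i]]$safe)
  }
})

test_that("hybrid stepping tags provenance and falls back to the safety controller", {
  # inactive gate: pure policy behaviour
  env <- quiet_env(); env_reset(env, 3)
  ag <- frozen_ppo(seed = 8)
  pr <- predictor_init(predictor_config(), seed = 9)
  gate <- rmse_gate()  # inactive
  hs <- hybrid_step(env, ag, pr, gate, planner_config(), local_rng(1))
  expect_equal(hs$tag, "rl")
  # a predictor that always forecasts severe hypoglycemia forces the
  # safety controller on every step
  mock_low <- make_mock_predictor(function(w, a) 45)
  gate2 <- rmse_gate(); gate_update(gate2, 1)
  env2 <- quiet_env(); env_reset(env2, 3)
  q <- glucontrol:::queue_init(100)
  tags <- character(0)
  for (i in 1:10) {
    hs <- hybrid_step(env2, ag, mock_low, gate2, planner_config(),
                      local_rng(i), imitation_queue = q)
    tags <- c(tags, hs$tag)
    if (hs$result$terminated) break
  }
  expect_true(all(tags == "safety"))
  expect_equal(length(q$a_star), length(tags))
  # provenance fractions over a mixed episode sum to one
  counts <- table(factor(tags, levels = c("rl", "mpc", "safety")))
  expect_equal(sum(counts / length(tags)), 1)
})

test_that("the truthful mock reproduces the simulator's next-step glucose", {
  env <- quiet_env()
  env_reset(env, 11)
  tp <- truthful_predictor(env)
  w <- env$window
  a <- -0.3
  pred <- predict_next(tp, w, a)
  snap <- glucontrol:::env_snapshot(env)
  res <- env_step(env, a)
  expect_equal(pred$mean, res$true_glucose, tolerance = 1e-9)
  glucontrol:::env_restore(env, snap)
})

test_that("truthful-predictor screening reduces severe hypoglycemia exposure", {
  # untrained policies overdose; screening must not increase sub-54 time
  ag <- agent_init("ppo", learner_config(), seed = 31)
  n_eps <- 3
  count_sub54 <- function(hybrid) {
    total <- 0
    for (e in seq_len(n_eps)) {
      env <- quiet_env()
      env_reset(env, 100 + e)
      rng <- local_rng(200 + e)
      while (!env$terminated) {
        if (hybrid) {
          gate <- rmse_gate(); gate_update(gate, 1)
          hs <- hybrid_step(env, ag, truthful_predictor(env), gate,
                            planner_config(), rng)
          res <- hs$result
        } else {
          act <- agent_act(ag, env$window, rng = rng)
          res <- env_step(env, act$action)
        }
        total <- total + (res$true_glucose < 54)
      }
    }
    total
  }
  expect_lte(count_sub54(TRUE), count_sub54(FALSE))
})
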