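# Shared encoder, GAE, the learning-rate schedule and the three
# actor-critic updates.

test_that("learning-rate schedule: warm-up anchors, floor, and monotone decay", {
  cfg <- learner_config()
  expect_equal(lr_at(20000, cfg), 3e-4)
  expect_equal(lr_at(10000, cfg), 1.5e-4)
  expect_equal(lr_at(0, cfg), 0)
  expect_equal(lr_at(cfg$total_steps, cfg), 0.01 * 3e-4)
  steps <- seq(20000, cfg$total_steps, by = 4000)
  lrs <- vapply(steps, lr_at, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) <= 1e-12))
  expect_true(all(lrs >= 0.01 * 3e-4 - 1e-15))
})

test_that("GAE matches the brute-force nested discounted sums", {
  # single step, zero values: advantage is the reward itself
  g <- gae_advantages(2.5, 0, 0.9, 0.95, dones = TRUE)
  expect_equal(g$advantages, 2.5)
  expect_equal(g$returns, 2.5)
  # 3-step toy against an explicit oracle
  r <- c(1, 0, 1); v <- c(0.5, 0.5, 0.5); gam <- 0.9; lam <- 0.95
  v_next <- c(v[-1], 0)
  delta <- r + gam * v_next - v
  oracle <- c(
    delta[1] + (gam * lam) * delta[2] + (gam * lam)^2 * delta[3],
    delta[2] + (gam * lam) * delta[3],
    delta[3])
  g2 <- gae_advantages(r, v, gam, lam, dones = c(FALSE, FALSE, TRUE))
  expect_equal(g2$advantages, oracle, tolerance = 1e-12)
  expect_equal(g2$returns, oracle + v)
  # lambda = 0 reduces to one-step TD errors
  g3 <- gae_advantages(r, v, gam, 0, dones = c(FALSE, FALSE, TRUE))
  expect_equal(g3$advantages, delta)
  expect_error(gae_advantages(c(1, NaN), c(0, 0), 0.9, 0.95), "non-finite")
})

test_that("encoder features are deterministic and time-order sensitive", {
  ag <- agent_init("ppo", learner_config(), seed = 3)
  w <- flat_window(130, 0.05)
  enc <- glucontrol:::enc_obj(ag)
  f1 <- encode(enc, w)
  f2 <- encode(enc, w)
  expect_identical(f1, f2)
  w2 <- list(glucose = seq(80, 190, length.out = 12),
             insulin = rep(0.02, 12))
  w2rev <- list(glucose = rev(w2$glucose), insulin = w2$insulin)
  expect_gt(max(abs(encode(enc, w2) - encode(enc, w2rev))), 1e-6)
  expect_error(encode(enc, list(glucose = 1:12, insulin = 1:5)),
               "malformed")
})

test_that("both actor and critic losses propagate gradients into the encoder", {
  cfg <- learner_config(entropy_coef = 0)
  ag <- agent_init("ppo", cfg, seed = 5)
  rng <- local_rng(2)
  n <- 16
  X <- array(rng$rnorm(n * 12 * 2, 0, 0.5), c(n, 12, 2))
  u <- rng$rnorm(n, 0, 0.3)
  lp <- glucontrol:::squashed_logprob(
    u, 0, exp(ag$params$log_std[1, 1]))
  # critic-only gradient: zero advantages, non-trivial returns
  b1 <- list(X = X, u = u, log_prob = lp,
             advantages = rep(0, n), returns = rng$rnorm(n, 5, 1))
  up1 <- ppo_update(ag, b1, lr = 1e-3)
  d1 <- max(abs(up1$agent$params$enc[[1]]$Wx - ag$params$enc[[1]]$Wx))
  expect_gt(d1, 0)
  # actor-only gradient: zero out the value loss via value_coef
  cfg2 <- learner_config(value_coef = 0, entropy_coef = 0)
  ag2 <- agent_init("ppo", cfg2, seed = 5)
  b2 <- list(X = X, u = u, log_prob = lp,
             advantages = rng$rnorm(n), returns = rep(0, n))
  up2 <- ppo_update(ag2, b2, lr = 1e-3)
  d2 <- max(abs(up2$agent$params$enc[[1]]$Wx - ag2$params$enc[[1]]$Wx))
  expect_gt(d2, 0)
})

test_that("PPO clip boundary: constant advantages give the clipped surrogate", {
  cfg <- learner_config(entropy_coef = 0)
  ag <- agent_init("ppo", cfg, seed = 7)
  n <- 8
  X <- array(0, c(n, 12, 2))
  u <- rep(0.1, n)
  feat <- glucontrol:::lstm_forward(glucontrol:::enc_obj(ag), X,
                                    need_cache = FALSE)$features
  d <- glucontrol:::policy_dist(ag, feat)
  lp_now <- glucontrol:::squashed_logprob(u, d$mu, exp(d$log_std))
  eps <- cfg$clip_eps
  # behaviour log-prob chosen so the ratio is exactly 1 + 2 eps
  b <- list(X = X, u = u, log_prob = lp_now - log(1 + 2 * eps),
            advantages = rep(2, n), returns = rep(0, n))
  up <- ppo_update(ag, b, lr = 0)
  expect_equal(up$diagnostics$clip_frac, 1)
  # per-sample surrogate = (1 + eps) * A (constant adv skips normalisation)
  expect_equal(up$diagnostics$policy_loss, -(1 + eps) * 2,
               tolerance = 1e-10)
})

test_that("PPO critic loss decreases over updates on a fixed batch", {
  cfg <- learner_config(entropy_coef = 0)
  ag <- agent_init("ppo", cfg, seed = 11)
  rng <- local_rng(4)
  n <- 32
  X <- array(rng$rnorm(n * 12 * 2, 0, 0.5), c(n, 12, 2))
  u <- rng$rnorm(n, 0, 0.3)
  lp <- glucontrol:::squashed_logprob(u, 0, exp(ag$params$log_std[1, 1]))
  b <- list(X = X, u = u, log_prob = lp, advantages = rep(0, n),
            returns = rng$rnorm(n, 3, 1))
  l0 <- ppo_update(ag, b, lr = 1e-2)
  ag2 <- l0$agent
  for (i in 1:10) ag2 <- ppo_update(ag2, b, lr = 1e-2)$agent
  lN <- ppo_update(ag2, b, lr = 0)
  expect_lt(lN$diagnostics$value_loss, l0$diagnostics$value_loss)
})

test_that("DDPG and SAC losses decrease on a fixed replay batch", {
  rng <- local_rng(6)
  n <- 32
  mk_batch <- function() list(
    X = array(rng$rnorm(n * 12 * 2, 0, 0.5), c(n, 12, 2)),
    A = rng$runif(n, -1, 1), R = rng$runif(n, 0, 1),
    X2 = array(rng$rnorm(n * 12 * 2, 0, 0.5), c(n, 12, 2)),
    D = rep(1, n))  # terminal: targets reduce to the rewards
  b <- mk_batch()
  ag <- agent_init("ddpg", learner_config(), seed = 2)
  l0 <- ddpg_update(ag, b, 1e-3)
  agk <- l0$agent
  for (i in 1:15) agk <- ddpg_update(agk, b, 1e-3)$agent
  lN <- ddpg_update(agk, b, 1e-3)
  expect_lt(lN$diagnostics$critic_loss, l0$diagnostics$critic_loss)
  ags <- agent_init("sac", learner_config(), seed = 2)
  s0 <- sac_update(ags, b, 1e-3, rng)
  agk <- s0$agent
  for (i in 1:15) agk <- sac_update(agk, b, 1e-3, rng)$agent
  sN <- sac_update(agk, b, 1e-3, rng)
  expect_lt(sN$diagnostics$critic_loss, s0$diagnostics$critic_loss)
  expect_error(ddpg_update(ag, list(R = numeric(0)), 1e-3), "empty")
})

test_that("target networks follow the soft-update contract", {
  ag <- agent_init("ddpg", learner_config(soft_update = 1), seed = 3)
  rng <- local_rng(8)
  n <- 8
  b <- list(X = array(rng$rnorm(n * 24), c(n, 12, 2)),
            A = rng$runif(n, -1, 1), R = rng$runif(n),
            X2 = array(rng$rnorm(n * 24), c(n, 12, 2)), D = rep(1, n))
  up <- ddpg_update(ag, b, 1e-3)
  # rate 1: target equals the online parameters after the update
  expect_equal(up$agent$target$actor$l1$W, up$agent$params$actor$l1$W)
  # fractional rate: target is a convex combination old/new
  ag2 <- agent_init("ddpg", learner_config(soft_update = 0.3), seed = 3)
  old_t <- ag2$target$actor$l1$W
  up2 <- ddpg_update(ag2, b, 1e-3)
  expected <- 0.7 * old_t + 0.3 * up2$agent$params$actor$l1$W
  expect_equal(up2$agent$target$actor$l1$W, expected, tolerance = 1e-12)
})

test_that("SAC rejects a negative entropy temperature", {
  ag <- agent_init("sac", learner_config(), seed = 1)
  ag$cfg$temperature <- -0.1
  b <- list(X = array(0, c(2, 12, 2)), A = c(0, 0), R = c(0, 0),
            X2 = array(0, c(2, 12, 2)), D = c(1, 1))
  expect_error(sac_update(ag, b, 1e-3), "temperature")
})

test_that("each learner concentrates on the rewarded side of a two-armed bandit", {
  w <- flat_window()
  x <- glucontrol:::windows_to_array(w)[1, , ]
  # PPO: on-policy batches
  cfg <- learner_config(rollout_steps = 64, ppo_epochs = 5,
                        entropy_coef = 0)
  ag <- agent_init("ppo", cfg, seed = 11)
  rng <- local_rng(99)
  for (it in 1:31) {  # ~2000 environment steps
    n <- 64
    X <- array(rep(x, each = n), c(n, 12, 2))
    act <- agent_act(ag, rep(list(w), n), rng = rng)
    r <- as.numeric(act$action > 0)
    g <- gae_advantages(r, act$value, 0, 0.95, dones = rep(TRUE, n))
    b <- list(X = X, u = act$u, log_prob = act$log_prob,
              advantages = g$advantages, returns = g$returns)
    for (e in 1:cfg$ppo_epochs) ag <- ppo_update(ag, b, 3e-3)$agent
  }
  feat <- encode(glucontrol:::enc_obj(ag), w)
  d <- glucontrol:::policy_dist(ag, feat)
  p_pos <- 1 - stats::pnorm(0, d$mu, exp(d$log_std))
  expect_gte(p_pos, 0.9)
  # DDPG and SAC: replay-driven
  for (algo in c("ddpg", "sac")) {
    cfg2 <- learner_config(explore_noise = 0.3, temperature = 0.05,
                           soft_update = 0.02)
    agx <- agent_init(algo, cfg2, seed = 7)
    rngx <- local_rng(42)
    buf <- glucontrol:::replay_init(3000)
    for (s in 1:2000) {
      act <- agent_act(agx, w, rng = rngx)
      glucontrol:::replay_add(buf, x, act$action,
                              as.numeric(act$action > 0), x, TRUE)
      if (s >= 100 && s %% 4 == 0) {
        bb <- glucontrol:::replay_sample(buf, 64, rngx)
        agx <- if (algo == "ddpg") ddpg_update(agx, bb, 1e-3)$agent
               else sac_update(agx, bb, 1e-3, rngx)$agent
      }
    }
    feat <- encode(glucontrol:::enc_obj(agx), w)
    d <- glucontrol:::policy_dist(agx, feat)
    mass <- if (algo == "ddpg") as.numeric(tanh(d$mu) > 0) else
      1 - stats::pnorm(0, d$mu, exp(d$log_std))
    expect_gte(mass, 0.9)
  }
})

test_that("short training runs are reproducible under a fixed seed", {
  f1 <- train_controller("ppo", n_train_steps = 300,
                         cfg = learner_config(rollout_steps = 128),
                         seed = 21)
  f2 <- train_controller("ppo", n_train_steps = 300,
                         cfg = learner_config(rollout_steps = 128),
                         seed = 21)
  expect_identical(f1$agent$params$actor$l1$W, f2$agent$params$actor$l1$W)
  expect_identical(f1$curve, f2$curve)
})
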