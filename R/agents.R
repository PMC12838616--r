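# Recurrent actor-critic learners over the shared LSTM encoder.
# Three learners share the encoder/feature contract: PPO (stochastic,
# on-policy, clipped surrogate; the primary algorithm), DDPG
# (deterministic, off-policy, target networks) and SAC (stochastic,
# off-policy, twin critics with entropy regularisation).

#' Learner configuration
#'
#' @param discount Discount factor gamma in (0, 1).
#' @param gae_lambda GAE lambda in \[0, 1\].
#' @param clip_eps PPO clipping parameter.
#' @param value_coef Critic-loss weight in the PPO objective.
#' @param entropy_coef Entropy-bonus weight in the PPO objective.
#' @param temperature SAC entropy temperature (lambda), non-negative.
#' @param soft_update Polyak rate for DDPG/SAC target networks.
#' @param actor_lr Target learning rate alpha.
#' @param total_steps Total environment steps of a full run.
#' @param warmup_steps Linear warm-up length (steps).
#' @param decay Geometric decay factor applied per training iteration on
#'   top of the cosine envelope.
#' @param lr_floor_frac Learning-rate floor as a fraction of `actor_lr`.
#' @param steps_per_iter Environment steps per training iteration (one
#'   10-day iteration = 2880 control steps).
#' @param batch_size Update batch size.
#' @param rollout_steps On-policy steps collected per PPO update.
#' @param ppo_epochs Optimisation epochs per PPO update.
#' @param replay_capacity Off-policy replay capacity (DDPG/SAC).
#' @param explore_noise DDPG exploration noise SD (action units).
#' @param grad_clip Global gradient-norm clip.
#' @param imitation_weight Weight of the imitation (guidance) loss added
#'   to the PPO objective by the hybrid layer.
#' @return An object of class `learner_config`.
#' @export
learner_config <- function(discount = 0.99, gae_lambda = 0.95,
                           clip_eps = 0.2, value_coef = 0.5,
                           entropy_coef = 0.001, temperature = 0.2,
                           soft_update = 0.005, actor_lr = 3e-4,
                           total_steps = 400000, warmup_steps = 20000,
                           decay = 0.998, lr_floor_frac = 0.01,
                           steps_per_iter = 2880, batch_size = 1024,
                           rollout_steps = 1024, ppo_epochs = 6,
                           replay_capacity = 100000, explore_noise = 0.1,
                           grad_clip = 5, imitation_weight = 0.5) {
  stopifnot(discount > 0, discount < 1, gae_lambda >= 0, gae_lambda <= 1,
            clip_eps > 0, actor_lr > 0, temperature >= 0)
  structure(as.list(environment()), class = "learner_config")
}

#' Learning rate at a training step
#'
#' Linear warm-up from (almost) zero to the target rate over
#' `warmup_steps`, then a cosine envelope multiplied by
#' `decay^iteration`, floored at `lr_floor_frac * actor_lr`. Monotone
#' nonincreasing after warm-up.
#'
#' @param step Training step in \[0, total_steps\].
#' @param cfg A [learner_config()].
#' @return The learning rate.
#' @export
#' @examples
#' lr_at(20000, learner_config())   # 3e-4 (end of warm-up)
#' lr_at(10000, learner_config())   # 1.5e-4
lr_at <- function(step, cfg = learner_config()) {
  stopifnot(step >= 0, step <= cfg$total_steps)
  alpha <- cfg$actor_lr
  if (step <= cfg$warmup_steps) {
    return(alpha * step / cfg$warmup_steps)
  }
  prog <- (step - cfg$warmup_steps) / (cfg$total_steps - cfg$warmup_steps)
  iter <- floor((step - cfg$warmup_steps) / cfg$steps_per_iter)
  lr <- alpha * 0.5 * (1 + cos(pi * prog)) * cfg$decay^iter
  max(lr, cfg$lr_floor_frac * alpha)
}

#' Generalized advantage estimation
#'
#' TD errors `delta_t = r_t + gamma V(s_t+1) (1 - done_t) - V(s_t)`
#' accumulated into exponentially weighted advantages; returns are
#' advantages plus values.
#'
#' @param rewards,values Aligned per-step vectors.
#' @param gamma Discount factor.
#' @param lambda GAE lambda; 0 reduces to one-step TD errors.
#' @param dones Logical terminal flags (bootstrap value 0 past a terminal).
#' @param last_value Bootstrap value of the state after the final step.
#' @return A list with `advantages` and `returns`.
#' @export
gae_advantages <- function(rewards, values, gamma, lambda,
                           dones = rep(FALSE, length(rewards)),
                           last_value = 0) {
  n <- length(rewards)
  stopifnot(length(values) == n, length(dones) == n)
  if (any(!is.finite(rewards)) || any(!is.finite(values))) {
    stop("non-finite inputs to GAE")
  }
  v_next <- c(values[-1], last_value)
  nd <- 1 - as.numeric(dones)
  delta <- rewards + gamma * v_next * nd - values
  adv <- numeric(n)
  acc <- 0
  for (t in seq(n, 1)) {
    acc <- delta[t] + gamma * lambda * nd[t] * acc
    adv[t] <- acc
  }
  list(advantages = adv, returns = adv + values)
}

# ---- agent construction ----------------------------------------------------

enc_obj <- function(agent) list(hidden = agent$hidden,
                                layers = agent$params$enc)

#' Initialise an actor-critic agent
#'
#' @param algo `"ppo"`, `"ddpg"` or `"sac"`.
#' @param cfg A [learner_config()].
#' @param hidden LSTM hidden units (default 16).
#' @param enc_layers LSTM layers (default 2).
#' @param head_hidden Hidden units of the actor/critic MLP heads.
#' @param seed Initialisation seed.
#' @return An object of class `rl_agent`.
#' @export
agent_init <- function(algo = c("ppo", "ddpg", "sac"),
                       cfg = learner_config(), hidden = 16,
                       enc_layers = 2, head_hidden = 32, seed = 1L) {
  algo <- match.arg(algo)
  rng <- local_rng(derive_seed(seed, paste0("agent_", algo)))
  enc <- encoder_init(2, hidden, enc_layers,
                      seed = derive_seed(seed, "enc"))
  params <- list(enc = enc$layers)
  if (algo == "ppo") {
    params$actor <- mlp_init(hidden, head_hidden, 1, rng)
    params$critic <- mlp_init(hidden, head_hidden, 1, rng)
    params$log_std <- matrix(log(0.5), 1, 1)
  } else if (algo == "ddpg") {
    params$actor <- mlp_init(hidden, head_hidden, 1, rng)
    params$critic <- mlp_init(hidden + 1, head_hidden, 1, rng)
  } else {
    params$actor <- mlp_init(hidden, head_hidden, 2, rng)
    params$q1 <- mlp_init(hidden + 1, head_hidden, 1, rng)
    params$q2 <- mlp_init(hidden + 1, head_hidden, 1, rng)
  }
  agent <- list(algo = algo, cfg = cfg, hidden = hidden, params = params,
                opt = adam_init(params))
  if (algo != "ppo") agent$target <- params
  structure(agent, class = "rl_agent")
}

# squashed-Gaussian log-density of pre-squash value u under (mu, sigma)
squashed_logprob <- function(u, mu, sigma) {
  z <- (u - mu) / sigma
  -0.5 * z^2 - log(sigma) - 0.5 * LOG2PI - log(1 - tanh(u)^2 + 1e-12)
}

# forward policy head; X: (n, T, 2) array. Returns mu (and sigma).
policy_dist <- function(agent, feat) {
  if (agent$algo == "sac") {
    out <- mlp_forward(feat, agent$params$actor)$out
    list(mu = out[, 1], log_std = pmin(2, pmax(-5, out[, 2])))
  } else {
    mu <- mlp_forward(feat, agent$params$actor)$out[, 1]
    if (agent$algo == "ppo") {
      list(mu = mu, log_std = rep(agent$params$log_std[1, 1], length(mu)))
    } else {
      list(mu = mu)  # deterministic
    }
  }
}

#' Select an action for one or more observation windows
#'
#' Stochastic policies sample a squashed-Gaussian action; `deterministic`
#' uses the squashed mean. DDPG adds exploration noise unless
#' deterministic.
#'
#' @param agent An [agent_init()] object.
#' @param windows One window or a list of windows.
#' @param deterministic Use the policy mode instead of sampling.
#' @param rng Optional [local_rng()] stream.
#' @return List with `action` (in \[-1, 1\]), `u` (pre-squash),
#'   `log_prob`, `value` (PPO state value, else NA).
#' @export
agent_act <- function(agent, windows, deterministic = FALSE, rng = NULL) {
  act_core(agent, windows_to_array(windows), deterministic, rng)
}

# sample actions from pre-drawn standard-normal noise (one per row of X);
# used by the rollout planner so R and compiled paths share draws
policy_sample_eps <- function(agent, X, eps) {
  feat <- lstm_forward(enc_obj(agent), X, need_cache = FALSE)$features
  d <- policy_dist(agent, feat)
  if (agent$algo == "ddpg") {
    return(pmin(1, pmax(-1, tanh(d$mu) + agent$cfg$explore_noise * eps)))
  }
  tanh(d$mu + exp(d$log_std) * eps)
}

# fast path on a pre-built (n, T, 2) input array
act_core <- function(agent, X, deterministic = FALSE, rng = NULL) {
  fw <- lstm_forward(enc_obj(agent), X, need_cache = FALSE)
  feat <- fw$features
  n <- nrow(feat)
  draw <- function(k) if (is.null(rng)) stats::rnorm(k) else rng$rnorm(k)
  d <- policy_dist(agent, feat)
  if (agent$algo == "ddpg") {
    a <- tanh(d$mu)
    if (!deterministic) {
      a <- pmin(1, pmax(-1, a + agent$cfg$explore_noise * draw(n)))
    }
    return(list(action = a, u = atanh(pmin(0.999999, pmax(-0.999999, a))),
                log_prob = rep(NA_real_, n), value = rep(NA_real_, n)))
  }
  sigma <- exp(d$log_std)
  u <- if (deterministic) d$mu else d$mu + sigma * draw(n)
  a <- tanh(u)
  lp <- squashed_logprob(u, d$mu, sigma)
  value <- if (agent$algo == "ppo") {
    mlp_forward(feat, agent$params$critic)$out[, 1]
  } else rep(NA_real_, n)
  list(action = a, u = u, log_prob = lp, value = value)
}

#' State value estimate (PPO critic)
#' @param agent A PPO [agent_init()] object.
#' @param windows One window or a list of windows.
#' @return Numeric vector of values.
#' @export
agent_value <- function(agent, windows) {
  feat <- encode(enc_obj(agent), windows)
  mlp_forward(feat, agent$params$critic)$out[, 1]
}

# ---- PPO -------------------------------------------------------------------

#' One PPO update on a collected batch
#'
#' Maximises the clipped surrogate, fits the critic to the GAE returns by
#' halved squared error, adds an entropy bonus, and optionally a weighted
#' imitation (guidance) term on planner-selected actions. Gradients from
#' the actor and critic losses both flow into the shared encoder.
#'
#' @param agent A PPO agent.
#' @param batch List: `X` (n,k,2 input array), `u` (pre-squash actions),
#'   `log_prob` (behaviour log-probs), `advantages`, `returns`.
#' @param lr Learning rate for this update.
#' @param imitation Optional list `X`, `a_star` of guidance pairs.
#' @return List: updated `agent` and `diagnostics` (`clip_frac`,
#'   `kl`, `value_loss`, `policy_loss`, `imitation_loss`).
#' @export
ppo_update <- function(agent, batch, lr, imitation = NULL) {
  stopifnot(agent$algo == "ppo")
  cfg <- agent$cfg
  n <- length(batch$u)
  adv <- batch$advantages
  if (stats::sd(adv) > 0) adv <- (adv - mean(adv)) / stats::sd(adv)
  enc <- enc_obj(agent)
  feat <- lstm_forward(enc, batch$X, need_cache = FALSE)$features
  afw <- mlp_forward(feat, agent$params$actor)
  mu <- afw$out[, 1]
  log_std <- agent$params$log_std[1, 1]
  sigma <- exp(log_std)
  if (!is.finite(sigma) || sigma <= 1e-6) stop("degenerate policy std")
  cfw <- mlp_forward(feat, agent$params$critic)
  v <- cfw$out[, 1]

  lp <- squashed_logprob(batch$u, mu, sigma)
  ratio <- exp(lp - batch$log_prob)
  clipped <- pmin(pmax(ratio, 1 - cfg$clip_eps), 1 + cfg$clip_eps)
  s_un <- ratio * adv
  s_cl <- clipped * adv
  active <- s_un <= s_cl  # unclipped branch carries the gradient
  policy_loss <- -mean(pmin(s_un, s_cl))
  dlp <- -(active * adv * ratio) / n

  z <- (batch$u - mu) / sigma
  dmu <- dlp * z / sigma
  dlogstd <- sum(dlp * (z^2 - 1)) - cfg$entropy_coef
  dv <- cfg$value_coef * (v - batch$returns) / n
  value_loss <- 0.5 * mean((batch$returns - v)^2)

  ab <- mlp_backward(afw, agent$params$actor, matrix(dmu, n, 1))
  cb <- mlp_backward(cfw, agent$params$critic, matrix(dv, n, 1))
  dfeat <- ab$dx + cb$dx
  eg <- lstm_train_grad(enc, batch$X, dfeat)
  grads <- list(enc = eg, actor = ab$grads, critic = cb$grads,
                log_std = matrix(dlogstd, 1, 1))

  imi_loss <- NA_real_
  if (!is.null(imitation) && length(imitation$a_star) > 0) {
    ig <- imitation_grads(agent, imitation$X, imitation$a_star)
    w <- cfg$imitation_weight
    grads$enc <- tree_add(grads$enc, tree_map(ig$grads$enc,
                                              function(x) w * x))
    grads$actor <- tree_add(grads$actor, tree_map(ig$grads$actor,
                                                  function(x) w * x))
    grads$log_std <- grads$log_std + w * ig$grads$log_std
    imi_loss <- ig$loss
  }
  grads <- tree_clip(grads, agent$cfg$grad_clip)
  st <- adam_step(agent$params, grads, agent$opt, lr)
  agent$params <- st$params; agent$opt <- st$opt
  diagnostics <- list(
    clip_frac = mean(ratio < 1 - cfg$clip_eps | ratio > 1 + cfg$clip_eps),
    kl = mean(batch$log_prob - lp),
    value_loss = value_loss, policy_loss = policy_loss,
    imitation_loss = imi_loss)
  list(agent = agent, diagnostics = diagnostics)
}

# gradients of the mean negative log-likelihood of target actions under
# the current squashed-Gaussian policy (PPO head)
imitation_grads <- function(agent, X, a_star) {
  a_star <- pmin(1 - 1e-7, pmax(-1 + 1e-7, a_star))
  u_star <- atanh(a_star)
  m <- length(u_star)
  enc <- enc_obj(agent)
  feat <- lstm_forward(enc, X, need_cache = FALSE)$features
  afw <- mlp_forward(feat, agent$params$actor)
  mu <- afw$out[, 1]
  sigma <- exp(agent$params$log_std[1, 1])
  lp <- squashed_logprob(u_star, mu, sigma)
  loss <- -mean(lp)
  z <- (u_star - mu) / sigma
  dmu <- -(z / sigma) / m           # d(-lp)/dmu
  dlogstd <- -sum(z^2 - 1) / m
  ab <- mlp_backward(afw, agent$params$actor, matrix(dmu, m, 1))
  eg <- lstm_train_grad(enc, X, ab$dx)
  list(loss = loss,
       grads = list(enc = eg, actor = ab$grads,
                    log_std = matrix(dlogstd, 1, 1)))
}

#' Imitation (guidance) loss of an optimal action under the policy
#'
#' The negative log-likelihood `-log pi(a* | s)` of performing the
#' planner's optimal action in state `s`, with the tanh-squashing
#' correction. Used to fine-tune the policy towards MPC/safety-selected
#' actions.
#'
#' @param agent A PPO agent.
#' @param windows One window or a list of windows.
#' @param a_star Optimal action(s) in \[-1, 1\].
#' @return Scalar mean loss.
#' @export
imitation_loss <- function(agent, windows, a_star) {
  stopifnot(all(a_star >= -1), all(a_star <= 1))
  X <- windows_to_array(windows)
  imitation_grads(agent, X, a_star)$loss
}

#' Take gradient steps of the imitation loss only
#'
#' @param agent A PPO agent.
#' @param windows A list of windows (states).
#' @param a_star Matching optimal actions.
#' @param lr Learning rate.
#' @param steps Number of gradient steps.
#' @return The updated agent.
#' @export
imitation_finetune <- function(agent, windows, a_star, lr = 1e-3,
                               steps = 1) {
  X <- windows_to_array(windows)
  for (s in seq_len(steps)) {
    ig <- imitation_grads(agent, X, a_star)
    grads <- tree_zeros_like(agent$params)
    grads$enc <- ig$grads$enc
    grads$actor <- ig$grads$actor
    grads$log_std <- ig$grads$log_std
    grads <- tree_clip(grads, agent$cfg$grad_clip)
    st <- adam_step(agent$params, grads, agent$opt, lr)
    agent$params <- st$params; agent$opt <- st$opt
  }
  agent
}

# ---- off-policy machinery --------------------------------------------------

soft_update <- function(target, online, tau) {
  tree_map2(target, online, function(t, o) (1 - tau) * t + tau * o)
}

#' One DDPG update on a replay minibatch
#'
#' Critic regresses `Q(s, a)` to `r + gamma Q_target(s', mu_target(s'))`;
#' the actor ascends the critic's value of its own action; target
#' networks are Polyak-averaged.
#'
#' @param agent A DDPG agent.
#' @param batch List: `X`, `A` (actions in \[-1,1\]), `R`, `X2`, `D`
#'   (terminal flags).
#' @param lr Learning rate.
#' @return List: updated `agent`, `diagnostics` (`critic_loss`,
#'   `actor_loss`).
#' @export
ddpg_update <- function(agent, batch, lr) {
  stopifnot(agent$algo == "ddpg")
  n <- length(batch$R)
  if (n == 0) stop("empty replay batch")
  cfg <- agent$cfg
  tgt <- agent$target
  tgt_enc <- list(hidden = agent$hidden, layers = tgt$enc)
  feat2 <- lstm_forward(tgt_enc, batch$X2, need_cache = FALSE)$features
  a2 <- tanh(mlp_forward(feat2, tgt$actor)$out[, 1])
  q2 <- mlp_forward(cbind(feat2, a2), tgt$critic)$out[, 1]
  y <- batch$R + cfg$discount * (1 - batch$D) * q2

  enc <- enc_obj(agent)
  feat <- lstm_forward(enc, batch$X, need_cache = FALSE)$features
  qin <- cbind(feat, batch$A)
  qfw <- mlp_forward(qin, agent$params$critic)
  q <- qfw$out[, 1]
  critic_loss <- mean((q - y)^2)
  dq <- 2 * (q - y) / n
  cb <- mlp_backward(qfw, agent$params$critic, matrix(dq, n, 1))
  dfeat_c <- cb$dx[, seq_len(agent$hidden), drop = FALSE]

  # actor: maximise Q(s, tanh(mu(s))) with the critic frozen
  afw <- mlp_forward(feat, agent$params$actor)
  a_pi <- tanh(afw$out[, 1])
  q_pi_fw <- mlp_forward(cbind(feat, a_pi), agent$params$critic)
  actor_loss <- -mean(q_pi_fw$out[, 1])
  dq_pi <- matrix(-1 / n, n, 1)
  qb <- mlp_backward(q_pi_fw, agent$params$critic, dq_pi)
  da <- qb$dx[, agent$hidden + 1]
  dmu <- da * (1 - a_pi^2)
  ab <- mlp_backward(afw, agent$params$actor, matrix(dmu, n, 1))
  dfeat_a <- ab$dx + qb$dx[, seq_len(agent$hidden), drop = FALSE]

  eg <- lstm_train_grad(enc, batch$X, dfeat_c + dfeat_a)
  grads <- list(enc = eg, actor = ab$grads, critic = cb$grads)
  grads <- tree_clip(grads, cfg$grad_clip)
  st <- adam_step(agent$params, grads, agent$opt, lr)
  agent$params <- st$params; agent$opt <- st$opt
  agent$target <- soft_update(agent$target, agent$params, cfg$soft_update)
  list(agent = agent,
       diagnostics = list(critic_loss = critic_loss,
                          actor_loss = actor_loss))
}

#' One SAC update on a replay minibatch
#'
#' Twin critics regress to the entropy-regularised TD target built from
#' the minimum of the target critics; the actor maximises
#' `min(Q1, Q2) - lambda log pi` through the reparameterisation trick.
#'
#' @inheritParams ddpg_update
#' @param rng Optional [local_rng()] stream for the reparameterised draws.
#' @return List: updated `agent`, `diagnostics` (`critic_loss`,
#'   `actor_loss`, `entropy`).
#' @export
sac_update <- function(agent, batch, lr, rng = NULL) {
  stopifnot(agent$algo == "sac")
  cfg <- agent$cfg
  if (cfg$temperature < 0) stop("negative entropy temperature")
  n <- length(batch$R)
  if (n == 0) stop("empty replay batch")
  draw <- function(k) if (is.null(rng)) stats::rnorm(k) else rng$rnorm(k)
  lam <- cfg$temperature
  H <- agent$hidden

  tgt <- agent$target
  tgt_enc <- list(hidden = H, layers = tgt$enc)
  feat2 <- lstm_forward(tgt_enc, batch$X2, need_cache = FALSE)$features
  d2 <- {
    out <- mlp_forward(feat2, agent$params$actor)$out
    list(mu = out[, 1], log_std = pmin(2, pmax(-5, out[, 2])))
  }
  sig2 <- exp(d2$log_std)
  u2 <- d2$mu + sig2 * draw(n)
  a2 <- tanh(u2)
  lp2 <- squashed_logprob(u2, d2$mu, sig2)
  q1t <- mlp_forward(cbind(feat2, a2), tgt$q1)$out[, 1]
  q2t <- mlp_forward(cbind(feat2, a2), tgt$q2)$out[, 1]
  y <- batch$R + cfg$discount * (1 - batch$D) * (pmin(q1t, q2t) - lam * lp2)

  enc <- enc_obj(agent)
  feat <- lstm_forward(enc, batch$X, need_cache = FALSE)$features
  q1fw <- mlp_forward(cbind(feat, batch$A), agent$params$q1)
  q2fw <- mlp_forward(cbind(feat, batch$A), agent$params$q2)
  qv1 <- q1fw$out[, 1]; qv2 <- q2fw$out[, 1]
  critic_loss <- 0.5 * mean((qv1 - y)^2 + (qv2 - y)^2)
  b1 <- mlp_backward(q1fw, agent$params$q1, matrix((qv1 - y) / n, n, 1))
  b2 <- mlp_backward(q2fw, agent$params$q2, matrix((qv2 - y) / n, n, 1))
  dfeat_c <- (b1$dx + b2$dx)[, seq_len(H), drop = FALSE]

  # actor (critics frozen): minimise lambda*logpi - min(Q1,Q2)
  afw <- mlp_forward(feat, agent$params$actor)
  mu <- afw$out[, 1]
  log_std <- pmin(2, pmax(-5, afw$out[, 2]))
  sig <- exp(log_std)
  epsd <- draw(n)
  u <- mu + sig * epsd
  a <- tanh(u)
  lp <- squashed_logprob(u, mu, sig)
  qa1fw <- mlp_forward(cbind(feat, a), agent$params$q1)
  qa2fw <- mlp_forward(cbind(feat, a), agent$params$q2)
  qa1 <- qa1fw$out[, 1]; qa2 <- qa2fw$out[, 1]
  use1 <- qa1 <= qa2
  actor_loss <- mean(lam * lp - pmin(qa1, qa2))

  # route -dQ/da through the per-sample minimum critic
  dmin1 <- matrix(ifelse(use1, -1 / n, 0), n, 1)
  dmin2 <- matrix(ifelse(use1, 0, -1 / n), n, 1)
  qb1 <- mlp_backward(qa1fw, agent$params$q1, dmin1)
  qb2 <- mlp_backward(qa2fw, agent$params$q2, dmin2)
  da <- qb1$dx[, H + 1] + qb2$dx[, H + 1]
  dfeat_q <- (qb1$dx + qb2$dx)[, seq_len(H), drop = FALSE]
  # d(lam*lp)/du = lam*2a ; d(lp)/dlogstd = 2*a*eps*sig - 1
  du <- (lam * 2 * a) / n + da * (1 - a^2)
  dmu <- du
  dlogstd <- (lam * (2 * a * epsd * sig - 1)) / n + da * (1 - a^2) * epsd * sig
  dlogstd <- dlogstd * (log_std > -5 & log_std < 2)  # clamp gradient gate
  ab <- mlp_backward(afw, agent$params$actor, cbind(dmu, dlogstd))
  dfeat_a <- ab$dx + dfeat_q

  eg <- lstm_train_grad(enc, batch$X, dfeat_c + dfeat_a)
  grads <- list(enc = eg, actor = ab$grads, q1 = b1$grads, q2 = b2$grads)
  grads <- tree_clip(grads, cfg$grad_clip)
  st <- adam_step(agent$params, grads, agent$opt, lr)
  agent$params <- st$params; agent$opt <- st$opt
  agent$target <- soft_update(agent$target, agent$params, cfg$soft_update)
  list(agent = agent,
       diagnostics = list(critic_loss = critic_loss,
                          actor_loss = actor_loss,
                          entropy = mean(-lp)))
}

# ---- replay buffer ---------------------------------------------------------

# transitions are stored as flat rows [x (k*2), a, r, x2 (k*2), d] in a
# chunked ring store
replay_init <- function(capacity, k = 12) {
  st <- store_init(capacity, 4 * k + 3)
  st$k <- k
  st
}

replay_add <- function(buf, x, a, r, x2, done) {
  store_add(buf, c(as.vector(x), a, r, as.vector(x2), as.numeric(done)))
}

replay_sample <- function(buf, size, rng) {
  idx <- ceiling(rng$runif(size, 0, buf$n))
  rows <- store_rows(buf, idx)
  k <- buf$k
  X <- array(rows[, 1:(2 * k)], c(size, k, 2))
  X2 <- array(rows[, (2 * k + 3):(4 * k + 2)], c(size, k, 2))
  list(X = X, A = rows[, 2 * k + 1], R = rows[, 2 * k + 2], X2 = X2,
       D = rows[, 4 * k + 3])
}
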