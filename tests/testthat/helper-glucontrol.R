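# Shared fixtures: small configurations and generators used across the
# module tests. Everything is built in code at test time.

# a quiet patient (no sensor noise) for deterministic checks
quiet_env <- function(...) {
  patient_env(params = patient_params(cgm_noise_sd = 0), ...)
}

# constant observation window at the zero-risk glucose
flat_window <- function(g = 112.5, i = 0.02, k = 12) {
  list(glucose = rep(g, k), insulin = rep(i, k))
}

# controller holding the action that maps to the basal infusion rate
basal_controller <- function() {
  function(w, env) {
    1 + log(env$params$basal_rate / env$params$pump_max_rate) /
      env$action_tau
  }
}

# synthetic predictor-training set where the label follows a known
# linear-Gaussian rule g' = g + b (basal - g) - c * i_last * scale + eps
linear_rule_data <- function(n, b = 0.12, cc = 30, basal = 140,
                             noise_sd = 3, seed = 1) {
  rng <- local_rng(seed)
  k <- 12
  G <- matrix(0, n, k)
  G[, 1] <- rng$runif(n, 80, 220)
  for (t in 2:k) {
    G[, t] <- pmax(50, G[, t - 1] + rng$rnorm(n, 0, 4))
  }
  I <- matrix(rng$runif(n * k, 0, 0.2), n, k)
  A <- rng$runif(n, -1, 0.3)  # clinically plausible infusion range
  i_last <- action_to_insulin(A)
  Y <- G[, k] + b * (basal - G[, k]) - cc * i_last + rng$rnorm(n, 0, noise_sd)
  Y <- pmax(30, Y)
  list(G = G, I = I, A = A, Y = Y, noise_sd = noise_sd)
}

# mock predictor with a fixed prediction rule, exercising the generic path
make_mock_predictor <- function(fn) {
  structure(list(fn = fn, trained = TRUE), class = "mock_predictor")
}

predict_next.mock_predictor <- function(pred, windows, action) {
  if (!is.null(windows$glucose)) windows <- list(windows)
  means <- vapply(windows, function(w) pred$fn(w, NA), numeric(1))
  structure(list(mean = means, variance = rep(1e-8, length(means)),
                 trained = TRUE), class = "gaussian_prediction")
}
registerS3method("predict_next", "mock_predictor",
                 predict_next.mock_predictor,
                 envir = asNamespace("glucontrol"))

# an agent whose policy is (almost) deterministic at its mean
frozen_ppo <- function(seed = 1) {
  ag <- agent_init("ppo", learner_config(), seed = seed)
  ag$params$log_std[1, 1] <- log(1e-8)
  ag
}
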