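# Gaussian one-step glucose forecaster: attention encoder, Gaussian head,
# auxiliary buffer, training and the MPC activation gate.

test_that("predictions are deterministic with positive variance", {
  pr <- predictor_init(predictor_config(), seed = 4)
  w <- flat_window(140, 0.05)
  p1 <- predict_next(pr, w, 0.2)
  p2 <- predict_next(pr, w, 0.2)
  expect_identical(p1, p2)
  expect_gt(p1$variance, 0)
  expect_false(p1$trained)
  expect_error(predict_next(pr, w, 1.5), "outside")
  expect_error(predict_next(pr, list(glucose = 1:3, insulin = 1:3), 0),
               "malformed")
})

test_that("prob-sparse attention with full query budget equals dense attention", {
  cfg <- predictor_config(attention = "prob_sparse", sparse_factor = 100)
  pr <- predictor_init(cfg, seed = 4)
  rng <- local_rng(3)
  G <- matrix(rng$runif(5 * 12, 60, 300), 5, 12)
  I <- matrix(rng$runif(5 * 12, 0, 0.5), 5, 12)
  A <- rng$runif(5, -1, 1)
  fd <- glucontrol:::predictor_forward(pr, G, I, A, sparse = FALSE)
  fs <- glucontrol:::predictor_forward(pr, G, I, A, sparse = TRUE)
  expect_equal(fs$delta, fd$delta, tolerance = 1e-6)
  expect_equal(fs$logvar, fd$logvar, tolerance = 1e-6)
  # and a genuinely sparse budget changes (only) the lazy queries' mix
  cfg2 <- predictor_config(attention = "prob_sparse", sparse_factor = 1)
  pr2 <- pr; pr2$cfg <- cfg2
  fs2 <- glucontrol:::predictor_forward(pr2, G, I, A, sparse = TRUE)
  expect_true(is.finite(sum(fs2$delta)))
})

test_that("Gaussian sampling is seeded, unbiased, and collapses at zero variance", {
  pred <- structure(list(mean = 150, variance = 0, trained = TRUE),
                    class = "gaussian_prediction")
  expect_equal(sample_prediction(pred), 150)
  pred2 <- structure(list(mean = rep(120, 1e5), variance = rep(49, 1e5),
                          trained = TRUE), class = "gaussian_prediction")
  s <- sample_prediction(pred2, local_rng(5))
  expect_lt(abs(mean(s) - 120), 3 * 7 / sqrt(1e5))
  expect_identical(sample_prediction(pred2, local_rng(5)), s)
})

test_that("the Gaussian NLL matches the normal log-density", {
  err <- c(0, 0.5, -1.2)
  lv <- c(0, log(0.25), 1)
  nll <- 0.5 * (lv + err^2 * exp(-lv) + log(2 * pi))
  ref <- -stats::dnorm(err, 0, sqrt(exp(lv)), log = TRUE)
  expect_equal(nll, ref, tolerance = 1e-12)
})

test_that("training on the identity task drives held-out RMSE below 2 mg/dL", {
  rng <- local_rng(31)
  n <- 1500
  G <- matrix(rng$runif(n * 12, 60, 300), n, 12)
  I <- matrix(rng$runif(n * 12, 0, 0.5), n, 12)
  A <- rng$runif(n, -1, 1)
  pr <- predictor_init(predictor_config(epochs = 8), seed = 3)
  pr <- train_predictor(pr, list(G = G, I = I, A = A, Y = G[, 12]),
                        seed = 5)
  expect_lt(pr$last_rmse, 2)
  expect_true(pr$trained)
  expect_equal(nrow(pr$report), 8)
})

test_that("a predictor that reproduces its own mean has zero RMSE", {
  pr <- predictor_init(predictor_config(), seed = 9)
  rng <- local_rng(7)
  G <- matrix(rng$runif(20 * 12, 80, 200), 20, 12)
  I <- matrix(rng$runif(20 * 12, 0, 0.3), 20, 12)
  A <- rng$runif(20, -1, 1)
  mu <- predict_next(pr, lapply(seq_len(20), function(i)
    list(glucose = G[i, ], insulin = I[i, ])), A)$mean
  expect_equal(glucontrol:::predictor_rmse(pr, G, I, A, mu), 0,
               tolerance = 1e-9)
})

test_that("trained mean recovers a linear-Gaussian rule down to the noise floor", {
  dat <- linear_rule_data(4000, seed = 13)
  pr <- predictor_init(predictor_config(epochs = 12), seed = 17)
  pr <- train_predictor(pr, dat, seed = 19)
  expect_lt(pr$last_rmse, dat$noise_sd * 1.25)
})

test_that("auxiliary buffer gates training on its trigger threshold", {
  buf <- aux_buffer(capacity = 100, trigger_threshold = 10)
  w <- flat_window()
  for (i in 1:5) aux_add(buf, w, 0, 120)
  expect_false(aux_ready(buf))
  pr <- predictor_init(predictor_config(), seed = 1)
  expect_error(train_predictor(pr, buf), "threshold")
  for (i in 1:5) aux_add(buf, w, 0, 120 + i)
  expect_true(aux_ready(buf))
  expect_error(aux_add(buf, w, 0, -5), "next_glucose")
  # constant labels are degenerate
  buf2 <- aux_buffer(capacity = 100, trigger_threshold = 5)
  for (i in 1:6) aux_add(buf2, w, 0, 120)
  expect_error(train_predictor(pr, buf2), "degenerate")
})

test_that("RMSE gate activates at threshold and latches with hysteresis", {
  g <- rmse_gate(threshold = 15, hysteresis = 2)
  expect_false(gate_update(g, 15.1))
  expect_true(gate_update(g, 14.9))
  expect_true(gate_update(g, 0))
  # latched: within the hysteresis band it stays active
  expect_true(gate_update(g, 16.5))
  # a lower RMSE never deactivates
  expect_true(gate_update(g, 1))
  # beyond threshold + hysteresis it releases
  expect_false(gate_update(g, 17.5))
  g2 <- rmse_gate()
  expect_true(gate_update(g2, 0))
  expect_error(gate_update(g2, -1), ">= 0")
})

test_that("compiled forward passes match the reference implementation", {
  pr <- predictor_init(predictor_config(), seed = 23)
  rng <- local_rng(29)
  G <- matrix(rng$runif(9 * 12, 60, 300), 9, 12)
  I <- matrix(rng$runif(9 * 12, 0, 0.5), 9, 12)
  A <- rng$runif(9, -1, 1)
  fR <- glucontrol:::predictor_forward(pr, G, I, A, need_cache = TRUE)
  fC <- glucontrol:::predictor_forward(pr, G, I, A, need_cache = FALSE)
  expect_equal(fC$delta, fR$delta, tolerance = 1e-6)
  expect_equal(fC$logvar, fR$logvar, tolerance = 1e-6)
  enc <- encoder_init(2, 16, 2, seed = 31)
  X <- array(rng$rnorm(7 * 12 * 2), c(7, 12, 2))
  hR <- glucontrol:::lstm_forward(list(hidden = 16, layers = enc$layers),
                                  X, need_cache = TRUE)$features
  hC <- glucontrol:::lstm_features_cpp(X, enc$layers, 16)
  expect_lt(max(abs(hC - hR)), 1e-6)
  # compiled training gradients against the reference backward pass
  dfeat <- matrix(rng$rnorm(7 * 16), 7, 16)
  fw <- glucontrol:::lstm_forward(list(hidden = 16, layers = enc$layers),
                                  X, need_cache = TRUE)
  gR <- glucontrol:::lstm_backward(list(hidden = 16, layers = enc$layers),
                                   fw, dfeat)
  gC <- glucontrol:::lstm_train_grad(list(hidden = 16,
                                          layers = enc$layers), X, dfeat)
  for (l in 1:2) {
    expect_lt(max(abs(gR[[l]]$Wx - gC[[l]]$Wx)), 1e-6)
    expect_lt(max(abs(gR[[l]]$Wh - gC[[l]]$Wh)), 1e-6)
    expect_lt(max(abs(gR[[l]]$b - gC[[l]]$b)), 1e-6)
  }
})
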