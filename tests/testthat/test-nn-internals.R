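# Numerical guards for the hand-derived gradients and the seeded RNG
# streams: every backward pass is validated against central finite
# differences.

test_that("LSTM backprop-through-time matches finite differences", {
  enc <- encoder_init(input_dim = 2, hidden = 5, layers = 2, seed = 3)
  rng <- local_rng(12)
  n <- 4; Tn <- 6
  X <- array(rng$rnorm(n * Tn * 2), c(n, Tn, 2))
  M <- matrix(rng$rnorm(n * 5), n, 5)
  loss <- function(e) {
    sum(glucontrol:::lstm_forward(e, X, need_cache = TRUE)$features * M)
  }
  fw <- glucontrol:::lstm_forward(enc, X)
  g <- glucontrol:::lstm_backward(enc, fw, M)
  eps <- 1e-5
  for (l in 1:2) {
    for (nm in c("Wx", "Wh", "b")) {
      P <- enc$layers[[l]][[nm]]
      for (i in sample(length(P), 4)) {
        e1 <- enc; e1$layers[[l]][[nm]][i] <- P[i] + eps
        e2 <- enc; e2$layers[[l]][[nm]][i] <- P[i] - eps
        num <- (loss(e1) - loss(e2)) / (2 * eps)
        expect_equal(g[[l]][[nm]][i], num, tolerance = 1e-5)
      }
    }
  }
})

test_that("attention-layer backward matches finite differences", {
  cfg <- predictor_config(embedding_dim = 16, attention_heads = 4,
                          feedforward_hidden = 32)
  pr <- predictor_init(cfg, k = 6, seed = 2)
  rng <- local_rng(21)
  n <- 5
  G <- matrix(rng$runif(n * 6, 80, 200), n, 6)
  I <- matrix(rng$runif(n * 6, 0, 0.5), n, 6)
  A <- rng$runif(n, -1, 1)
  y <- rng$rnorm(n)
  nll_of <- function(params) {
    pr2 <- pr; pr2$params <- params
    fw <- glucontrol:::predictor_forward(pr2, G, I, A, need_cache = TRUE)
    err <- fw$delta - y
    mean(0.5 * (fw$logvar + err^2 * exp(-fw$logvar) + log(2 * pi)))
  }
  fw <- glucontrol:::predictor_forward(pr, G, I, A, need_cache = TRUE)
  err <- fw$delta - y
  invv <- exp(-fw$logvar)
  dd <- err * invv / n
  dl <- 0.5 * (1 - err^2 * invv) / n *
    (fw$raw_logvar > -10 & fw$raw_logvar < 5)
  p <- pr$params
  hb <- glucontrol:::dense_backward(fw$cache$pooled, p$head, cbind(dd, dl))
  dx <- matrix(0, n * pr$L, cfg$embedding_dim)
  dx[fw$cache$act_rows, ] <- hb$dx
  bb <- glucontrol:::attn_layer_backward(fw$cache$caches[[1]],
                                         p$layers[[1]], dx)
  eps <- 1e-5
  for (nm in c("Wq", "Wk", "Wv", "Wo", "g1")) {
    P <- p$layers[[1]][[nm]]
    for (i in sample(length(P), 3)) {
      p1 <- p; p1$layers[[1]][[nm]][i] <- P[i] + eps
      p2 <- p; p2$layers[[1]][[nm]][i] <- P[i] - eps
      num <- (nll_of(p1) - nll_of(p2)) / (2 * eps)
      expect_equal(bb$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
  ffW <- p$layers[[1]]$ff1$W
  for (i in sample(length(ffW), 3)) {
    p1 <- p; p1$layers[[1]]$ff1$W[i] <- ffW[i] + eps
    p2 <- p; p2$layers[[1]]$ff1$W[i] <- ffW[i] - eps
    num <- (nll_of(p1) - nll_of(p2)) / (2 * eps)
    expect_equal(bb$grads$ff1$W[i], num, tolerance = 1e-4)
  }
})

test_that("imitation gradients match finite differences across the tree", {
  ag <- agent_init("ppo", learner_config(), hidden = 6, enc_layers = 2,
                   head_hidden = 8, seed = 5)
  rng <- local_rng(31)
  X <- array(rng$rnorm(3 * 12 * 2), c(3, 12, 2))
  a_star <- c(0.2, -0.5, 0.7)
  ig <- glucontrol:::imitation_grads(ag, X, a_star)
  loss_of <- function(p) {
    ag2 <- ag; ag2$params <- p
    glucontrol:::imitation_grads(ag2, X, a_star)$loss
  }
  eps <- 1e-5
  checks <- list(
    list(g = ig$grads$actor$l1$W,
         set = function(p, i, d) { p$actor$l1$W[i] <- p$actor$l1$W[i] + d; p }),
    list(g = ig$grads$enc[[1]]$Wx,
         set = function(p, i, d) { p$enc[[1]]$Wx[i] <- p$enc[[1]]$Wx[i] + d; p }),
    list(g = ig$grads$enc[[2]]$Wh,
         set = function(p, i, d) { p$enc[[2]]$Wh[i] <- p$enc[[2]]$Wh[i] + d; p }),
    list(g = ig$grads$log_std,
         set = function(p, i, d) { p$log_std[i] <- p$log_std[i] + d; p }))
  for (ck in checks) {
    for (i in sample(length(ck$g), min(3, length(ck$g)))) {
      num <- (loss_of(ck$set(ag$params, i, eps)) -
                loss_of(ck$set(ag$params, i, -eps))) / (2 * eps)
      expect_equal(ck$g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("named RNG streams are isolated and reproducible", {
  s1 <- derive_seed(1, "env"); s2 <- derive_seed(1, "policy")
  expect_true(s1 != s2)
  expect_identical(derive_seed(1, "env"), s1)
  expect_true(s1 >= 0 && s1 < 2^31)
  r1 <- local_rng(5); r2 <- local_rng(5); r3 <- local_rng(6)
  a <- r1$rnorm(5)
  set.seed(123)  # global RNG interference must not leak into streams
  b <- r2$rnorm(5)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, r3$rnorm(5))))
  # interleaved draws continue each stream independently
  x1 <- r1$runif(3); x2 <- r2$runif(3)
  expect_identical(x1, x2)
})

test_that("Adam updates follow the bias-corrected first step", {
  p <- list(w = matrix(c(1, 2), 1))
  g <- list(w = matrix(c(0.5, -0.25), 1))
  opt <- glucontrol:::adam_init(p)
  st <- glucontrol:::adam_step(p, g, opt, lr = 0.1)
  # first step moves by ~lr * sign(grad) under bias correction
  expect_equal(st$params$w, matrix(c(1 - 0.1, 2 + 0.1), 1),
               tolerance = 1e-6)
})

test_that("gradient clipping preserves direction and caps the global norm", {
  g <- list(a = matrix(3, 1), b = matrix(4, 1))
  gc <- glucontrol:::tree_clip(g, 1)
  nrm <- sqrt(gc$a[1]^2 + gc$b[1]^2)
  expect_equal(nrm, 1, tolerance = 1e-12)
  expect_equal(gc$a[1] / gc$b[1], 3 / 4, tolerance = 1e-12)
  g2 <- glucontrol:::tree_clip(g, 100)
  expect_identical(g2, g)
})
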