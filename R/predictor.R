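#' Glucose predictor configuration
#'
#' @param encoder_layers Number of attention encoder layers (default 1).
#' @param attention_heads Attention heads (default 4).
#' @param embedding_dim Token embedding dimension (default 64), divisible
#'   by the head count.
#' @param feedforward_hidden Hidden units of the position-wise
#'   feed-forward block (default 128).
#' @param attention `"dense"` (default) or `"prob_sparse"`. At window
#'   length 12 the two are near-identical; prob-sparse keeps the top-u
#'   queries by a max-minus-mean sparsity score and routes the rest to
#'   the mean value.
#' @param sparse_factor `u = ceil(sparse_factor * ln L)` queries kept by
#'   the prob-sparse path.
#' @param lr Adam learning rate.
#' @param epochs Training epochs of the initial training call.
#' @param retrain_epochs Epochs of subsequent retraining calls (the
#'   parameters continue from the previous fit, so fewer passes suffice).
#' @param batch_size Minibatch size.
#' @param val_frac Held-out fraction used for the reported RMSE.
#' @param max_train_samples Cap on the samples drawn from the buffer per
#'   (re)training call; larger buffers are subsampled uniformly.
#' @param rmse_threshold MPC activation threshold (mg/dL), default 15.
#' @param rmse_hysteresis Deactivation margin above the threshold.
#' @return An object of class `predictor_config`.
#' @export
predictor_config <- function(encoder_layers = 1, attention_heads = 4,
                             embedding_dim = 64, feedforward_hidden = 128,
                             attention = c("dense", "prob_sparse"),
                             sparse_factor = 3, lr = 1e-3, epochs = 10,
                             retrain_epochs = 4,
                             batch_size = 256, val_frac = 0.2,
                             max_train_samples = 8000,
                             rmse_threshold = 15, rmse_hysteresis = 2) {
  attention <- match.arg(attention)
  stopifnot(embedding_dim %% attention_heads == 0, encoder_layers >= 1,
            val_frac > 0, val_frac < 1, rmse_threshold > 0)
  structure(as.list(environment()), class = "predictor_config")
}

# glucose/insulin/action -> (L = k + 1) x 4 token features
# glucose tokens: (g_scaled, i_scaled, 0, 0); action token: (0, 0, a, 1)
predictor_tokens <- function(G, I, A) {
  n <- nrow(G); k <- ncol(G); L <- k + 1
  X <- matrix(0, n * L, 4)
  for (t in seq_len(k)) {
    rows <- (seq_len(n) - 1) * L + t
    X[rows, 1] <- (G[, t] - 112.5) / 50
    X[rows, 2] <- I[, t] * 10
  }
  rows <- (seq_len(n) - 1) * L + L
  X[rows, 3] <- A
  X[rows, 4] <- 1
  X
}

#' Initialise the Gaussian one-step glucose predictor
#'
#' Embeds the k-step (glucose, insulin) window plus an action token, runs
#' a self-attention encoder and maps the action-token output to the mean
#' and log-variance of the next CGM glucose (as a residual on the last
#' observed glucose, in 50 mg/dL scaled units).
#'
#' @param cfg A [predictor_config()].
#' @param k Observation window length (default 12).
#' @param seed Initialisation seed.
#' @return An object of class `glucose_predictor` (untrained).
#' @export
predictor_init <- function(cfg = predictor_config(), k = 12, seed = 1L) {
  rng <- local_rng(derive_seed(seed, "predictor"))
  d <- cfg$embedding_dim; L <- k + 1
  params <- list(
    embed = dense_init(4, d, rng),
    pos = nn_mat(L, d, rng, scale = 0.02),
    layers = lapply(seq_len(cfg$encoder_layers), function(i)
      attn_layer_init(d, cfg$attention_heads, cfg$feedforward_hidden, rng)),
    head = dense_init(d, 2, rng, scale = 0.01)
  )
  structure(list(cfg = cfg, k = k, L = L, params = params,
                 opt = adam_init(params), trained = FALSE,
                 last_rmse = NA_real_),
            class = "glucose_predictor")
}

# forward pass; G,I: n x k matrices, A: length-n actions.
# Returns scaled residual mean/logvar (+cache).
predictor_forward <- function(pred, G, I, A, need_cache = FALSE,
                              sparse = FALSE) {
  cfg <- pred$cfg; p <- pred$params
  n <- nrow(G); L <- pred$L
  if (!need_cache && !sparse) {
    out <- predictor_forward_cpp(G, I, A, p, cfg$attention_heads)
    return(list(delta = out[, 1], logvar = pmin(5, pmax(-10, out[, 2])),
                raw_logvar = out[, 2]))
  }
  tok <- predictor_tokens(G, I, A)
  E <- dense_forward(tok, p$embed)
  # add positional embedding (rows cycle within each item)
  posrep <- p$pos[rep(seq_len(L), n), , drop = FALSE]
  E <- E + posrep
  caches <- if (need_cache) vector("list", length(p$layers)) else NULL
  x <- E
  u <- if (sparse) max(1L, ceiling(cfg$sparse_factor * log(L))) else NULL
  for (li in seq_along(p$layers)) {
    fw <- attn_layer_forward(x, p$layers[[li]], n, L, cfg$attention_heads,
                             need_cache = need_cache, sparse_u = u)
    if (need_cache) caches[[li]] <- fw$cache
    x <- fw$y
  }
  act_rows <- (seq_len(n) - 1) * L + L
  pooled <- x[act_rows, , drop = FALSE]
  out <- dense_forward(pooled, p$head)
  logvar <- pmin(5, pmax(-10, out[, 2]))
  res <- list(delta = out[, 1], logvar = logvar, raw_logvar = out[, 2])
  if (need_cache) {
    res$cache <- list(tok = tok, caches = caches, pooled = pooled,
                      act_rows = act_rows, n = n)
  }
  res
}

#' Predict the next-step glucose distribution
#'
#' @param pred A [predictor_init()] (ideally trained) predictor.
#' @param windows One observation window or a list of windows.
#' @param action Matching action(s) in \[-1, 1\].
#' @return A list of class `gaussian_prediction`: `mean` (mg/dL),
#'   `variance` ((mg/dL)^2), `trained` flag.
#' @export
predict_next <- function(pred, windows, action) UseMethod("predict_next")

#' @export
predict_next.glucose_predictor <- function(pred, windows, action) {
  if (any(!is.finite(action)) || any(action < -1) || any(action > 1)) {
    stop("action outside [-1, 1]")
  }
  if (!is.null(windows$glucose)) windows <- list(windows)
  n <- length(windows)
  G <- t(vapply(windows, function(w) {
    if (length(w$glucose) != pred$k) stop("malformed observation window")
    w$glucose
  }, numeric(pred$k)))
  I <- t(vapply(windows, `[[`, numeric(pred$k), "insulin"))
  fw <- predictor_forward(pred, G, I, rep_len(action, n),
                          sparse = pred$cfg$attention == "prob_sparse")
  structure(list(mean = G[, pred$k] + fw$delta * 50,
                 variance = exp(fw$logvar) * 2500,
                 trained = pred$trained),
            class = "gaussian_prediction")
}

#' Sample a glucose value from a Gaussian prediction
#'
#' @param prediction A `gaussian_prediction` from [predict_next()].
#' @param rng Optional [local_rng()] stream.
#' @return Sampled glucose value(s), clamped to at least 1 mg/dL.
#' @export
sample_prediction <- function(prediction, rng = NULL) {
  n <- length(prediction$mean)
  z <- if (is.null(rng)) stats::rnorm(n) else rng$rnorm(n)
  pmax(1, prediction$mean + sqrt(prediction$variance) * z)
}

# ---- auxiliary buffer ------------------------------------------------------

#' Auxiliary transition buffer for predictor training
#'
#' Bounded FIFO of (state window, action, next true glucose) samples
#' collected during reinforcement-learning interaction; training fires
#' once the sample count reaches the trigger threshold.
#'
#' @param capacity Maximum retained samples.
#' @param trigger_threshold Samples required before training triggers.
#' @param k Window length.
#' @return An `aux_buffer` environment.
#' @export
aux_buffer <- function(capacity = 20000, trigger_threshold = 5000,
                       k = 12) {
  e <- store_init(capacity, 2 * k + 2)
  e$k <- k
  e$trigger_threshold <- trigger_threshold
  class(e) <- "aux_buffer"
  e
}

#' @rdname aux_buffer
#' @param buf An `aux_buffer`.
#' @param window Observation window at decision time.
#' @param action Action taken.
#' @param next_glucose Simulator-true glucose after the step (mg/dL).
#' @export
aux_add <- function(buf, window, action, next_glucose) {
  stopifnot(next_glucose > 0)
  store_add(buf, c(window$glucose, window$insulin, action, next_glucose))
}

# materialise the buffer contents as training matrices
aux_materialize <- function(buf) {
  rows <- store_rows(buf, seq_len(buf$n))
  k <- buf$k
  list(G = rows[, 1:k, drop = FALSE],
       I = rows[, (k + 1):(2 * k), drop = FALSE],
       A = rows[, 2 * k + 1], Y = rows[, 2 * k + 2])
}

#' @rdname aux_buffer
#' @export
aux_ready <- function(buf) buf$n >= buf$trigger_threshold

#' Train the Gaussian glucose predictor on an auxiliary buffer
#'
#' Minimises the Gaussian negative log-likelihood of the next true
#' glucose (in scaled residual units) by minibatch Adam, on a random
#' train split, and reports the RMSE of the predicted mean on the
#' held-out fraction after each epoch.
#'
#' @param pred A [predictor_init()] object.
#' @param buf An [aux_buffer()] at (or above) its trigger threshold, or a
#'   list with fields `G`, `I`, `A`, `Y`.
#' @param seed Seed for the split and batch order.
#' @param epochs Override of `cfg$epochs`.
#' @return The trained predictor, with a `report` data frame
#'   (`epoch`, `train_nll`, `val_rmse`) attached and `last_rmse` set to
#'   the final held-out RMSE (mg/dL).
#' @export
train_predictor <- function(pred, buf, seed = 1L, epochs = NULL) {
  cfg <- pred$cfg
  if (is.null(epochs)) epochs <- cfg$epochs
  if (inherits(buf, "aux_buffer")) {
    if (!aux_ready(buf)) stop("auxiliary buffer below trigger threshold")
    buf <- aux_materialize(buf)
  }
  n <- length(buf$Y)
  rng <- local_rng(derive_seed(seed, "predictor_train"))
  idx <- seq_len(n)
  if (n > cfg$max_train_samples) {
    idx <- order(rng$runif(n))[seq_len(cfg$max_train_samples)]
    n <- cfg$max_train_samples
  }
  G <- buf$G[idx, , drop = FALSE]; I <- buf$I[idx, , drop = FALSE]
  A <- buf$A[idx]; Y <- buf$Y[idx]
  if (stats::sd(Y) < 1e-9) stop("degenerate (constant) buffer")
  y <- (Y - G[, ncol(G)]) / 50  # scaled residual target
  ord <- order(rng$runif(n))
  n_val <- max(1, floor(cfg$val_frac * n))
  val <- ord[seq_len(n_val)]; trn <- ord[-seq_len(n_val)]
  report <- data.frame(epoch = integer(0), train_nll = numeric(0),
                       val_rmse = numeric(0))
  for (ep in seq_len(epochs)) {
    perm <- trn[order(rng$runif(length(trn)))]
    nll_sum <- 0
    for (start in seq(1, length(perm), by = cfg$batch_size)) {
      bi <- perm[start:min(start + cfg$batch_size - 1, length(perm))]
      m <- length(bi)
      if (cfg$attention == "dense") {
        # compiled fused forward+backward (reference R path below is
        # asserted equal in the tests)
        out <- predictor_grads_cpp(G[bi, , drop = FALSE],
                                   I[bi, , drop = FALSE], A[bi], y[bi],
                                   pred$params, cfg$attention_heads)
        nll_sum <- nll_sum + out$loss_sum
        grads <- normalize_pred_grads(out$grads)
        grads <- tree_clip(grads, 10)
        st <- adam_step(pred$params, grads, pred$opt, cfg$lr)
        pred$params <- st$params; pred$opt <- st$opt
      } else {
        fw <- predictor_forward(pred, G[bi, , drop = FALSE],
                                I[bi, , drop = FALSE], A[bi],
                                need_cache = TRUE)
        err <- fw$delta - y[bi]
        invv <- exp(-fw$logvar)
        nll <- 0.5 * (fw$logvar + err^2 * invv + LOG2PI)
        nll_sum <- nll_sum + sum(nll)
        ddelta <- err * invv / m
        dlogvar <- 0.5 * (1 - err^2 * invv) / m
        dlogvar <- dlogvar * (fw$raw_logvar > -10 & fw$raw_logvar < 5)
        pred <- predictor_backstep(pred, fw$cache, ddelta, dlogvar)
      }
    }
    vr <- predictor_rmse(pred, G[val, , drop = FALSE],
                         I[val, , drop = FALSE], A[val], Y[val])
    report <- rbind(report, data.frame(epoch = ep,
                                       train_nll = nll_sum / length(trn),
                                       val_rmse = vr))
  }
  pred$trained <- TRUE
  pred$last_rmse <- report$val_rmse[nrow(report)]
  pred$report <- report
  pred
}

# coerce the compiled gradients' row vectors back to plain numerics so
# the gradient tree mirrors the parameter tree exactly
normalize_pred_grads <- function(g) {
  g$embed$b <- as.numeric(g$embed$b)
  g$head$b <- as.numeric(g$head$b)
  g$layers <- lapply(g$layers, function(l) {
    for (nm in c("g1", "b1", "g2", "b2")) l[[nm]] <- as.numeric(l[[nm]])
    l$ff1$b <- as.numeric(l$ff1$b)
    l$ff2$b <- as.numeric(l$ff2$b)
    l
  })
  g
}

# one Adam step from head gradients back through the encoder stack
predictor_backstep <- function(pred, cache, ddelta, dlogvar) {
  p <- pred$params; cfg <- pred$cfg
  n <- cache$n; L <- pred$L
  dout <- cbind(ddelta, dlogvar)
  hb <- dense_backward(cache$pooled, p$head, dout)
  dx <- matrix(0, n * L, cfg$embedding_dim)
  dx[cache$act_rows, ] <- hb$dx
  layer_grads <- vector("list", length(p$layers))
  for (li in seq(length(p$layers), 1)) {
    bb <- attn_layer_backward(cache$caches[[li]], p$layers[[li]], dx)
    layer_grads[[li]] <- bb$grads
    dx <- bb$dx
  }
  dpos <- rowsum(dx, rep(seq_len(L), n))
  eb <- dense_backward(cache$tok, p$embed, dx)
  grads <- list(embed = eb$grads, pos = unname(dpos), layers = layer_grads,
                head = hb$grads)
  grads <- tree_clip(grads, 10)
  st <- adam_step(p, grads, pred$opt, cfg$lr)
  pred$params <- st$params; pred$opt <- st$opt
  pred
}

# RMSE (mg/dL) of the predicted mean on given samples
predictor_rmse <- function(pred, G, I, A, Y) {
  fw <- predictor_forward(pred, G, I, A)
  mu <- G[, ncol(G)] + fw$delta * 50
  sqrt(mean((mu - Y)^2))
}

#' Latched RMSE activation gate for the MPC stage
#'
#' The planner activates once the predictor's held-out RMSE drops to the
#' threshold; activation is latched and only released when the RMSE
#' exceeds the threshold plus a hysteresis margin.
#'
#' @param threshold Activation RMSE (mg/dL), default 15.
#' @param hysteresis Deactivation margin (mg/dL), default 2.
#' @return An `rmse_gate` environment with an `active` flag.
#' @export
rmse_gate <- function(threshold = 15, hysteresis = 2) {
  e <- new.env(parent = emptyenv())
  e$threshold <- threshold; e$hysteresis <- hysteresis
  e$active <- FALSE
  class(e) <- "rmse_gate"
  e
}

#' @rdname rmse_gate
#' @param gate An `rmse_gate`.
#' @param recent_rmse Latest held-out RMSE (mg/dL), non-negative.
#' @return The updated `active` flag (logical).
#' @export
gate_update <- function(gate, recent_rmse) {
  stopifnot(recent_rmse >= 0)
  if (!gate$active && recent_rmse <= gate$threshold) gate$active <- TRUE
  if (gate$active && recent_rmse > gate$threshold + gate$hysteresis) {
    gate$active <- FALSE
  }
  gate$active
}
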