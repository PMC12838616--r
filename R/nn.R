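# Minimal neural-network toolkit: dense layers, a multi-layer LSTM with
# backprop-through-time, and Adam. Parameters are nested lists of
# matrices/vectors; gradients mirror their shape. All gradients here are
# hand-derived and covered by finite-difference tests.

LOG2PI <- log(2 * pi)

nn_mat <- function(nr, nc, rng, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(1 / nr)
  matrix(rng$rnorm(nr * nc, 0, scale), nr, nc)
}

sigm <- function(x) 1 / (1 + exp(-x))

#' Initialise the shared LSTM state encoder
#'
#' A stack of LSTM layers over the (glucose, insulin) observation window;
#' the final hidden state of the top layer is the feature vector shared by
#' the actor and critic heads.
#'
#' @param input_dim Features per timestep (2: scaled glucose and insulin).
#' @param hidden Hidden units per layer (default 16).
#' @param layers Number of LSTM layers (default 2).
#' @param seed Seed for the initialisation draws.
#' @return Encoder parameter list.
#' @export
encoder_init <- function(input_dim = 2, hidden = 16, layers = 2,
                         seed = 1L) {
  stopifnot(layers >= 1, hidden >= 1)
  rng <- local_rng(derive_seed(seed, "encoder_init"))
  out <- list(hidden = hidden, layers = vector("list", layers))
  d_in <- input_dim
  for (l in seq_len(layers)) {
    b <- rep(0, 4 * hidden)
    b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias
    out$layers[[l]] <- list(Wx = nn_mat(d_in, 4 * hidden, rng),
                            Wh = nn_mat(hidden, 4 * hidden, rng), b = b)
    d_in <- hidden
  }
  out
}

# X: array (n, T, input_dim). Returns features (n x hidden) and cache.
# The cache-free path dispatches to the compiled forward.
lstm_forward <- function(enc, X, need_cache = TRUE) {
  n <- dim(X)[1]; Tn <- dim(X)[2]; H <- enc$hidden
  if (!need_cache) {
    return(list(features = lstm_features_cpp(X, enc$layers, H),
                cache = NULL, n = n, Tn = Tn))
  }
  L <- length(enc$layers)
  cache <- if (need_cache) vector("list", L) else NULL
  inp <- X
  for (l in seq_len(L)) {
    P <- enc$layers[[l]]
    h <- matrix(0, n, H); cc <- matrix(0, n, H)
    st <- if (need_cache) vector("list", Tn) else NULL
    outs <- if (l < L) array(0, c(n, Tn, H)) else NULL
    for (t in seq_len(Tn)) {
      x_t <- matrix(inp[, t, ], n)
      z <- x_t %*% P$Wx + h %*% P$Wh
      z <- z + rep(P$b, each = n)  # column-major broadcast of the bias
      i <- sigm(z[, 1:H, drop = FALSE])
      f <- sigm(z[, (H + 1):(2 * H), drop = FALSE])
      g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
      o <- sigm(z[, (3 * H + 1):(4 * H), drop = FALSE])
      c_new <- f * cc + i * g
      h_new <- o * tanh(c_new)
      if (need_cache) {
        st[[t]] <- list(x = x_t, h_prev = h, c_prev = cc, i = i, f = f,
                        g = g, o = o, c = c_new)
      }
      h <- h_new; cc <- c_new
      if (l < L) outs[, t, ] <- h
    }
    if (need_cache) cache[[l]] <- st
    if (l < L) inp <- outs
  }
  list(features = h, cache = cache, n = n, Tn = Tn)
}

# Backprop from d(features) through the LSTM stack. Returns gradients with
# the same shape as enc$layers.
lstm_backward <- function(enc, fwd, dfeat) {
  H <- enc$hidden; L <- length(enc$layers)
  n <- fwd$n; Tn <- fwd$Tn
  grads <- vector("list", L)
  # d of this layer's output h_t for every t (only top layer's final step
  # receives dfeat initially; lower layers receive dx from above)
  dout <- vector("list", L)
  dout[[L]] <- vector("list", Tn)
  dout[[L]][[Tn]] <- dfeat
  for (l in seq(L, 1)) {
    P <- enc$layers[[l]]
    st <- fwd$cache[[l]]
    dWx <- matrix(0, nrow(P$Wx), ncol(P$Wx))
    dWh <- matrix(0, H, 4 * H)
    db <- rep(0, 4 * H)
    dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
    dx_all <- if (l > 1) vector("list", Tn) else NULL
    for (t in seq(Tn, 1)) {
      s <- st[[t]]
      dh <- dh_next
      if (!is.null(dout[[l]][[t]])) dh <- dh + dout[[l]][[t]]
      tc <- tanh(s$c)
      do_ <- dh * tc
      dc <- dc_next + dh * s$o * (1 - tc^2)
      di <- dc * s$g; dg <- dc * s$i; df <- dc * s$c_prev
      dc_next <- dc * s$f
      dz <- cbind(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
                  dg * (1 - s$g^2), do_ * s$o * (1 - s$o))
      dWx <- dWx + crossprod(s$x, dz)
      dWh <- dWh + crossprod(s$h_prev, dz)
      db <- db + colSums(dz)
      dh_next <- dz %*% t(P$Wh)
      if (l > 1) dx_all[[t]] <- dz %*% t(P$Wx)
    }
    grads[[l]] <- list(Wx = dWx, Wh = dWh, b = db)
    if (l > 1) dout[[l - 1]] <- dx_all
  }
  grads
}

# compiled fused forward+BPTT gradient with the same return shape as
# lstm_backward; the R pair stays the finite-difference reference
lstm_train_grad <- function(enc, X, dfeat) {
  g <- lstm_grad_cpp(X, enc$layers, enc$hidden, dfeat)
  lapply(g, function(l) list(Wx = l$Wx, Wh = l$Wh, b = as.numeric(l$b)))
}

#' Encode observation windows into feature vectors
#'
#' Scales the raw (glucose, insulin) histories and runs the shared LSTM.
#' Deterministic given parameters; identical windows give identical
#' features.
#'
#' @param enc Encoder parameters from [encoder_init()].
#' @param windows Either one window list (`glucose`, `insulin`) or a list
#'   of them.
#' @return A matrix of features (n x hidden).
#' @export
encode <- function(enc, windows) {
  X <- windows_to_array(windows)
  lstm_forward(enc, X, need_cache = FALSE)$features
}

# (glucose, insulin) history matrices (n x T) -> scaled (n, T, 2) array
ga_array <- function(G, I) {
  n <- nrow(G); Tn <- ncol(G)
  X <- array(0, c(n, Tn, 2))
  X[, , 1] <- (G - 112.5) / 50
  X[, , 2] <- I * 10
  X
}

# windows -> (n, T, 2) array of scaled inputs
windows_to_array <- function(windows) {
  if (!is.null(windows$glucose)) windows <- list(windows)
  Tn <- length(windows[[1]]$glucose)
  G <- t(vapply(windows, function(w) {
    if (length(w$glucose) != Tn) stop("malformed observation window")
    w$glucose
  }, numeric(Tn)))
  I <- t(vapply(windows, function(w) {
    if (length(w$insulin) != Tn) stop("malformed observation window")
    w$insulin
  }, numeric(Tn)))
  ga_array(G, I)
}

# ---- dense layers ----------------------------------------------------------

dense_init <- function(d_in, d_out, rng, scale = NULL) {
  list(W = nn_mat(d_in, d_out, rng, scale), b = rep(0, d_out))
}

dense_forward <- function(x, p) {
  y <- x %*% p$W
  y + rep(p$b, each = nrow(y))
}

# returns list(dx, grads = list(W, b))
dense_backward <- function(x, p, dy) {
  list(dx = dy %*% t(p$W),
       grads = list(W = crossprod(x, dy), b = colSums(dy)))
}

# two-layer tanh MLP head: d_in -> d_hid (tanh) -> d_out
mlp_init <- function(d_in, d_hid, d_out, rng) {
  list(l1 = dense_init(d_in, d_hid, rng), l2 = dense_init(d_hid, d_out, rng))
}

mlp_forward <- function(x, p) {
  a1 <- tanh(dense_forward(x, p$l1))
  list(out = dense_forward(a1, p$l2), a1 = a1, x = x)
}

mlp_backward <- function(fwd, p, dy) {
  b2 <- dense_backward(fwd$a1, p$l2, dy)
  da1 <- b2$dx * (1 - fwd$a1^2)
  b1 <- dense_backward(fwd$x, p$l1, da1)
  list(dx = b1$dx, grads = list(l1 = b1$grads, l2 = b2$grads))
}

# ---- parameter-tree utilities ---------------------------------------------

# apply f(elementwise) over two parallel nested lists of numerics
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- tree_map2(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- tree_map(a[[nm]], f)
    out
  } else f(a)
}

# sum of two gradient trees
tree_add <- function(a, b) tree_map2(a, b, `+`)

tree_zeros_like <- function(a) tree_map(a, function(x) x * 0)

# global gradient-norm clipping over a tree
tree_clip <- function(g, max_norm) {
  sq <- 0
  acc <- function(x) { sq <<- sq + sum(x^2); x }
  tree_map(g, acc)
  nrm <- sqrt(sq)
  if (is.finite(nrm) && nrm > max_norm) {
    g <- tree_map(g, function(x) x * (max_norm / nrm))
  }
  g
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  opt$m <- tree_map2(opt$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  opt$v <- tree_map2(opt$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  upd <- tree_map2(opt$m, opt$v, function(m, v)
    (m / bc1) / (sqrt(v / bc2) + eps))
  params <- tree_map2(params, upd, function(p, u) p - lr * u)
  list(params = params, opt = opt)
}
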