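# One transformer encoder layer (multi-head self-attention + feed-forward,
# both with residual connections and layer normalisation), with manual
# forward/backward passes. Batched token matrices are stored as
# (B*L) x d with item b occupying rows ((b-1)L+1):(bL).
#
# This R implementation owns the training path (it builds the caches the
# backward pass needs); the compiled forward in src/ is used for
# inference and asserted equal in the tests.

LN_EPS <- 1e-5

layernorm_forward <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  y <- xhat * rep(gamma, each = nrow(x)) + rep(beta, each = nrow(x))
  list(y = y, xhat = xhat, inv = inv)
}

layernorm_backward <- function(cache, gamma, dy) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(gamma, each = n)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

attn_layer_init <- function(d, heads, d_ff, rng) {
  stopifnot(d %% heads == 0)
  list(Wq = nn_mat(d, d, rng), Wk = nn_mat(d, d, rng),
       Wv = nn_mat(d, d, rng), Wo = nn_mat(d, d, rng),
       g1 = rep(1, d), b1 = rep(0, d),
       ff1 = dense_init(d, d_ff, rng), ff2 = dense_init(d_ff, d, rng),
       g2 = rep(1, d), b2 = rep(0, d))
}

# numerically stable row softmax of a small score matrix
row_softmax <- function(S) {
  rm_ <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  A <- exp(S - rm_)
  A / .rowSums(A, nrow(S), ncol(S))
}

# x: (B*L) x d batched tokens. Returns output and cache for backward.
attn_layer_forward <- function(x, p, B, L, heads, need_cache = TRUE,
                               sparse_u = NULL) {
  d <- ncol(x); dh <- d %/% heads
  Q <- x %*% p$Wq; K <- x %*% p$Wk; V <- x %*% p$Wv
  Ocat <- matrix(0, nrow(x), d)
  Acache <- if (need_cache) vector("list", B) else NULL
  inv_sq <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    Ab <- if (need_cache) vector("list", heads) else NULL
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qh <- Q[rows, cols, drop = FALSE]
      Kh <- K[rows, cols, drop = FALSE]
      Vh <- V[rows, cols, drop = FALSE]
      S <- tcrossprod(Qh, Kh) * inv_sq
      A <- row_softmax(S)
      if (!is.null(sparse_u) && sparse_u < L) {
        # prob-sparse: keep the top-u queries by the max-minus-mean
        # sparsity score; lazy queries output the mean value vector
        M <- apply(S, 1, max) - rowMeans(S)
        keep <- order(M, decreasing = TRUE)[seq_len(sparse_u)]
        Oh <- matrix(rep(colMeans(Vh), each = L), L, dh)
        Oh[keep, ] <- A[keep, , drop = FALSE] %*% Vh
        Ocat[rows, cols] <- Oh
      } else {
        Ocat[rows, cols] <- A %*% Vh
      }
      if (need_cache) Ab[[h]] <- A
    }
    if (need_cache) Acache[[b]] <- Ab
  }
  O <- Ocat %*% p$Wo
  r1 <- x + O
  ln1 <- layernorm_forward(r1, p$g1, p$b1)
  f1 <- dense_forward(ln1$y, p$ff1)
  a1 <- (f1 > 0) * f1
  f2 <- dense_forward(a1, p$ff2)
  r2 <- ln1$y + f2
  ln2 <- layernorm_forward(r2, p$g2, p$b2)
  out <- list(y = ln2$y)
  if (need_cache) {
    out$cache <- list(x = x, Q = Q, K = K, V = V, A = Acache,
                      O_pre = Ocat, ln1 = ln1, a1 = a1, ln2 = ln2,
                      B = B, L = L, heads = heads)
  }
  out
}

# dense-attention backward; dy: (B*L) x d. Returns dx and parameter grads.
attn_layer_backward <- function(cache, p, dy) {
  B <- cache$B; L <- cache$L; heads <- cache$heads
  d <- ncol(dy); dh <- d %/% heads
  ln2b <- layernorm_backward(cache$ln2, p$g2, dy)
  dr2 <- ln2b$dx
  f2b <- dense_backward(cache$a1, p$ff2, dr2)
  da1 <- f2b$dx * (cache$a1 > 0)
  f1b <- dense_backward(cache$ln1$y, p$ff1, da1)
  dln1y <- dr2 + f1b$dx
  ln1b <- layernorm_backward(cache$ln1, p$g1, dln1y)
  dr1 <- ln1b$dx
  dWo <- crossprod(cache$O_pre, dr1)
  dO <- tcrossprod(dr1, p$Wo)
  dQ <- matrix(0, nrow(dy), d)
  dK <- matrix(0, nrow(dy), d)
  dV <- matrix(0, nrow(dy), d)
  inv_sq <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[b]][[h]]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dOh <- dO[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[rows, cols] <- crossprod(A, dOh)
      dS <- (A * (dA - .rowSums(dA * A, L, L))) * inv_sq
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE]
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE])
    }
  }
  dx <- dr1 + tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) +
    tcrossprod(dV, p$Wv)
  grads <- list(Wq = crossprod(cache$x, dQ), Wk = crossprod(cache$x, dK),
                Wv = crossprod(cache$x, dV), Wo = dWo,
                g1 = ln1b$dgamma, b1 = ln1b$dbeta,
                ff1 = f1b$grads, ff2 = f2b$grads,
                g2 = ln2b$dgamma, b2 = ln2b$dbeta)
  list(dx = dx, grads = grads)
}
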