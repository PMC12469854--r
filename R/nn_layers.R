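# Low-level neural-network primitives for the synergy regressor.
#
# The network is small (a 3-token sequence, d_model <= a few hundred), so the
# forward and backward passes are written directly against BLAS-backed R
# matrix ops rather than binding a deep-learning runtime.  Every layer has a
# hand-derived backward pass; test-nn checks the full gradient against
# central finite differences.

LN_EPS <- 1e-5

addbias <- function(m, b) m + rep(b, each = nrow(m))

relu <- function(x) pmax(x, 0)

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  All stochastic package operations route through this so
# that no user-visible global state is mutated.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# Layer normalization over the feature dimension of a (batch x d) matrix.
ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc / sd
  list(y = addbias(xhat * rep(g, each = nrow(x)), b), xhat = xhat, sd = sd)
}

ln_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * rep(g, each = nrow(dy))
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) / cache$sd
  list(dx = dx, dg = dg, db = db)
}

# Inverted dropout; identity when p == 0 or train == FALSE.
drop_forward <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, mask = NULL))
  mask <- matrix((stats::runif(length(x)) >= p) / (1 - p), nrow(x), ncol(x))
  list(y = x * mask, mask = mask)
}

drop_backward <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# Multi-head self-attention over a fixed 3-token sequence.  H is a list of
# three (batch x d) matrices; returns the projected attention output per
# token plus the cache for the backward pass.
attn_forward <- function(H, blk, n_heads) {
  d <- ncol(H[[1]])
  dh <- d %/% n_heads
  scal <- 1 / sqrt(dh)
  Q <- lapply(H, function(h) addbias(h %*% blk$Wq, blk$bq))
  K <- lapply(H, function(h) addbias(h %*% blk$Wk, blk$bk))
  V <- lapply(H, function(h) addbias(h %*% blk$Wv, blk$bv))
  B <- nrow(H[[1]])
  O <- lapply(1:3, function(i) matrix(0, B, d))
  A <- vector("list", n_heads)         # A[[h]][[i]] = (B x 3) softmax weights
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    A[[h]] <- vector("list", 3)
    for (i in 1:3) {
      S <- vapply(1:3, function(j)
        rowSums(Q[[i]][, idx, drop = FALSE] * K[[j]][, idx, drop = FALSE]) * scal,
        numeric(B))
      S <- matrix(S, B, 3)
      e <- exp(S - apply(S, 1, max))
      Ai <- e / rowSums(e)
      A[[h]][[i]] <- Ai
      acc <- Ai[, 1] * V[[1]][, idx, drop = FALSE]
      acc <- acc + Ai[, 2] * V[[2]][, idx, drop = FALSE]
      acc <- acc + Ai[, 3] * V[[3]][, idx, drop = FALSE]
      O[[i]][, idx] <- acc
    }
  }
  out <- lapply(O, function(o) addbias(o %*% blk$Wo, blk$bo))
  list(out = out, cache = list(H = H, Q = Q, K = K, V = V, O = O, A = A,
                               dh = dh, scal = scal))
}

attn_backward <- function(dout, cache, blk, n_heads) {
  H <- cache$H; Q <- cache$Q; K <- cache$K; V <- cache$V
  dh <- cache$dh; scal <- cache$scal
  B <- nrow(H[[1]]); d <- ncol(H[[1]])
  dWo <- matrix(0, d, d); dbo <- numeric(d)
  dO <- vector("list", 3)
  for (i in 1:3) {
    dWo <- dWo + crossprod(cache$O[[i]], dout[[i]])
    dbo <- dbo + colSums(dout[[i]])
    dO[[i]] <- dout[[i]] %*% t(blk$Wo)
  }
  zero <- function() matrix(0, B, d)
  dQ <- lapply(1:3, function(i) zero())
  dK <- lapply(1:3, function(i) zero())
  dV <- lapply(1:3, function(i) zero())
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    for (i in 1:3) {
      dOi <- dO[[i]][, idx, drop = FALSE]
      Ai <- cache$A[[h]][[i]]
      dA <- vapply(1:3, function(j)
        rowSums(dOi * V[[j]][, idx, drop = FALSE]), numeric(B))
      dA <- matrix(dA, B, 3)
      for (j in 1:3) {
        dV[[j]][, idx] <- dV[[j]][, idx, drop = FALSE] + Ai[, j] * dOi
      }
      dS <- Ai * (dA - rowSums(Ai * dA))
      for (j in 1:3) {
        dQ[[i]][, idx] <- dQ[[i]][, idx, drop = FALSE] +
          dS[, j] * K[[j]][, idx, drop = FALSE] * scal
        dK[[j]][, idx] <- dK[[j]][, idx, drop = FALSE] +
          dS[, j] * Q[[i]][, idx, drop = FALSE] * scal
      }
    }
  }
  dWq <- matrix(0, d, d); dWk <- matrix(0, d, d); dWv <- matrix(0, d, d)
  dbq <- numeric(d); dbk <- numeric(d); dbv <- numeric(d)
  dH <- vector("list", 3)
  for (k in 1:3) {
    dWq <- dWq + crossprod(H[[k]], dQ[[k]])
    dWk <- dWk + crossprod(H[[k]], dK[[k]])
    dWv <- dWv + crossprod(H[[k]], dV[[k]])
    dbq <- dbq + colSums(dQ[[k]])
    dbk <- dbk + colSums(dK[[k]])
    dbv <- dbv + colSums(dV[[k]])
    dH[[k]] <- dQ[[k]] %*% t(blk$Wq) + dK[[k]] %*% t(blk$Wk) +
      dV[[k]] %*% t(blk$Wv)
  }
  list(dH = dH, grads = list(Wq = dWq, bq = dbq, Wk = dWk, bk = dbk,
                             Wv = dWv, bv = dbv, Wo = dWo, bo = dbo))
}

# --- parameter-tree helpers (params, grads and Adam state share structure) ---

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- tree_map(function(m) m / bc1, state$m)
  vh <- tree_map(function(v) v / bc2, state$v)
  upd <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mh, vh)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
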