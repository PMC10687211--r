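# Transformer building blocks on plain BLAS matrix ops, each as a
# forward/backward pair. Forward returns `out` plus the cache its backward
# needs; backward takes the upstream gradient and returns input and
# parameter gradients. Conventions: sequences are rows (n x d); per-row
# (token-wise) broadcasting uses rep(v, each = n).

addBias <- function(M, b) M + rep(b, each = nrow(M))

linFwd <- function(X, W, b) list(out = addBias(X %*% W, b), X = X)

linBwd <- function(dY, cache, W)
  list(dX = tcrossprod(dY, W), dW = crossprod(cache$X, dY), db = colSums(dY))

lnFwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = addBias(xhat * rep(g, each = nrow(X)), b), xhat = xhat, inv = inv)
}

lnBwd <- function(dY, cache, g) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = n)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dX = cache$inv * (dxhat - m1 - xhat * m2),
       dg = colSums(dY * xhat), db = colSums(dY))
}

# Multi-head scaled dot-product attention. Queries from Xq, keys/values
# from Xkv (Xkv == Xq for self-attention, encoder states for
# cross-attention). `mask` is an optional nq x nk logical matrix of
# *allowed* attention edges; it implements both the autoregressive mask and
# the block-diagonal mask that keeps packed mini-batch instances from
# attending across instance boundaries.
rowMaxs <- function(S) S[cbind(seq_len(nrow(S)), max.col(S, "first"))]

attnFwd <- function(Xq, Xkv, p, nHeads, mask = NULL) {
  d <- ncol(Xq)
  dk <- d %/% nHeads
  scale <- 1 / sqrt(dk)
  Q <- addBias(Xq %*% p$Wq, p$bq)
  K <- addBias(Xkv %*% p$Wk, p$bk)
  V <- addBias(Xkv %*% p$Wv, p$bv)
  O <- matrix(0, nrow(Xq), d)
  A <- vector("list", nHeads)
  for (h in seq_len(nHeads)) {
    ix <- ((h - 1L) * dk + 1L):(h * dk)
    S <- tcrossprod(Q[, ix, drop = FALSE], K[, ix, drop = FALSE]) * scale
    if (!is.null(mask)) S[!mask] <- -1e30
    S <- S - rowMaxs(S)
    E <- exp(S)
    A[[h]] <- E / rowSums(E)
    O[, ix] <- A[[h]] %*% V[, ix, drop = FALSE]
  }
  list(out = addBias(O %*% p$Wo, p$bo),
       Q = Q, K = K, V = V, A = A, O = O, Xq = Xq, Xkv = Xkv)
}

attnBwd <- function(dY, cache, p, nHeads) {
  d <- ncol(dY)
  dk <- d %/% nHeads
  scale <- 1 / sqrt(dk)
  dO <- tcrossprod(dY, p$Wo)
  g <- list(Wo = crossprod(cache$O, dY), bo = colSums(dY))
  dQ <- matrix(0, nrow(cache$Q), d)
  dK <- matrix(0, nrow(cache$K), d)
  dV <- matrix(0, nrow(cache$V), d)
  for (h in seq_len(nHeads)) {
    ix <- ((h - 1L) * dk + 1L):(h * dk)
    Ah <- cache$A[[h]]
    dOh <- dO[, ix, drop = FALSE]
    dAh <- tcrossprod(dOh, cache$V[, ix, drop = FALSE])
    dS <- Ah * (dAh - rowSums(dAh * Ah))
    dQ[, ix] <- dS %*% cache$K[, ix, drop = FALSE] * scale
    dK[, ix] <- crossprod(dS, cache$Q[, ix, drop = FALSE]) * scale
    dV[, ix] <- crossprod(Ah, dOh)
  }
  g$Wq <- crossprod(cache$Xq, dQ); g$bq <- colSums(dQ)
  g$Wk <- crossprod(cache$Xkv, dK); g$bk <- colSums(dK)
  g$Wv <- crossprod(cache$Xkv, dV); g$bv <- colSums(dV)
  list(dXq = tcrossprod(dQ, p$Wq),
       dXkv = tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv),
       grads = g)
}

ffnFwd <- function(X, p) {
  pre <- addBias(X %*% p$W1, p$b1)
  mask <- pre > 0
  H <- pre * mask
  list(out = addBias(H %*% p$W2, p$b2), X = X, H = H, mask = mask)
}

ffnBwd <- function(dY, cache, p) {
  dH <- tcrossprod(dY, p$W2) * cache$mask
  list(dX = tcrossprod(dH, p$W1),
       grads = list(W1 = crossprod(cache$X, dH), b1 = colSums(dH),
                    W2 = crossprod(cache$H, dY), b2 = colSums(dY)))
}

dropFwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  m <- (matrix(runif(length(X)), nrow(X)) >= rate) / (1 - rate)
  list(out = X * m, mask = m)
}

dropBwd <- function(dY, cache) if (is.null(cache$mask)) dY else dY * cache$mask

# Softmax cross-entropy over rows of a logit matrix; targets are 1-based
# column indices. Returns mean loss, row-wise log-probabilities, and the
# gradient of the mean loss w.r.t. the logits.
ceFwd <- function(logits, targets, wantGrad = TRUE) {
  n <- nrow(logits)
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  s <- rowSums(e)
  logp <- z - log(s)
  pick <- cbind(seq_len(n), targets)
  loss <- -mean(logp[pick])
  out <- list(loss = loss, logp = logp)
  if (wantGrad) {
    dlog <- e / s
    dlog[pick] <- dlog[pick] - 1
    out$dlogits <- dlog / n
  }
  out
}

# Sinusoidal embedding of scalar time/position values into d dimensions:
# column pair (2i-1, 2i) is (sin, cos) of t / 10000^(2(i-1)/d).
sinusoidalEmbedding <- function(tvals, d) {
  i <- seq_len(d %/% 2L)
  freq <- 1 / 10000^((2 * (i - 1)) / d)
  ang <- outer(tvals, freq)
  E <- matrix(0, length(tvals), d)
  E[, 2L * i - 1L] <- sin(ang)
  E[, 2L * i] <- cos(ang)
  E
}

# --- nested parameter-tree helpers -------------------------------------------

paramPaths <- function(x, prefix = character(0)) {
  if (is.list(x))
    return(unlist(lapply(names(x), function(n)
      paramPaths(x[[n]], c(prefix, n))), recursive = FALSE))
  list(prefix)
}

zeroLike <- function(x) {
  if (is.list(x)) return(lapply(x, zeroLike))
  x * 0
}

treeAdd <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (n in names(b)) a[[n]] <- treeAdd(a[[n]], b[[n]])
    return(a)
  }
  a + b
}

treeGet <- function(x, path) {
  for (n in path) {
    if (!is.list(x) || is.null(x[[n]])) return(NULL)
    x <- x[[n]]
  }
  x
}

treeScale <- function(a, s) {
  if (is.list(a)) return(lapply(a, treeScale, s = s))
  a * s
}
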