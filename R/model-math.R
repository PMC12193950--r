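# Numerical building blocks of the network. Everything here is plain matrix
# code; the backward functions return analytic gradients that are checked
# against finite differences in the test suite.

# additive mask value: most-negative practical number; a literal -Inf would
# propagate NaN through exp() when a whole row is masked
.MASK_NEG <- -1e30
.LN_EPS <- 1e-6

#' Sinusoidal positional-encoding table
#'
#' Entry (pos, 2i) is sin(pos / 10000^(2i / dModel)) and entry (pos, 2i+1)
#' is cos of the same angle, for pos = 0..maxLen-1 and dimension pairs
#' i = 0..dModel/2-1. The per-dimension wavelengths form a geometric
#' progression from 2*pi towards 10000*2*pi. The table is added to (not
#' concatenated with) the token embeddings.
#'
#' @param maxLen number of positions.
#' @param dModel even embedding dimension.
#' @return numeric matrix of shape maxLen x dModel.
#' @export
positionalEncoding <- function(maxLen, dModel) {
  maxLen <- as.integer(maxLen); dModel <- as.integer(dModel)
  if (is.na(maxLen) || maxLen < 1L) stop("maxLen must be >= 1")
  if (is.na(dModel) || dModel < 2L || dModel %% 2L != 0L)
    stop("dModel must be a positive even integer")
  pos <- 0:(maxLen - 1L)
  i2 <- seq.int(0L, dModel - 2L, by = 2L)          # the 2i of each pair
  invFreq <- 10000^(-i2 / dModel)
  ang <- outer(pos, invFreq)                        # maxLen x dModel/2
  pe <- matrix(0, nrow = maxLen, ncol = dModel)
  pe[, i2 + 1L] <- sin(ang)
  pe[, i2 + 2L] <- cos(ang)
  pe
}

# row-wise softmax with additive-mask semantics already applied to s;
# rows whose entries are all ~ .MASK_NEG fall back to uniform (see
# scaledDotProductAttention)
.rowSoftmax <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' Computes softmax(Q K' / sqrt(d_k) + mask) V. The optional mask disallows
#' key positions (padding); disallowed keys receive effectively zero
#' weight. There is no look-ahead structure: both sequences are interpreted
#' as a whole, so only padding is ever masked.
#'
#' If every key is disallowed for some query row, that row's weights fall
#' back to uniform over all keys and a warning is raised; this situation
#' only arises for an entirely-padding stream.
#'
#' @param Q,K,V numeric matrices; Q and K share the inner dimension d_k, K
#'   and V share their row count.
#' @param mask `NULL`, a logical vector over key positions, or a logical
#'   matrix (query x key); `TRUE` = allowed.
#' @return list with `output` (nrow(Q) x ncol(V)) and the attention
#'   `weights` matrix (nrow(Q) x nrow(K)).
#' @export
scaledDotProductAttention <- function(Q, K, V, mask = NULL) {
  if (ncol(Q) != ncol(K)) stop("Q and K must share the inner dimension d_k")
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows")
  s <- (Q %*% t(K)) / sqrt(ncol(K))
  if (!is.null(mask)) {
    if (is.matrix(mask)) {
      if (!identical(dim(mask), dim(s))) stop("mask/stream shape mismatch")
      s[!mask] <- .MASK_NEG
    } else {
      if (length(mask) != nrow(K)) stop("mask length must match key count")
      if (!any(mask)) s[] <- .MASK_NEG else s[, !mask] <- .MASK_NEG
    }
    dead <- rowSums(if (is.matrix(mask)) mask else
                    matrix(mask, nrow(s), ncol(s), byrow = TRUE)) == 0
    if (any(dead)) {
      warning("all keys masked for some query row(s); using uniform weights")
      s[dead, ] <- 0
    }
  }
  a <- .rowSoftmax(s)
  list(output = a %*% V, weights = a)
}

## ---- parameter initialization -------------------------------------------

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nrow = nin, ncol = nout)
}

.initDense <- function(nin, nout) list(W = .glorot(nin, nout),
                                       b = numeric(nout))

.initMHA <- function(d) list(q = .initDense(d, d), k = .initDense(d, d),
                             v = .initDense(d, d), o = .initDense(d, d))

.initLN <- function(d) list(g = rep(1, d), b = numeric(d))

## ---- layer normalization -------------------------------------------------

# x: n x d; normalizes each row over the feature axis (biased variance)
.lnForward <- function(x, p) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + .LN_EPS)
  xhat <- xc * inv
  list(y = sweep(xhat * p$g[col(xhat)], 2L, p$b, "+"),
       xhat = xhat, inv = inv)
}

.lnBackward <- function(dy, cache, p) {
  xhat <- cache$xhat
  dxhat <- dy * p$g[col(dy)]
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

## ---- multi-head attention over a batch of equal-length streams -----------

# Xq: (B*Lq) x d stacked query streams (sample-major), Xkv: (B*Lk) x d,
# keyMask: B x Lk logical. The linear projections are single large matrix
# products; the per-sample attention runs in the compiled kernel.
.mhaForward <- function(Xq, Xkv, keyMask, B, Lq, Lk, p, nh) {
  Q <- Xq %*% p$q$W; Q <- sweep(Q, 2L, p$q$b, "+")
  K <- Xkv %*% p$k$W; K <- sweep(K, 2L, p$k$b, "+")
  V <- Xkv %*% p$v$W; V <- sweep(V, 2L, p$v$b, "+")
  C <- mhaAttendFwd(Q, K, V, .maskInt(keyMask), B, Lq, Lk, nh)
  out <- C %*% p$o$W
  out <- sweep(out, 2L, p$o$b, "+")
  list(out = out, Q = Q, K = K, V = V, C = C)
}

.maskInt <- function(m) {
  storage.mode(m) <- "integer"
  m
}

# recomputes attention weights from the cached projections instead of
# storing B*Lq x Lk matrices per head (memory stays O(B*L*d))
.mhaBackward <- function(dOut, Xq, Xkv, keyMask, B, Lq, Lk, p, nh, cache) {
  Q <- cache$Q; K <- cache$K; V <- cache$V
  dWo <- crossprod(cache$C, dOut)
  dbo <- colSums(dOut)
  dC <- dOut %*% t(p$o$W)
  kb <- mhaAttendBwd(dC, Q, K, V, .maskInt(keyMask), B, Lq, Lk, nh)
  dQ <- kb$dQ; dK <- kb$dK; dV <- kb$dV
  list(dXq = dQ %*% t(p$q$W),
       dXkv = dK %*% t(p$k$W) + dV %*% t(p$v$W),
       grads = list(q = list(W = crossprod(Xq, dQ), b = colSums(dQ)),
                    k = list(W = crossprod(Xkv, dK), b = colSums(dK)),
                    v = list(W = crossprod(Xkv, dV), b = colSums(dV)),
                    o = list(W = dWo, b = dbo)))
}

## ---- position-wise dense projection (two dense layers, GELU hidden) ------

# GELU (exact, via the normal CDF): smooth, no dead region. A hard ReLU
# here lets the whole hidden layer die at small scale (the pooled stream
# is nearly constant across samples, so units die for all samples at
# once); GELU keeps gradients flowing.
.gelu <- function(z) z * stats::pnorm(z)
.geluGrad <- function(z) stats::pnorm(z) + z * stats::dnorm(z)

.ffnForward <- function(x, p) {
  z <- sweep(x %*% p$W1, 2L, p$b1, "+")
  h <- .gelu(z)
  y <- sweep(h %*% p$W2, 2L, p$b2, "+")
  list(y = y, h = h, z = z)
}

.ffnBackward <- function(dy, x, cache, p) {
  dh <- (dy %*% t(p$W2)) * .geluGrad(cache$z)
  list(dx = dh %*% t(p$W1),
       grads = list(W1 = crossprod(x, dh), b1 = colSums(dh),
                    W2 = crossprod(cache$h, dy), b2 = colSums(dy)))
}
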