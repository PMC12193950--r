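#' Architectural configuration for the binding model
#'
#' All hyperparameters of the dual-stream attention network. The per-head
#' key/query dimension is `dModel / numHeads` (values use the same
#' dimension). Defaults are deliberately modest: the architecture itself,
#' not capacity, carries the signal for seed-driven binding.
#'
#' @param dModel token embedding / per-position feature dimension
#'   (default 64, even, divisible by `numHeads`).
#' @param numHeads attention heads (default 4).
#' @param dDense hidden width of the position-wise dense projection
#'   (default 128).
#' @param nCores number of cascaded core blocks (default 1).
#' @param maxK maximum k-mer size for tokenization (default 3).
#' @param useSelfAttention apply self-attention to each stream before
#'   cross-attention (default TRUE); FALSE gives the cross-attention-only
#'   variant with exactly one attention module and two add-and-normalize
#'   stages per core.
#' @param useBackwardKmers interleave reversed k-mer copies (default FALSE).
#' @param symmetricCores also cross-update the target-side stream in each
#'   core (default FALSE: the target stream is self-attended and carried
#'   forward unchanged).
#' @param complementInput which input is base-wise complemented before
#'   tokenization ("pirna" by default; "mrna" or "none").
#' @param queryInput which input drives the attention queries and the
#'   pooled classification stream ("pirna" by default, the shorter
#'   targeting sequence).
#' @param pooling "global_average" (over real tokens only, default) or
#'   "global_max".
#' @param dropoutRate dropout on the pooled vector during training
#'   (default 0.3).
#' @param headWidths widths of the three output dense layers
#'   (default c(64, 32, 1); the last must be 1).
#' @param maxLenA,maxLenB padded token-stream lengths; `NA` (default) uses
#'   the longest stream observed at tokenization time.
#' @param seed RNG seed for weight initialization (default 1).
#' @return a [ModelConfig].
#' @export
modelConfig <- function(dModel = 64L, numHeads = 4L, dDense = 128L,
                        nCores = 1L, maxK = 3L, useSelfAttention = TRUE,
                        useBackwardKmers = FALSE, symmetricCores = FALSE,
                        complementInput = "pirna", queryInput = "pirna",
                        pooling = "global_average", dropoutRate = 0.3,
                        headWidths = c(64L, 32L, 1L),
                        maxLenA = NA_integer_, maxLenB = NA_integer_,
                        seed = 1L) {
  new("ModelConfig", dModel = as.integer(dModel),
      numHeads = as.integer(numHeads), dDense = as.integer(dDense),
      nCores = as.integer(nCores), maxK = as.integer(maxK),
      useSelfAttention = isTRUE(useSelfAttention),
      useBackwardKmers = isTRUE(useBackwardKmers),
      symmetricCores = isTRUE(symmetricCores),
      complementInput = complementInput, queryInput = queryInput,
      pooling = pooling, dropoutRate = as.numeric(dropoutRate),
      headWidths = as.integer(headWidths),
      maxLenA = as.integer(maxLenA), maxLenB = as.integer(maxLenB),
      seed = as.integer(seed))
}

#' Tokenize a labeled pair dataset for the model
#'
#' Applies the complement conversion to the configured input, extracts the
#' hierarchical k-mer list of every sequence, encodes it against `vocab`,
#' and pads each stream side to a common length. The query side ("a") is
#' the configured `queryInput` sequence.
#'
#' @param pairs data.frame with columns `pirna`, `mrna`, `label`.
#' @param vocab a [KmerVocabulary] (its `maxK` must be at least the
#'   config's).
#' @param config a [ModelConfig].
#' @return a [TokenizedPairs].
#' @export
tokenizePairs <- function(pairs, vocab, config) {
  stopifnot(is.data.frame(pairs),
            all(c("pirna", "mrna", "label") %in% names(pairs)))
  if (vocab@maxK < config@maxK)
    stop("vocabulary maxK is smaller than the model's maxK")
  pirna <- vapply(pairs$pirna, normalizeSequence, character(1L),
                  USE.NAMES = FALSE)
  mrna <- vapply(pairs$mrna, normalizeSequence, character(1L),
                 USE.NAMES = FALSE)
  if (config@complementInput == "pirna")
    pirna <- vapply(pirna, complementSequence, character(1L),
                    USE.NAMES = FALSE)
  else if (config@complementInput == "mrna")
    mrna <- vapply(mrna, complementSequence, character(1L), USE.NAMES = FALSE)
  if (config@queryInput == "pirna") { aSeq <- pirna; bSeq <- mrna }
  else { aSeq <- mrna; bSeq <- pirna }
  tok <- function(seqs) lapply(seqs, function(s)
    encodeKmers(extractKmers(s, config@maxK, config@useBackwardKmers), vocab))
  aStreams <- tok(aSeq)
  bStreams <- tok(bSeq)
  lenA <- if (is.na(config@maxLenA)) max(lengths(aStreams)) else config@maxLenA
  lenB <- if (is.na(config@maxLenB)) max(lengths(bStreams)) else config@maxLenB
  new("TokenizedPairs",
      a = padBatch(aStreams, lenA), b = padBatch(bStreams, lenB),
      labels = as.numeric(pairs$label))
}

#' Build an untrained binding model
#'
#' Creates the full parameter set: one embedding table per stream, the
#' cascaded core blocks (self-attention, cross-attention, dense projection,
#' add-and-normalize stages), and the pooled three-layer classification
#' head ending in a sigmoid. Weights are Glorot-uniform, seeded by the
#' config, so identical configs give identical models.
#'
#' @param vocabA,vocabB the [KmerVocabulary] of the query and target
#'   streams (usually the same object).
#' @param config a [ModelConfig].
#' @return an [RbpTransformer].
#' @export
buildModel <- function(vocabA, vocabB, config) {
  stopifnot(is(vocabA, "KmerVocabulary"), is(vocabB, "KmerVocabulary"),
            is(config, "ModelConfig"))
  validObject(config)
  d <- config@dModel
  params <- withr::with_seed(config@seed, {
    p <- list(
      embA = matrix(stats::runif(vocabSize(vocabA) * d, -0.05, 0.05),
                    ncol = d),
      embB = matrix(stats::runif(vocabSize(vocabB) * d, -0.05, 0.05),
                    ncol = d),
      cores = lapply(seq_len(config@nCores), function(j) {
        core <- list()
        if (config@useSelfAttention) {
          core$selfA <- .initMHA(d); core$lnSA <- .initLN(d)
          core$selfB <- .initMHA(d); core$lnSB <- .initLN(d)
        }
        core$cross <- .initMHA(d); core$lnC <- .initLN(d)
        core$ffn <- list(W1 = .glorot(d, config@dDense),
                         b1 = numeric(config@dDense),
                         W2 = .glorot(config@dDense, d), b2 = numeric(d))
        core$lnF <- .initLN(d)
        if (config@symmetricCores) {
          core$crossB <- .initMHA(d); core$lnCB <- .initLN(d)
          core$ffnB <- list(W1 = .glorot(d, config@dDense),
                            b1 = numeric(config@dDense),
                            W2 = .glorot(config@dDense, d), b2 = numeric(d))
          core$lnFB <- .initLN(d)
        }
        core
      }),
      head = {
        w <- config@headWidths
        list(W1 = .glorot(d, w[1L]), b1 = numeric(w[1L]),
             W2 = .glorot(w[1L], w[2L]), b2 = numeric(w[2L]),
             W3 = .glorot(w[2L], w[3L]), b3 = numeric(w[3L]))
      })
    p
  })
  new("RbpTransformer", config = config, vocabA = vocabA, vocabB = vocabB,
      params = params, nParams = .countParams(params), trained = FALSE,
      history = NULL)
}

.countParams <- function(p) {
  if (is.list(p)) sum(vapply(p, .countParams, numeric(1L))) else length(p)
}

#' Number of trainable parameters
#'
#' @param model an [RbpTransformer].
#' @return total count of trainable scalars.
#' @export
nParams <- function(model) model@nParams

#' Per-epoch training history
#'
#' @param model a trained [RbpTransformer].
#' @return `data.frame` of per-epoch losses and accuracies, or `NULL` for
#'   an untrained model.
#' @export
trainingHistory <- function(model) model@history

#' @export
setMethod("show", "RbpTransformer", function(object) {
  cfg <- object@config
  cat(sprintf(
    "RbpTransformer: %d core(s), d_model=%d, %d head(s), maxK=%d\n",
    cfg@nCores, cfg@dModel, cfg@numHeads, cfg@maxK))
  cat(sprintf("  self-attention: %s | backward k-mers: %s | pooling: %s\n",
              cfg@useSelfAttention, cfg@useBackwardKmers, cfg@pooling))
  cat(sprintf("  trainable parameters: %d | trained: %s\n",
              as.integer(object@nParams), object@trained))
})

#' @export
setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: d_model=%d heads=%d cores=%d maxK=%d selfAttn=%s\n",
    object@dModel, object@numHeads, object@nCores, object@maxK,
    object@useSelfAttention))
})

## ---- forward / backward composition --------------------------------------

.coreForward <- function(Xa, Xb, maskA, maskB, B, La, Lb, p, cfg) {
  nh <- cfg@numHeads
  cache <- list(Xa = Xa, Xb = Xb)
  if (cfg@useSelfAttention) {
    sa <- .mhaForward(Xa, Xa, maskA, B, La, La, p$selfA, nh)
    lnA <- .lnForward(Xa + sa$out, p$lnSA); a1 <- lnA$y
    sb <- .mhaForward(Xb, Xb, maskB, B, Lb, Lb, p$selfB, nh)
    lnB <- .lnForward(Xb + sb$out, p$lnSB); b1 <- lnB$y
    cache$sa <- sa; cache$lnA <- lnA; cache$sb <- sb; cache$lnB <- lnB
  } else {
    a1 <- Xa; b1 <- Xb
  }
  ca <- .mhaForward(a1, b1, maskB, B, La, Lb, p$cross, nh)
  lnC <- .lnForward(a1 + ca$out, p$lnC); c1 <- lnC$y
  ff <- .ffnForward(c1, p$ffn)
  lnF <- .lnForward(c1 + ff$y, p$lnF); aOut <- lnF$y
  cache$a1 <- a1; cache$b1 <- b1; cache$ca <- ca; cache$lnC <- lnC
  cache$c1 <- c1; cache$ff <- ff; cache$lnF <- lnF
  if (cfg@symmetricCores) {
    cb <- .mhaForward(b1, a1, maskA, B, Lb, La, p$crossB, nh)
    lnCB <- .lnForward(b1 + cb$out, p$lnCB); c2 <- lnCB$y
    ffB <- .ffnForward(c2, p$ffnB)
    lnFB <- .lnForward(c2 + ffB$y, p$lnFB); bOut <- lnFB$y
    cache$cb <- cb; cache$lnCB <- lnCB; cache$c2 <- c2
    cache$ffB <- ffB; cache$lnFB <- lnFB
  } else {
    bOut <- b1
  }
  list(aOut = aOut, bOut = bOut, cache = cache)
}

.coreBackward <- function(dAout, dBout, cache, maskA, maskB, B, La, Lb,
                          p, cfg) {
  nh <- cfg@numHeads
  g <- list()
  if (cfg@symmetricCores) {
    tFB <- .lnBackward(dBout, cache$lnFB, p$lnFB)
    fb <- .ffnBackward(tFB$dx, cache$c2, cache$ffB, p$ffnB)
    dc2 <- tFB$dx + fb$dx
    tCB <- .lnBackward(dc2, cache$lnCB, p$lnCB)
    mb <- .mhaBackward(tCB$dx, cache$b1, cache$a1, maskA, B, Lb, La,
                       p$crossB, nh, cache$cb)
    db1 <- tCB$dx + mb$dXq
    da1Extra <- mb$dXkv
    g$crossB <- mb$grads
    g$lnCB <- list(g = tCB$dg, b = tCB$db)
    g$ffnB <- fb$grads
    g$lnFB <- list(g = tFB$dg, b = tFB$db)
  } else {
    db1 <- dBout
    da1Extra <- 0
  }
  tF <- .lnBackward(dAout, cache$lnF, p$lnF)
  fB <- .ffnBackward(tF$dx, cache$c1, cache$ff, p$ffn)
  dc1 <- tF$dx + fB$dx
  tC <- .lnBackward(dc1, cache$lnC, p$lnC)
  mA <- .mhaBackward(tC$dx, cache$a1, cache$b1, maskB, B, La, Lb,
                     p$cross, nh, cache$ca)
  da1 <- tC$dx + mA$dXq + da1Extra
  db1 <- db1 + mA$dXkv
  g$cross <- mA$grads
  g$lnC <- list(g = tC$dg, b = tC$db)
  g$ffn <- fB$grads
  g$lnF <- list(g = tF$dg, b = tF$db)
  if (cfg@useSelfAttention) {
    tA <- .lnBackward(da1, cache$lnA, p$lnSA)
    mSA <- .mhaBackward(tA$dx, cache$Xa, cache$Xa, maskA, B, La, La,
                        p$selfA, nh, cache$sa)
    dXa <- tA$dx + mSA$dXq + mSA$dXkv
    tB <- .lnBackward(db1, cache$lnB, p$lnSB)
    mSB <- .mhaBackward(tB$dx, cache$Xb, cache$Xb, maskB, B, Lb, Lb,
                        p$selfB, nh, cache$sb)
    dXb <- tB$dx + mSB$dXq + mSB$dXkv
    g$selfA <- mSA$grads; g$lnSA <- list(g = tA$dg, b = tA$db)
    g$selfB <- mSB$grads; g$lnSB <- list(g = tB$dg, b = tB$db)
  } else {
    dXa <- da1
    dXb <- db1
  }
  # reorder gradients to mirror the parameter layout exactly
  ord <- names(p)
  list(dXa = dXa, dXb = dXb, grads = g[ord])
}

# Forward pass over one padded batch.
# idsA/idsB: B x L integer matrices (0-based ids); maskA/maskB logical.
.forwardPass <- function(params, cfg, idsA, maskA, idsB, maskB, peA, peB,
                         training = FALSE, dropMask = NULL,
                         keepCaches = FALSE) {
  B <- nrow(idsA); La <- ncol(idsA); Lb <- ncol(idsB)
  d <- cfg@dModel
  flatA <- as.vector(t(idsA)) + 1L
  flatB <- as.vector(t(idsB)) + 1L
  # embeddings are scaled by sqrt(d_model) before the positional encoding
  # is added, so token identity is not drowned by the unit-amplitude
  # sinusoids (the standard transformer convention)
  embScale <- sqrt(d)
  Xa <- params$embA[flatA, , drop = FALSE] * embScale +
    peA[rep(seq_len(La), times = B), , drop = FALSE]
  Xb <- params$embB[flatB, , drop = FALSE] * embScale +
    peB[rep(seq_len(Lb), times = B), , drop = FALSE]
  coreCaches <- if (keepCaches) vector("list", cfg@nCores) else NULL
  for (j in seq_len(cfg@nCores)) {
    cf <- .coreForward(Xa, Xb, maskA, maskB, B, La, Lb,
                       params$cores[[j]], cfg)
    if (keepCaches) coreCaches[[j]] <- cf$cache
    Xa <- cf$aOut; Xb <- cf$bOut
  }
  # pooling over the query stream's real tokens
  grp <- rep(seq_len(B), each = La)
  mvec <- as.numeric(as.vector(t(maskA)))
  nReal <- rowSums(maskA)
  if (cfg@pooling == "global_average") {
    P <- rowsum(Xa * mvec, grp) / nReal
    poolCache <- list(mvec = mvec, nReal = nReal)
  } else {
    P <- matrix(0, B, d)
    argIdx <- matrix(0L, B, d)
    for (i in seq_len(B)) {
      rows <- ((i - 1L) * La + 1L):(i * La)
      rows <- rows[maskA[i, ]]
      sub <- Xa[rows, , drop = FALSE]
      w <- max.col(t(sub), ties.method = "first")
      argIdx[i, ] <- rows[w]
      P[i, ] <- sub[cbind(w, seq_len(d))]
    }
    poolCache <- list(argIdx = argIdx)
  }
  Pd <- P
  if (training && cfg@dropoutRate > 0) {
    if (is.null(dropMask))
      dropMask <- matrix((stats::runif(B * d) >= cfg@dropoutRate) /
                           (1 - cfg@dropoutRate), B, d)
    Pd <- P * dropMask
  }
  h <- params$head
  z1 <- sweep(Pd %*% h$W1, 2L, h$b1, "+")
  h1 <- .gelu(z1)
  z2 <- sweep(h1 %*% h$W2, 2L, h$b2, "+")
  h2 <- .gelu(z2)
  z <- sweep(h2 %*% h$W3, 2L, h$b3, "+")
  prob <- 1 / (1 + exp(-z))
  res <- list(prob = as.vector(prob), logit = as.vector(z))
  if (keepCaches) {
    res$caches <- list(coreCaches = coreCaches, XaOut = Xa,
                       pool = poolCache, P = P, Pd = Pd,
                       dropMask = if (training && cfg@dropoutRate > 0)
                         dropMask else NULL,
                       h1 = h1, h2 = h2, z1 = z1, z2 = z2,
                       flatA = flatA, flatB = flatB,
                       B = B, La = La, Lb = Lb)
  }
  res
}

# Backward pass; dz is dLoss/dlogit (length B). Returns gradients with the
# same nested structure as params.
.backwardPass <- function(dz, params, cfg, maskA, maskB, caches) {
  cc <- caches
  B <- cc$B; La <- cc$La; Lb <- cc$Lb
  d <- cfg@dModel
  h <- params$head
  dz <- matrix(dz, ncol = 1L)
  dW3 <- crossprod(cc$h2, dz); db3 <- colSums(dz)
  dh2 <- (dz %*% t(h$W3)) * .geluGrad(cc$z2)
  dW2 <- crossprod(cc$h1, dh2); db2 <- colSums(dh2)
  dh1 <- (dh2 %*% t(h$W2)) * .geluGrad(cc$z1)
  dW1 <- crossprod(cc$Pd, dh1); db1 <- colSums(dh1)
  dPd <- dh1 %*% t(h$W1)
  dP <- if (!is.null(cc$dropMask)) dPd * cc$dropMask else dPd
  # un-pool into the query stream
  dXa <- matrix(0, B * La, d)
  if (cfg@pooling == "global_average") {
    grp <- rep(seq_len(B), each = La)
    dXa <- (dP / cc$pool$nReal)[grp, , drop = FALSE] * cc$pool$mvec
  } else {
    for (jcol in seq_len(d))
      dXa[cbind(cc$pool$argIdx[, jcol], jcol)] <-
        dXa[cbind(cc$pool$argIdx[, jcol], jcol)] + dP[, jcol]
  }
  dXb <- matrix(0, B * Lb, d)
  coreGrads <- vector("list", cfg@nCores)
  for (j in rev(seq_len(cfg@nCores))) {
    cb <- .coreBackward(dXa, dXb, cc$coreCaches[[j]], maskA, maskB,
                        B, La, Lb, params$cores[[j]], cfg)
    dXa <- cb$dXa; dXb <- cb$dXb
    coreGrads[[j]] <- cb$grads
  }
  embScale <- sqrt(d)
  dEmbA <- matrix(0, nrow(params$embA), d)
  gA <- rowsum(dXa, cc$flatA)
  dEmbA[as.integer(rownames(gA)), ] <- gA * embScale
  dEmbB <- matrix(0, nrow(params$embB), d)
  gB <- rowsum(dXb, cc$flatB)
  dEmbB[as.integer(rownames(gB)), ] <- gB * embScale
  list(embA = dEmbA, embB = dEmbB, cores = coreGrads,
       head = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                   W3 = dW3, b3 = db3))
}

#' Predict binding probabilities for tokenized pairs
#'
#' Runs the forward pass in inference mode (no dropout) over minibatches.
#'
#' @param model an [RbpTransformer].
#' @param data a [TokenizedPairs] tokenized with a compatible config.
#' @param batchSize forward-pass batch size.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predictPairs <- function(model, data, batchSize = 256L) {
  stopifnot(is(model, "RbpTransformer"), is(data, "TokenizedPairs"))
  cfg <- model@config
  peA <- positionalEncoding(ncol(data@a@ids), cfg@dModel)
  peB <- positionalEncoding(ncol(data@b@ids), cfg@dModel)
  n <- length(data@labels)
  out <- numeric(n)
  starts <- seq(1L, n, by = batchSize)
  for (s in starts) {
    idx <- s:min(s + batchSize - 1L, n)
    fw <- .forwardPass(model@params, cfg,
                       data@a@ids[idx, , drop = FALSE],
                       data@a@mask[idx, , drop = FALSE],
                       data@b@ids[idx, , drop = FALSE],
                       data@b@mask[idx, , drop = FALSE],
                       peA, peB, training = FALSE)
    out[idx] <- fw$prob
  }
  out
}

#' @describeIn predictPairs `predict` method delegating to `predictPairs()`.
#' @param object an [RbpTransformer].
#' @param ... passed on to `predictPairs()`.
#' @export
setMethod("predict", "RbpTransformer",
          function(object, data, ...) predictPairs(object, data, ...))
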