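# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# brute-force double-loop k-mer enumerator (ascending k, positional order)
bruteForceKmers <- function(seq, maxK) {
  out <- character(0)
  L <- nchar(seq)
  for (k in seq_len(min(maxK, L))) {
    for (s in seq_len(L - k + 1L)) {
      out <- c(out, substr(seq, s, s + k - 1L))
    }
  }
  out
}

# loop-based evaluation of softmax(QK'/sqrt(dk))V, one query row at a time
loopAttentionOracle <- function(Q, K, V, allowed = NULL) {
  dk <- ncol(K)
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    if (!is.null(allowed)) s[!allowed] <- -Inf
    w <- exp(s - max(s))
    w <- w / sum(w)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

randomSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a tiny balanced pair set with an obvious planted rule, for fast training
# sanity checks
tinyPairSet <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    pos <- replicate(n / 2, {
      p <- randomSeq(12)
      m <- randomSeq(30)
      w <- substr(p, 3, 10)
      substr(m, 11, 18) <- complementSequence(w)
      c(p, m)
    })
    neg <- replicate(n / 2, c(randomSeq(12), randomSeq(30)))
    df <- data.frame(pirna = c(pos[1, ], neg[1, ]),
                     mrna = c(pos[2, ], neg[2, ]),
                     label = rep(c(1L, 0L), each = n / 2))
    df[sample.int(n), ]
  })
}
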