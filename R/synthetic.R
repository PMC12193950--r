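#' Configuration of the synthetic CLASH-like pair generator
#'
#' The generator emulates the structure of chimeric-read interaction
#' datasets: short piRNA-like sequences paired with longer mRNA fragments,
#' balanced classes, positives carrying a planted base-wise complementary
#' seed region. Defaults: 21-nt piRNAs (typical piRNA length range is
#' ~21-31 nt), 60-nt mRNA fragments, a 10-nt perfect seed, negatives
#' rejection-sampled below a 7-nt complementary run.
#'
#' @param nPairs even total number of pairs, half per class (default 1000).
#' @param pirnaLen piRNA length in nt (default 21).
#' @param mrnaLen mRNA fragment length in nt (default 60).
#' @param seedLen planted complementary region length (default 10).
#' @param nMismatches substitutions inside the planted region (default 0).
#' @param negMaxRun negatives must have longest complementary run strictly
#'   below this (default `seedLen - 3`).
#' @param gcContent expected G+C fraction (default 0.45, a typical
#'   transcriptome-scale value).
#' @param seed RNG seed (default 1).
#' @return a [SyntheticConfig].
#' @export
syntheticConfig <- function(nPairs = 1000L, pirnaLen = 21L, mrnaLen = 60L,
                            seedLen = 10L, nMismatches = 0L,
                            negMaxRun = seedLen - 3L, gcContent = 0.45,
                            seed = 1L) {
  new("SyntheticConfig", nPairs = as.integer(nPairs),
      pirnaLen = as.integer(pirnaLen), mrnaLen = as.integer(mrnaLen),
      seedLen = as.integer(seedLen), nMismatches = as.integer(nMismatches),
      negMaxRun = as.integer(negMaxRun), gcContent = as.numeric(gcContent),
      seed = as.integer(seed))
}

.randomSequence <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Longest base-wise complementary run between two sequences
#'
#' Exhaustively scans every alignment offset for the longest stretch of
#' consecutive positions where the first sequence's base complements
#' (A-T / G-C) the second's. This is the brute-force ground truth the
#' generator and the oracle classifier are built on; no G-U wobble, no
#' bulges.
#'
#' @param s1,s2 normalized sequences.
#' @return integer length of the longest complementary run.
#' @export
longestComplementRun <- function(s1, s2) {
  c1 <- strsplit(complementSequence(s1), "", fixed = TRUE)[[1]]
  c2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  m <- outer(c1, c2, "==")
  n1 <- length(c1); n2 <- length(c2)
  best <- 0L
  for (off in (-(n1 - 1L)):(n2 - 1L)) {
    i <- max(1L, 1L - off):min(n1, n2 - off)
    diag <- m[cbind(i, i + off)]
    if (any(diag)) {
      r <- rle(diag)
      best <- max(best, max(r$lengths[r$values]))
    }
  }
  best
}

#' Generate one labeled synthetic pair
#'
#' Positives: a random piRNA is drawn, a window of `seedLen` is chosen,
#' and the base-wise complement of that window (with `nMismatches` random
#' substitutions) is embedded at a random offset in an otherwise random
#' mRNA. Negatives: both sequences are drawn at random and
#' rejection-sampled until their longest complementary run is below
#' `negMaxRun`. Uses the caller's RNG state.
#'
#' @param positive logical; generate a binding pair?
#' @param cfg a [SyntheticConfig].
#' @return one-row data.frame with columns `pirna`, `mrna`, `label`,
#'   `seedStart`, `targetStart` (provenance columns are `NA` for
#'   negatives).
#' @export
generatePair <- function(positive, cfg = syntheticConfig()) {
  stopifnot(is(cfg, "SyntheticConfig"))
  gc <- cfg@gcContent
  if (positive) {
    pirna <- .randomSequence(cfg@pirnaLen, gc)
    sStart <- sample.int(cfg@pirnaLen - cfg@seedLen + 1L, 1L)
    window <- substr(pirna, sStart, sStart + cfg@seedLen - 1L)
    planted <- complementSequence(window)
    if (cfg@nMismatches > 0L) {
      ch <- strsplit(planted, "", fixed = TRUE)[[1]]
      pos <- sample.int(cfg@seedLen, cfg@nMismatches)
      for (p in pos)
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      planted <- paste(ch, collapse = "")
    }
    mrna <- .randomSequence(cfg@mrnaLen, gc)
    tStart <- sample.int(cfg@mrnaLen - cfg@seedLen + 1L, 1L)
    substr(mrna, tStart, tStart + cfg@seedLen - 1L) <- planted
    data.frame(pirna = pirna, mrna = mrna, label = 1L,
               seedStart = sStart, targetStart = tStart)
  } else {
    for (attempt in seq_len(10000L)) {
      pirna <- .randomSequence(cfg@pirnaLen, gc)
      mrna <- .randomSequence(cfg@mrnaLen, gc)
      if (longestComplementRun(pirna, mrna) < cfg@negMaxRun)
        return(data.frame(pirna = pirna, mrna = mrna, label = 0L,
                          seedStart = NA_integer_,
                          targetStart = NA_integer_))
    }
    stop("rejection sampling exceeded 10000 attempts; loosen negMaxRun")
  }
}

#' Generate a balanced synthetic dataset
#'
#' Draws `nPairs/2` positives and `nPairs/2` negatives with the configured
#' seed and shuffles them; the same config reproduces the identical
#' dataset.
#'
#' @param cfg a [SyntheticConfig].
#' @return data.frame of labeled pairs with provenance columns (see
#'   [generatePair()]).
#' @export
generateDataset <- function(cfg = syntheticConfig()) {
  stopifnot(is(cfg, "SyntheticConfig"))
  validObject(cfg)
  withr::with_seed(cfg@seed, {
    half <- cfg@nPairs %/% 2L
    rows <- c(lapply(seq_len(half), function(i) generatePair(TRUE, cfg)),
              lapply(seq_len(half), function(i) generatePair(FALSE, cfg)))
    out <- do.call(rbind, rows)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Exact complementarity oracle classifier
#'
#' Predicts binding iff the longest base-wise complementary run between
#' the two sequences reaches `runThreshold`. On data from
#' [generateDataset()] with `nMismatches = 0` and
#' `runThreshold = seedLen`, the oracle is exact by construction; it
#' certifies class separability independently of any trained model.
#'
#' @param pirna,mrna normalized sequences, or a data.frame of pairs as
#'   first argument.
#' @param runThreshold minimum run length called as binding.
#' @return predicted label(s) in \{0, 1\}.
#' @export
oracleClassify <- function(pirna, mrna = NULL, runThreshold) {
  if (is.data.frame(pirna)) {
    df <- pirna
    return(vapply(seq_len(nrow(df)), function(i)
      oracleClassify(df$pirna[i], df$mrna[i], runThreshold = runThreshold),
      integer(1L)))
  }
  as.integer(longestComplementRun(pirna, mrna) >= runThreshold)
}

#' @export
setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d pairs, piRNA %dnt / mRNA %dnt, seed region %dnt (%d mismatches), neg run < %d, GC %.2f\n",
    object@nPairs, object@pirnaLen, object@mrnaLen, object@seedLen,
    object@nMismatches, object@negMaxRun, object@gcContent))
})
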