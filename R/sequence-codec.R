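#' Normalize a raw nucleotide string
#'
#' Strips whitespace, uppercases, and replaces U by T so that RNA and DNA
#' spellings tokenize identically. Any character outside the nucleotide
#' alphabet is rejected with a diagnostic naming its position.
#'
#' @param raw a single character string.
#' @return the normalized sequence (a character scalar over A/C/G/T).
#' @examples
#' normalizeSequence("uagu")  # "TAGT"
#' @export
normalizeSequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop("raw must be a single character string")
  s <- chartr("u", "t", gsub("\\s+", "", raw))
  s <- chartr("acgtu", "ACGTU", s)
  s <- chartr("U", "T", s)
  if (!nzchar(s)) stop("sequence is empty after removing whitespace")
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L)
    stop(sprintf("invalid character %s at position %d",
                 substr(s, bad, bad), bad))
  s
}

#' Base-wise complement of a nucleotide sequence
#'
#' Replaces A<->T and G<->C position by position, preserving order (this is
#' not a reverse complement). Applied to one of the two inputs before
#' tokenization so that k-mers able to base-pair receive the same token id.
#'
#' @param seq a normalized sequence (see [normalizeSequence()]).
#' @return the complemented sequence, same length.
#' @examples
#' complementSequence("TAGTTTCT")  # "ATCAAAGA"
#' @export
complementSequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L)
    stop("seq must be a single character string")
  if (grepl("[^ACGT]", seq))
    stop("seq must be normalized first (A/C/G/T only)")
  chartr("ACGT", "TGCA", seq)
}

.reverseStrings <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L))
}

#' Hierarchical k-mer extraction
#'
#' Enumerates every k-mer of the sequence for k = 1..`maxK` in ascending
#' order of k, left to right within each k (high-order k-mers cover the
#' low-order ones). With `includeBackward = TRUE`, each k-mer longer than
#' one nucleotide is immediately followed by its character-reversed copy.
#'
#' @param seq a normalized sequence.
#' @param maxK maximum k-mer length; may exceed the sequence length, in
#'   which case the higher-order groups are simply empty.
#' @param includeBackward interleave reversed copies of k-mers of length
#'   greater than 1.
#' @return character vector of k-mers in canonical order.
#' @examples
#' extractKmers("GCATTACG", 3)
#' extractKmers("ATGCA", 3, includeBackward = TRUE)
#' @export
extractKmers <- function(seq, maxK, includeBackward = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("seq must be a non-empty sequence")
  if (grepl("[^ACGT]", seq)) stop("seq must be normalized (A/C/G/T only)")
  maxK <- as.integer(maxK)
  if (is.na(maxK) || maxK < 1L) stop("maxK must be >= 1")
  L <- nchar(seq)
  out <- vector("list", min(maxK, L))
  for (k in seq_len(min(maxK, L))) {
    starts <- seq_len(L - k + 1L)
    kms <- substring(seq, starts, starts + k - 1L)
    if (includeBackward && k > 1L) {
      kms <- as.vector(rbind(kms, .reverseStrings(kms)))
    }
    out[[k]] <- kms
  }
  unlist(out, use.names = FALSE)
}

#' Build the k-mer vocabulary
#'
#' Constructs the total mapping from every k-mer over \{A,C,G,T\} of length
#' 1..`maxK` to a unique integer id, plus `<PAD>` (id 0) and `<UNK>`
#' (id 1). Content ids start at 2 and run lexicographically within
#' ascending k, so two calls always agree.
#'
#' @param maxK maximum k-mer length, between 1 and 6 (the vocabulary grows
#'   as the sum of 4^k).
#' @return a [KmerVocabulary].
#' @examples
#' vocabSize(buildVocabulary(3))  # 84 content tokens + 2 specials
#' @export
buildVocabulary <- function(maxK) {
  maxK <- as.integer(maxK)
  if (is.na(maxK) || maxK < 1L || maxK > 6L)
    stop("maxK must be an integer in 1..6")
  bases <- c("A", "C", "G", "T")
  toks <- character(0)
  for (k in seq_len(maxK)) {
    grid <- do.call(expand.grid,
                    c(rev(rep(list(bases), k)),
                      list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
    kms <- do.call(paste0, rev(grid))
    toks <- c(toks, sort(kms, method = "radix"))
  }
  ids <- c(0L, 1L, seq_along(toks) + 1L)
  names(ids) <- c("<PAD>", "<UNK>", toks)
  new("KmerVocabulary", maxK = maxK, tokenIds = ids)
}

#' @describeIn buildVocabulary number of tokens (content plus the two
#'   specials).
#' @param vocab a [KmerVocabulary].
#' @export
vocabSize <- function(vocab) length(vocab@tokenIds)

#' @describeIn buildVocabulary maximum k-mer length of a vocabulary.
#' @export
maxKmerSize <- function(vocab) vocab@maxK

#' Encode k-mers as integer token ids
#'
#' @param kmers character vector of k-mers (e.g. from [extractKmers()]).
#' @param vocab a [KmerVocabulary] with `maxK` at least the longest k-mer.
#' @return integer vector of ids, same order as the input. K-mers absent
#'   from the vocabulary are substituted by the `<UNK>` id with a counted
#'   warning (this never fires on valid input).
#' @export
encodeKmers <- function(kmers, vocab) {
  stopifnot(is(vocab, "KmerVocabulary"))
  if (length(kmers) == 0L) return(integer(0))
  ids <- unname(vocab@tokenIds[kmers])
  missing <- is.na(ids)
  if (any(missing)) {
    warning(sprintf("%d k-mer(s) absent from the vocabulary; substituted <UNK>",
                    sum(missing)))
    ids[missing] <- 1L
  }
  ids
}

#' Decode token ids back to k-mers
#'
#' @param ids integer vector of token ids.
#' @param vocab a [KmerVocabulary].
#' @return character vector of tokens.
#' @export
decodeIds <- function(ids, vocab) {
  stopifnot(is(vocab, "KmerVocabulary"))
  lut <- names(vocab@tokenIds)[order(vocab@tokenIds)]
  bad <- ids < 0L | ids >= length(lut)
  if (any(bad)) stop("id out of vocabulary range")
  lut[ids + 1L]
}

#' Pad a list of token streams into a rectangular batch
#'
#' Streams shorter than `maxLen` are right-padded with the `<PAD>` id (0);
#' streams longer than `maxLen` are truncated from the tail, with the
#' number of truncated streams reported via a message.
#'
#' @param streams list of integer id vectors.
#' @param maxLen common stream length after padding.
#' @return a [TokenBatch].
#' @export
padBatch <- function(streams, maxLen) {
  maxLen <- as.integer(maxLen)
  if (is.na(maxLen) || maxLen < 1L) stop("maxLen must be >= 1")
  lens <- lengths(streams)
  nTrunc <- sum(lens > maxLen)
  if (nTrunc > 0L)
    message(sprintf("padBatch: %d stream(s) longer than %d truncated from the tail",
                    nTrunc, maxLen))
  B <- length(streams)
  ids <- matrix(0L, nrow = B, ncol = maxLen)
  for (i in seq_len(B)) {
    n <- min(lens[i], maxLen)
    if (n > 0L) ids[i, seq_len(n)] <- streams[[i]][seq_len(n)]
  }
  nReal <- as.integer(pmin(lens, maxLen))
  mask <- matrix(FALSE, nrow = B, ncol = maxLen)
  mask[cbind(rep(seq_len(B), nReal),
             unlist(lapply(nReal, seq_len), use.names = FALSE))] <- TRUE
  new("TokenBatch", ids = ids, mask = mask, nReal = nReal)
}

#' @describeIn padBatch token id matrix of a [TokenBatch].
#' @param x a [TokenBatch].
#' @export
tokenIds <- function(x) x@ids

#' @describeIn padBatch padding mask of a [TokenBatch] (`TRUE` = real token).
#' @export
tokenMask <- function(x) x@mask

#' @describeIn padBatch real-token counts of a [TokenBatch].
#' @export
nRealTokens <- function(x) x@nReal

#' Serialize a vocabulary as flat two-column text
#'
#' Writes one `token<TAB>id` line per token in ascending id order
#' (deterministic), atomically (write-temp-then-rename).
#'
#' @param vocab a [KmerVocabulary].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVocabulary <- function(vocab, path) {
  stopifnot(is(vocab, "KmerVocabulary"))
  ord <- order(vocab@tokenIds)
  lines <- paste(names(vocab@tokenIds)[ord], vocab@tokenIds[ord], sep = "\t")
  .atomicWriteLines(lines, path)
  invisible(path)
}

#' @describeIn writeVocabulary read a vocabulary back from its two-column
#'   text serialization.
#' @export
readVocabulary <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed vocabulary file")
  toks <- vapply(parts, `[`, character(1L), 1L)
  ids <- as.integer(vapply(parts, `[`, character(1L), 2L))
  content <- toks[!toks %in% c("<PAD>", "<UNK>")]
  ids <- stats::setNames(ids, toks)
  new("KmerVocabulary", maxK = max(nchar(content)), tokenIds = ids)
}

#' @export
setMethod("show", "KmerVocabulary", function(object) {
  cat(sprintf("KmerVocabulary: maxK = %d, %d tokens (%d k-mers + 2 specials)\n",
              object@maxK, length(object@tokenIds),
              length(object@tokenIds) - 2L))
})

#' @export
setMethod("show", "TokenBatch", function(object) {
  cat(sprintf("TokenBatch: %d stream(s) padded to length %d (real tokens %d-%d)\n",
              nrow(object@ids), ncol(object@ids),
              min(object@nReal), max(object@nReal)))
})

#' @export
setMethod("show", "TokenizedPairs", function(object) {
  cat(sprintf(
    "TokenizedPairs: %d pairs (%d positive), query len %d, target len %d\n",
    length(object@labels), sum(object@labels == 1),
    ncol(object@a@ids), ncol(object@b@ids)))
})

# write lines atomically: temp file in the same directory, then rename
.atomicWriteLines <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}
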