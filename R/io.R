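# Readers and writers for the pair-TSV dialect, paired FASTA input, run
# configurations and model checkpoints.

#' Read a labeled pair dataset
#'
#' The canonical on-disk format is a 3-column TSV
#' (`pirna<TAB>mrna<TAB>label`, label in \{0,1\}) with an optional header
#' line starting with `#`. Alternatively two FASTA files with matched
#' record order plus a one-label-per-line file can be read
#' (`format = "fasta_pair"`). Sequences are normalized (uppercase, U->T);
#' malformed rows are rejected with their line number, or dropped with a
#' counted warning when `onInvalid = "drop"`.
#'
#' @param path TSV path (for `format = "tsv"`) or the piRNA FASTA path
#'   (for `format = "fasta_pair"`).
#' @param format "tsv" or "fasta_pair".
#' @param mrnaPath,labelPath companion files for `format = "fasta_pair"`.
#' @param onInvalid "error" (default) or "drop".
#' @return data.frame with columns `pirna`, `mrna`, `label`.
#' @export
readPairs <- function(path, format = c("tsv", "fasta_pair"),
                      mrnaPath = NULL, labelPath = NULL,
                      onInvalid = c("error", "drop")) {
  format <- match.arg(format)
  onInvalid <- match.arg(onInvalid)
  if (format == "tsv") {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    keep <- !startsWith(lines, "#") & nzchar(lines)
    lineNo <- which(keep)
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    nc <- lengths(parts)
    if (any(nc != 3L)) {
      i <- which(nc != 3L)[1L]
      stop(sprintf("line %d: expected 3 tab-separated columns, found %d",
                   lineNo[i], nc[i]))
    }
    raw <- data.frame(pirna = vapply(parts, `[`, character(1L), 1L),
                      mrna = vapply(parts, `[`, character(1L), 2L),
                      label = vapply(parts, `[`, character(1L), 3L))
  } else {
    if (is.null(mrnaPath) || is.null(labelPath))
      stop("format 'fasta_pair' needs mrnaPath and labelPath")
    # read as raw strings: RNA spellings (U) are handled by the codec's
    # normalization, which a DNA-alphabet parser would reject
    pirna <- as.character(Biostrings::readBStringSet(path))
    mrna <- as.character(Biostrings::readBStringSet(mrnaPath))
    labels <- readLines(labelPath)
    labels <- labels[nzchar(labels)]
    if (length(pirna) != length(mrna) || length(pirna) != length(labels))
      stop("fasta_pair inputs must have matched record counts")
    raw <- data.frame(pirna = unname(pirna), mrna = unname(mrna),
                      label = labels)
    lineNo <- seq_len(nrow(raw))
  }
  badLabel <- !raw$label %in% c("0", "1")
  if (any(badLabel)) {
    i <- which(badLabel)[1L]
    if (onInvalid == "error")
      stop(sprintf("line %d: invalid label '%s' (must be 0 or 1)",
                   lineNo[i], raw$label[i]))
  }
  norm <- function(s) tryCatch(normalizeSequence(s),
                               error = function(e) NA_character_)
  pirna <- vapply(raw$pirna, norm, character(1L), USE.NAMES = FALSE)
  mrna <- vapply(raw$mrna, norm, character(1L), USE.NAMES = FALSE)
  badSeq <- is.na(pirna) | is.na(mrna)
  if (any(badSeq) && onInvalid == "error") {
    i <- which(badSeq)[1L]
    stop(sprintf("line %d: %s", lineNo[i], tryCatch({
      normalizeSequence(raw$pirna[i]); normalizeSequence(raw$mrna[i]); ""
    }, error = function(e) conditionMessage(e))))
  }
  bad <- badLabel | badSeq
  if (any(bad))
    warning(sprintf("dropped %d malformed row(s)", sum(bad)))
  data.frame(pirna = pirna[!bad], mrna = mrna[!bad],
             label = as.integer(raw$label[!bad]))
}

#' @describeIn readPairs write pairs in the 3-column TSV dialect
#'   (atomically: write-temp-then-rename). Provenance columns are not
#'   written.
#' @param pairs data.frame with columns `pirna`, `mrna`, `label`.
#' @param header write the `#`-prefixed header line.
#' @export
writePairs <- function(pairs, path, header = TRUE) {
  stopifnot(all(c("pirna", "mrna", "label") %in% names(pairs)))
  lines <- paste(pairs$pirna, pairs$mrna, pairs$label, sep = "\t")
  if (header) lines <- c("#pirna_seq\tmrna_seq\tlabel", lines)
  .atomicWriteLines(lines, path)
  invisible(path)
}

#' @describeIn readPairs convenience reader for datasets split into a
#'   positive and a negative file, each a 2-column TSV
#'   (`pirna<TAB>mrna`); labels 1 and 0 are assigned by file.
#' @param positivePath,negativePath the two 2-column TSV files.
#' @export
readPairsSplit <- function(positivePath, negativePath,
                           onInvalid = c("error", "drop")) {
  readTwoCol <- function(p, lab) {
    lines <- readLines(p)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L)) stop("expected 2 columns in ", p)
    data.frame(pirna = vapply(parts, `[`, character(1L), 1L),
               mrna = vapply(parts, `[`, character(1L), 2L),
               label = lab)
  }
  df <- rbind(readTwoCol(positivePath, "1"), readTwoCol(negativePath, "0"))
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(paste(df$pirna, df$mrna, df$label, sep = "\t"), tmp)
  readPairs(tmp, onInvalid = match.arg(onInvalid))
}

## ---- run-configuration serialization -------------------------------------

.s4ToList <- function(obj) {
  sn <- methods::slotNames(class(obj))
  out <- lapply(sn, function(s) methods::slot(obj, s))
  names(out) <- sn
  out
}

#' Serialize / restore a composite run configuration
#'
#' A run configuration bundles the model, training, split and synthetic
#' configs into one YAML document so that every run can be reproduced
#' from the file written beside its outputs. Round-trips losslessly.
#'
#' @param model a [ModelConfig].
#' @param train a [TrainConfig].
#' @param split a [SplitSpec].
#' @param synthetic a [SyntheticConfig] or `NULL`.
#' @param path output/input YAML path.
#' @return `writeRunConfig()` returns `path` invisibly; `readRunConfig()`
#'   returns a named list of the restored config objects.
#' @export
writeRunConfig <- function(path, model = modelConfig(),
                           train = trainConfig(), split = splitSpec(),
                           synthetic = NULL) {
  doc <- list(model = .s4ToList(model), train = .s4ToList(train),
              split = .s4ToList(split))
  if (!is.null(synthetic)) doc$synthetic <- .s4ToList(synthetic)
  .atomicWriteLines(yaml::as.yaml(doc), path)
  invisible(path)
}

#' @describeIn writeRunConfig restore the configuration objects from YAML.
#' @export
readRunConfig <- function(path) {
  doc <- yaml::yaml.load_file(path)
  out <- list(model = do.call(modelConfig, doc$model),
              train = do.call(trainConfig, doc$train),
              split = do.call(splitSpec, doc$split))
  if (!is.null(doc$synthetic))
    out$synthetic <- do.call(syntheticConfig, doc$synthetic)
  out
}

## ---- model checkpoints ----------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding the weights (`weights.rds`), the
#' vocabularies as flat text, the model config as YAML (so the checkpoint
#' is self-describing) and a format version marker.
#'
#' @param model an [RbpTransformer].
#' @param dir checkpoint directory (created if needed).
#' @return `saveModel()` returns `dir` invisibly; `loadModel()` returns
#'   the restored [RbpTransformer].
#' @export
saveModel <- function(model, dir) {
  stopifnot(is(model, "RbpTransformer"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(model@params, file.path(dir, "weights.rds"))
  writeVocabulary(model@vocabA, file.path(dir, "vocab_a.tsv"))
  writeVocabulary(model@vocabB, file.path(dir, "vocab_b.tsv"))
  .atomicWriteLines(yaml::as.yaml(list(
    format_version = 1L, trained = model@trained,
    model = .s4ToList(model@config))), file.path(dir, "config.yaml"))
  if (!is.null(model@history))
    utils::write.csv(model@history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @describeIn saveModel load a checkpoint directory.
#' @export
loadModel <- function(dir) {
  doc <- yaml::yaml.load_file(file.path(dir, "config.yaml"))
  if (is.null(doc$format_version) || doc$format_version != 1L)
    stop("unrecognized checkpoint format in ", dir)
  params <- readRDS(file.path(dir, "weights.rds"))
  histPath <- file.path(dir, "history.csv")
  new("RbpTransformer", config = do.call(modelConfig, doc$model),
      vocabA = readVocabulary(file.path(dir, "vocab_a.tsv")),
      vocabB = readVocabulary(file.path(dir, "vocab_b.tsv")),
      params = params, nParams = .countParams(params),
      trained = isTRUE(doc$trained),
      history = if (file.exists(histPath)) utils::read.csv(histPath)
                else NULL)
}

# write a data.frame as TSV, atomically
.writeTsv <- function(df, path) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  .atomicWriteLines(out, path)
}
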