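#' @import methods
NULL

#' KmerVocabulary: bijection between k-mers and integer token ids
#'
#' Maps every k-mer over \{A,C,G,T\} of length 1..`maxK`, plus the two special
#' tokens `<PAD>` (id 0) and `<UNK>` (id 1), to a unique integer id. Content
#' ids start at 2 and are assigned lexicographically within ascending k, so
#' the mapping is fully deterministic and serializes stably.
#'
#' @slot maxK maximum k-mer length covered by the vocabulary.
#' @slot tokenIds named integer vector; names are tokens (including the
#'   specials), values are ids.
#' @name KmerVocabulary-class
#' @aliases KmerVocabulary
#' @exportClass KmerVocabulary
setClass("KmerVocabulary",
  representation(maxK = "integer", tokenIds = "integer"),
  validity = function(object) {
    msg <- character()
    k <- object@maxK
    if (length(k) != 1L || is.na(k) || k < 1L)
      msg <- c(msg, "maxK must be a single positive integer")
    else {
      expected <- 2L + sum(4L^seq_len(k))
      if (length(object@tokenIds) != expected)
        msg <- c(msg, sprintf("vocabulary must hold %d tokens, found %d",
                              expected, length(object@tokenIds)))
    }
    if (anyDuplicated(object@tokenIds))
      msg <- c(msg, "token ids must be unique")
    if (anyDuplicated(names(object@tokenIds)))
      msg <- c(msg, "tokens must be unique")
    if (!identical(unname(object@tokenIds[c("<PAD>", "<UNK>")]), c(0L, 1L)))
      msg <- c(msg, "<PAD> must have id 0 and <UNK> id 1")
    if (length(msg)) msg else TRUE
  })

#' TokenBatch: a padded batch of token streams
#'
#' Holds the integer token ids of a batch of sequences, right-padded to a
#' common length, together with the boolean padding mask (`TRUE` = real
#' token) and the per-stream count of real tokens.
#'
#' @slot ids integer matrix, one row per stream.
#' @slot mask logical matrix of the same shape; `TRUE` exactly where `ids`
#'   holds a real (non-pad) token.
#' @slot nReal integer vector of real-token counts per stream.
#' @name TokenBatch-class
#' @aliases TokenBatch
#' @exportClass TokenBatch
setClass("TokenBatch",
  representation(ids = "matrix", mask = "matrix", nReal = "integer"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@ids), dim(object@mask)))
      msg <- c(msg, "ids and mask must have identical dimensions")
    if (length(object@nReal) != nrow(object@ids))
      msg <- c(msg, "nReal must have one entry per row")
    if (!all(rowSums(object@mask) == object@nReal))
      msg <- c(msg, "mask row sums must equal nReal")
    if (length(msg)) msg else TRUE
  })

#' TokenizedPairs: a tokenized labeled pair dataset
#'
#' The result of [tokenizePairs()]: the query-side and target-side token
#' batches plus the binary labels, ready to feed the model.
#'
#' @slot a [TokenBatch] of the query-side streams (piRNA by default).
#' @slot b [TokenBatch] of the key/value-side streams (mRNA by default).
#' @slot labels numeric vector of 0/1 labels.
#' @name TokenizedPairs-class
#' @aliases TokenizedPairs
#' @exportClass TokenizedPairs
setClass("TokenizedPairs",
  representation(a = "TokenBatch", b = "TokenBatch", labels = "numeric"),
  validity = function(object) {
    n <- nrow(object@a@ids)
    if (nrow(object@b@ids) != n || length(object@labels) != n)
      return("a, b and labels must describe the same number of pairs")
    if (!all(object@labels %in% c(0, 1)))
      return("labels must be 0 or 1")
    TRUE
  })

#' ModelConfig: architectural hyperparameters of the binding model
#'
#' Created by [modelConfig()]; see that constructor for the meaning and
#' defaults of every field.
#'
#' @slot dModel token embedding / per-position feature dimension.
#' @slot numHeads number of attention heads (`dModel` must be divisible).
#' @slot dDense hidden width of the position-wise dense projection.
#' @slot nCores number of cascaded core blocks.
#' @slot maxK maximum k-mer size used for tokenization.
#' @slot useSelfAttention whether each core applies self-attention before
#'   cross-attention.
#' @slot useBackwardKmers whether reversed copies of k-mers (length > 1)
#'   are interleaved into the token list.
#' @slot symmetricCores whether the target-side stream is also cross-updated
#'   in each core (default: it is only self-attended and carried forward).
#' @slot complementInput which input is base-wise complemented
#'   ("pirna", "mrna" or "none").
#' @slot queryInput which input drives the attention queries and the pooled
#'   output ("pirna" or "mrna").
#' @slot pooling "global_average" (over real tokens) or "global_max".
#' @slot dropoutRate dropout applied to the pooled vector during training.
#' @slot headWidths widths of the three output dense layers.
#' @slot maxLenA,maxLenB padded token-stream lengths (NA = longest observed).
#' @slot seed RNG seed for weight initialization.
#' @name ModelConfig-class
#' @aliases ModelConfig
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(dModel = "integer", numHeads = "integer", dDense = "integer",
                 nCores = "integer", maxK = "integer",
                 useSelfAttention = "logical", useBackwardKmers = "logical",
                 symmetricCores = "logical", complementInput = "character",
                 queryInput = "character", pooling = "character",
                 dropoutRate = "numeric", headWidths = "integer",
                 maxLenA = "integer", maxLenB = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@dModel %% 2L != 0L)
      msg <- c(msg, "dModel must be even (paired sine/cosine dimensions)")
    if (object@dModel %% object@numHeads != 0L)
      msg <- c(msg, "dModel must be divisible by numHeads")
    if (object@nCores < 1L) msg <- c(msg, "nCores must be >= 1")
    if (object@maxK < 1L || object@maxK > 6L)
      msg <- c(msg, "maxK must be in 1..6")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      msg <- c(msg, "dropoutRate must be in [0, 1)")
    if (length(object@headWidths) != 3L || object@headWidths[3L] != 1L)
      msg <- c(msg, "headWidths must be three widths ending in 1")
    if (!object@pooling %in% c("global_average", "global_max"))
      msg <- c(msg, "pooling must be 'global_average' or 'global_max'")
    if (!object@complementInput %in% c("pirna", "mrna", "none"))
      msg <- c(msg, "complementInput must be 'pirna', 'mrna' or 'none'")
    if (!object@queryInput %in% c("pirna", "mrna"))
      msg <- c(msg, "queryInput must be 'pirna' or 'mrna'")
    if (length(msg)) msg else TRUE
  })

#' TrainConfig: optimization hyperparameters
#'
#' Created by [trainConfig()].
#'
#' @slot optimizer one of "rmsprop", "adam", "sgd", "adagrad", "nadam",
#'   "adamax".
#' @slot learningRate step size; `NA` uses the optimizer's customary default.
#' @slot batchSize minibatch size.
#' @slot maxEpochs maximum number of passes over the training data.
#' @slot patience early-stopping patience on the monitored validation
#'   quantity (0 disables early stopping).
#' @slot objective "accuracy" selects the checkpoint with the lowest
#'   validation loss; "auc" selects the highest validation AUC.
#' @slot seed RNG seed for shuffling and dropout.
#' @name TrainConfig-class
#' @aliases TrainConfig
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(optimizer = "character", learningRate = "numeric",
                 batchSize = "integer", maxEpochs = "integer",
                 patience = "integer", objective = "character",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@optimizer %in%
        c("rmsprop", "adam", "sgd", "adagrad", "nadam", "adamax"))
      msg <- c(msg, "unknown optimizer")
    if (!object@objective %in% c("accuracy", "auc"))
      msg <- c(msg, "objective must be 'accuracy' or 'auc'")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be positive")
    if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be positive")
    if (length(msg)) msg else TRUE
  })

#' SplitSpec: train/validation/test split fractions
#'
#' Created by [splitSpec()]. Defaults follow the standard protocol of
#' holding out 20% for testing and 25% of the remainder for validation,
#' i.e. a 60/20/20 partition.
#'
#' @slot testFraction fraction of all pairs held out for testing.
#' @slot valFraction fraction of the non-test remainder used for validation.
#' @slot seed shuffle seed.
#' @name SplitSpec-class
#' @aliases SplitSpec
#' @exportClass SplitSpec
setClass("SplitSpec",
  representation(testFraction = "numeric", valFraction = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@testFraction <= 0 || object@testFraction >= 1 ||
        object@valFraction <= 0 || object@valFraction >= 1)
      return("fractions must be in (0, 1)")
    TRUE
  })

#' SyntheticConfig: parameters of the CLASH-like pair generator
#'
#' Created by [syntheticConfig()]; see that constructor for defaults.
#'
#' @slot nPairs even total number of pairs (balanced classes).
#' @slot pirnaLen,mrnaLen sequence lengths in nucleotides.
#' @slot seedLen length of the planted complementary region in positives.
#' @slot nMismatches substitutions introduced inside the planted region.
#' @slot negMaxRun negatives are rejection-sampled until their longest
#'   complementary run is strictly below this bound.
#' @slot gcContent expected G+C fraction of generated sequences.
#' @slot seed RNG seed.
#' @name SyntheticConfig-class
#' @aliases SyntheticConfig
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(nPairs = "integer", pirnaLen = "integer", mrnaLen = "integer",
                 seedLen = "integer", nMismatches = "integer",
                 negMaxRun = "integer", gcContent = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nPairs < 2L || object@nPairs %% 2L != 0L)
      msg <- c(msg, "nPairs must be a positive even integer")
    if (!(object@seedLen <= object@pirnaLen &&
          object@pirnaLen <= object@mrnaLen))
      msg <- c(msg, "need seedLen <= pirnaLen <= mrnaLen")
    if (object@negMaxRun >= object@seedLen - object@nMismatches)
      msg <- c(msg, "negMaxRun must be < seedLen - nMismatches")
    if (object@gcContent <= 0 || object@gcContent >= 1)
      msg <- c(msg, "gcContent must be in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' RbpTransformer: a built (possibly trained) binding model
#'
#' Created by [buildModel()]; trained in place by [trainModel()]. Weights
#' live in the `params` list; use [nParams()] for the trainable parameter
#' count and [predictPairs()] for inference.
#'
#' @slot config the [ModelConfig].
#' @slot vocabA,vocabB the [KmerVocabulary] of each input stream.
#' @slot params nested list of weight matrices and vectors.
#' @slot nParams total number of trainable parameters.
#' @slot trained whether [trainModel()] has run.
#' @slot history per-epoch training history (`data.frame`) or `NULL`.
#' @name RbpTransformer-class
#' @aliases RbpTransformer
#' @exportClass RbpTransformer
setClass("RbpTransformer",
  representation(config = "ModelConfig", vocabA = "KmerVocabulary",
                 vocabB = "KmerVocabulary", params = "list",
                 nParams = "numeric", trained = "logical", history = "ANY"))

#' EvalReport: classification metrics for one model on one test split
#'
#' Produced by [evaluateModel()]. Accuracy-family metrics use the decision
#' threshold stored in `threshold`; AUC is threshold-free.
#'
#' @slot precision,recall,f1,accuracy,auc metrics in \[0, 1\]; `auc` is `NA`
#'   for a degenerate single-class test set.
#' @slot confusion 2x2 integer matrix (rows: truth 1/0, columns:
#'   predicted 1/0), entries TP, FN, FP, TN.
#' @slot nTest number of test pairs.
#' @slot threshold decision threshold used.
#' @slot fingerprint short text description of the evaluated configuration.
#' @name EvalReport-class
#' @aliases EvalReport
#' @exportClass EvalReport
setClass("EvalReport",
  representation(precision = "numeric", recall = "numeric", f1 = "numeric",
                 accuracy = "numeric", auc = "numeric", confusion = "matrix",
                 nTest = "integer", threshold = "numeric",
                 fingerprint = "character"),
  validity = function(object) {
    if (sum(object@confusion) != object@nTest)
      return("confusion entries must sum to nTest")
    TRUE
  })
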