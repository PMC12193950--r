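#' Training configuration
#'
#' @param optimizer one of "rmsprop" (default, the empirically best
#'   performer for this model family), "adam", "sgd", "adagrad", "nadam",
#'   "adamax".
#' @param learningRate step size; `NA` (default) uses the optimizer's
#'   customary default (0.01 for sgd, 0.001 otherwise).
#' @param batchSize minibatch size (default 128).
#' @param maxEpochs maximum epochs (default 30).
#' @param patience early-stopping patience on the monitored validation
#'   quantity; 0 disables (default 5).
#' @param objective "accuracy" (default) monitors validation loss;
#'   "auc" monitors validation AUC and returns the checkpoint maximizing
#'   it.
#' @param seed RNG seed for shuffling and dropout (default 1).
#' @return a [TrainConfig].
#' @export
trainConfig <- function(optimizer = "rmsprop", learningRate = NA_real_,
                        batchSize = 128L, maxEpochs = 30L, patience = 5L,
                        objective = "accuracy", seed = 1L) {
  new("TrainConfig", optimizer = optimizer,
      learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      patience = as.integer(patience), objective = objective,
      seed = as.integer(seed))
}

#' Split specification for the 60/20/20 protocol
#'
#' @param testFraction fraction held out for testing (default 0.20).
#' @param valFraction fraction of the remainder used for validation
#'   (default 0.25, i.e. 20% of the whole).
#' @param seed shuffle seed (default 1).
#' @return a [SplitSpec].
#' @export
splitSpec <- function(testFraction = 0.20, valFraction = 0.25, seed = 1L) {
  new("SplitSpec", testFraction = testFraction, valFraction = valFraction,
      seed = as.integer(seed))
}

#' Stratified train/validation/test split
#'
#' Shuffles (seeded) and partitions the pairs into disjoint, exhaustive
#' train/validation/test subsets, stratified by label so the class ratio
#' is preserved within one sample per split.
#'
#' @param pairs data.frame with a `label` column.
#' @param spec a [SplitSpec].
#' @return named list of data.frames `train`, `val`, `test`.
#' @export
splitDataset <- function(pairs, spec = splitSpec()) {
  stopifnot(is.data.frame(pairs), "label" %in% names(pairs))
  n <- nrow(pairs)
  if (n < 10L) stop("dataset too small to split (need >= 10 pairs)")
  assign <- character(n)
  withr::with_seed(spec@seed, {
    for (cl in unique(pairs$label)) {
      idx <- sample(which(pairs$label == cl))
      nc <- length(idx)
      nTest <- round(spec@testFraction * nc)
      nVal <- round(spec@valFraction * (nc - nTest))
      assign[idx[seq_len(nTest)]] <- "test"
      assign[idx[nTest + seq_len(nVal)]] <- "val"
      assign[idx[(nTest + nVal + 1L):nc]] <- "train"
    }
  })
  list(train = pairs[assign == "train", , drop = FALSE],
       val = pairs[assign == "val", , drop = FALSE],
       test = pairs[assign == "test", , drop = FALSE])
}

.bceLoss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# exact rank (Mann-Whitney) AUC with midrank tie handling
.rankAuc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.evalOn <- function(model, data, batchSize) {
  prob <- predictPairs(model, data, batchSize)
  list(prob = prob, loss = .bceLoss(prob, data@labels),
       acc = mean((prob >= 0.5) == (data@labels == 1)))
}

#' Train a binding model
#'
#' Minimizes binary cross-entropy by minibatch gradient descent with the
#' configured optimizer. Per-epoch train/validation loss and accuracy are
#' recorded; the returned model carries the best-validation checkpoint
#' (lowest validation loss, or highest validation AUC when
#' `objective = "auc"`). Training aborts with a diagnostic if the loss
#' diverges to a non-finite value.
#'
#' @param model an [RbpTransformer] from [buildModel()].
#' @param trainData,valData [TokenizedPairs] for training and validation.
#' @param config a [TrainConfig].
#' @param verbose print a line per epoch.
#' @return the trained [RbpTransformer]; per-epoch history is available
#'   via [trainingHistory()].
#' @export
trainModel <- function(model, trainData, valData, config = trainConfig(),
                       verbose = FALSE) {
  stopifnot(is(model, "RbpTransformer"), is(trainData, "TokenizedPairs"),
            is(valData, "TokenizedPairs"), is(config, "TrainConfig"))
  cfg <- model@config
  params <- model@params
  opt <- .makeOptimizer(config@optimizer, config@learningRate)
  peA <- positionalEncoding(ncol(trainData@a@ids), cfg@dModel)
  peB <- positionalEncoding(ncol(trainData@b@ids), cfg@dModel)
  n <- length(trainData@labels)
  state <- NULL
  step <- 0L
  monitorAuc <- config@objective == "auc"
  best <- list(score = if (monitorAuc) -Inf else Inf, params = params,
               epoch = 0L)
  hist <- data.frame()
  wait <- 0L
  withr::with_seed(config@seed, {
    for (epoch in seq_len(config@maxEpochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config@batchSize)
      epochLoss <- 0; epochCorrect <- 0
      for (s in starts) {
        idx <- perm[s:min(s + config@batchSize - 1L, n)]
        B <- length(idx)
        y <- trainData@labels[idx]
        fw <- .forwardPass(params, cfg,
                           trainData@a@ids[idx, , drop = FALSE],
                           trainData@a@mask[idx, , drop = FALSE],
                           trainData@b@ids[idx, , drop = FALSE],
                           trainData@b@mask[idx, , drop = FALSE],
                           peA, peB, training = TRUE, keepCaches = TRUE)
        loss <- .bceLoss(fw$prob, y)
        if (!is.finite(loss))
          stop(sprintf(
            "training diverged (non-finite loss) at epoch %d; lower the learning rate",
            epoch))
        dz <- (fw$prob - y) / B
        grads <- .backwardPass(dz, params, cfg,
                               trainData@a@mask[idx, , drop = FALSE],
                               trainData@b@mask[idx, , drop = FALSE],
                               fw$caches)
        step <- step + 1L
        upd <- .applyUpdate(params, grads, state, opt, step)
        params <- upd$params
        state <- upd$state
        epochLoss <- epochLoss + loss * B
        epochCorrect <- epochCorrect + sum((fw$prob >= 0.5) == (y == 1))
      }
      tmpModel <- model
      tmpModel@params <- params
      val <- .evalOn(tmpModel, valData, config@batchSize)
      valAuc <- if (monitorAuc) .rankAuc(val$prob, valData@labels) else NA
      hist <- rbind(hist, data.frame(
        epoch = epoch, trainLoss = epochLoss / n, trainAcc = epochCorrect / n,
        valLoss = val$loss, valAcc = val$acc, valAuc = valAuc))
      if (verbose)
        message(sprintf(
          "epoch %d: train loss %.4f acc %.4f | val loss %.4f acc %.4f%s",
          epoch, epochLoss / n, epochCorrect / n, val$loss, val$acc,
          if (monitorAuc) sprintf(" auc %.4f", valAuc) else ""))
      score <- if (monitorAuc) valAuc else val$loss
      improved <- if (monitorAuc) score > best$score else score < best$score
      if (improved) {
        best <- list(score = score, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (config@patience > 0L && wait >= config@patience) break
      }
    }
  })
  model@params <- best$params
  model@trained <- TRUE
  model@history <- hist
  model
}

#' Evaluate a trained model on a test split
#'
#' Computes the confusion matrix at the decision threshold and the derived
#' precision, recall, F1, accuracy, plus the threshold-free AUC (area
#' under the ROC curve over all thresholds, computed by the exact rank
#' statistic). A single-class test set has no ROC; its AUC is reported as
#' `NA` with a warning.
#'
#' @param model a trained [RbpTransformer].
#' @param testData a [TokenizedPairs].
#' @param threshold decision threshold for the accuracy-family metrics
#'   (default 0.5).
#' @return an [EvalReport].
#' @export
evaluateModel <- function(model, testData, threshold = 0.5) {
  prob <- predictPairs(model, testData)
  y <- testData@labels
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  auc <- .rankAuc(prob, y)
  if (is.na(auc))
    warning("single-class test set: AUC is undefined and reported as NA")
  conf <- matrix(as.integer(c(tp, fn, fp, tn)), nrow = 2L, byrow = TRUE,
                 dimnames = list(truth = c("1", "0"),
                                 predicted = c("1", "0")))
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  cfg <- model@config
  new("EvalReport", precision = precision, recall = recall, f1 = f1,
      accuracy = (tp + tn) / length(y), auc = auc, confusion = conf,
      nTest = length(y), threshold = threshold,
      fingerprint = sprintf("cores=%d maxK=%d dModel=%d heads=%d selfAttn=%s",
                            cfg@nCores, cfg@maxK, cfg@dModel, cfg@numHeads,
                            cfg@useSelfAttention))
}

#' @describeIn evaluateModel metrics of an [EvalReport] as a named vector.
#' @param report an [EvalReport].
#' @export
metrics <- function(report) {
  c(precision = report@precision, recall = report@recall, f1 = report@f1,
    accuracy = report@accuracy, auc = report@auc)
}

#' @describeIn evaluateModel 2x2 confusion matrix of an [EvalReport]
#'   (rows: truth, columns: prediction).
#' @export
confusionMatrix <- function(report) report@confusion

#' @export
setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (%s; n = %d, threshold = %.2f)\n",
              object@fingerprint, object@nTest, object@threshold))
  cat(sprintf(
    "  precision %.3f | recall %.3f | F1 %.3f | accuracy %.3f | AUC %s\n",
    object@precision, object@recall, object@f1, object@accuracy,
    if (is.na(object@auc)) "NA" else sprintf("%.3f", object@auc)))
  print(object@confusion)
})

.reportRow <- function(report) {
  data.frame(Precision = report@precision, Recall = report@recall,
             `F1 Score` = report@f1, Accuracy = report@accuracy,
             AUC = report@auc, check.names = FALSE)
}

#' Repeated random-split cross-validation
#'
#' Re-shuffles the whole dataset `nRuns` times with distinct derived
#' seeds; each run re-splits 60/20/20, builds a fresh model, trains it and
#' evaluates on that run's test split. An unweighted arithmetic-mean row
#' labelled "Average" is appended to the summary. A failing run is
#' recorded (with its error message) and the remaining runs continue.
#'
#' @param pairs data.frame of labeled pairs.
#' @param nRuns number of repeats (default 10).
#' @param trainCfg a [TrainConfig]; its seed is the master seed.
#' @param modelCfg a [ModelConfig].
#' @param spec a [SplitSpec] giving the fractions.
#' @param vocab optional [KmerVocabulary]; built from `modelCfg@maxK` when
#'   missing.
#' @param verbose print one line per run.
#' @return list with `reports` (per-run [EvalReport]s, or `NULL` for
#'   failures), `summary` (data.frame of per-run rows plus the Average
#'   row), and `failures` (character vector of error messages).
#' @export
crossValidate <- function(pairs, nRuns = 10L, trainCfg = trainConfig(),
                          modelCfg = modelConfig(), spec = splitSpec(),
                          vocab = NULL, verbose = FALSE) {
  if (nRuns < 2L) stop("nRuns must be >= 2")
  if (is.null(vocab)) vocab <- buildVocabulary(modelCfg@maxK)
  reports <- vector("list", nRuns)
  failures <- character(0)
  rows <- list()
  for (r in seq_len(nRuns)) {
    runSeed <- as.integer((as.double(trainCfg@seed) + 7919 * r) %% 2147483647)
    res <- tryCatch({
      sp <- splitDataset(pairs, splitSpec(spec@testFraction,
                                          spec@valFraction, runSeed))
      mc <- modelCfg; mc@seed <- runSeed
      tc <- trainCfg; tc@seed <- runSeed
      tok <- function(d) tokenizePairs(d, vocab, mc)
      m <- buildModel(vocab, vocab, mc)
      m <- trainModel(m, tok(sp$train), tok(sp$val), tc)
      evaluateModel(m, tok(sp$test))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("run %d: %s", r, conditionMessage(res)))
      warning(sprintf("cross-validation run %d failed: %s", r,
                      conditionMessage(res)))
    } else {
      reports[[r]] <- res
      rows[[length(rows) + 1L]] <- cbind(Run = as.character(r),
                                         .reportRow(res))
      if (verbose)
        message(sprintf("run %d: accuracy %.3f auc %.3f", r, res@accuracy,
                        res@auc))
    }
  }
  summary <- do.call(rbind, rows)
  avg <- summary[1, , drop = FALSE]
  avg$Run <- "Average"
  for (col in setdiff(names(summary), "Run"))
    avg[[col]] <- mean(summary[[col]])
  summary <- rbind(summary, avg)
  rownames(summary) <- NULL
  list(reports = reports, summary = summary, failures = failures)
}

#' Core-number by k-mer-size ablation grid
#'
#' Trains and evaluates one model per grid cell on a shared stratified
#' split, reporting for each cell the trainable parameter count, wall
#' training time and the standard metric set. Per-cell failures are
#' recorded in the `Error` column and the grid continues.
#'
#' @param pairs data.frame of labeled pairs.
#' @param coreNumbers integer vector of cascade depths (default 1:4).
#' @param maxKs integer vector of maximum k-mer sizes (default 1:3).
#' @param selfAttention,backwardKmers variant flags applied to every cell.
#' @param trainCfg a [TrainConfig].
#' @param baseModelCfg template [ModelConfig]; each cell overrides
#'   `nCores`, `maxK` and the two flags.
#' @param spec a [SplitSpec].
#' @param verbose print one line per cell.
#' @return data.frame with one row per cell and the columns
#'   "Core Number", "Maximum k-mer Size", "Number of Parameters to Train",
#'   "Total Training Time (sec)", "Precision", "Recall", "F1 Score",
#'   "Accuracy" (plus "Error", NA unless the cell failed).
#' @export
ablationGrid <- function(pairs, coreNumbers = 1:4, maxKs = 1:3,
                         selfAttention = TRUE, backwardKmers = FALSE,
                         trainCfg = trainConfig(),
                         baseModelCfg = modelConfig(), spec = splitSpec(),
                         verbose = FALSE) {
  sp <- splitDataset(pairs, spec)
  rows <- list()
  for (k in maxKs) {
    vocab <- buildVocabulary(k)
    mcK <- baseModelCfg
    mcK@maxK <- as.integer(k)
    mcK@useSelfAttention <- isTRUE(selfAttention)
    mcK@useBackwardKmers <- isTRUE(backwardKmers)
    tokTrain <- tokenizePairs(sp$train, vocab, mcK)
    # validation/test streams must share the training padding lengths
    mcPad <- mcK
    mcPad@maxLenA <- ncol(tokTrain@a@ids)
    mcPad@maxLenB <- ncol(tokTrain@b@ids)
    tokVal <- tokenizePairs(sp$val, vocab, mcPad)
    tokTest <- tokenizePairs(sp$test, vocab, mcPad)
    for (nc in coreNumbers) {
      mc <- mcPad
      mc@nCores <- as.integer(nc)
      row <- data.frame(`Core Number` = nc, `Maximum k-mer Size` = k,
                        `Number of Parameters to Train` = NA_real_,
                        `Total Training Time (sec)` = NA_real_,
                        Precision = NA_real_, Recall = NA_real_,
                        `F1 Score` = NA_real_, Accuracy = NA_real_,
                        Error = NA_character_, check.names = FALSE)
      res <- tryCatch({
        m <- buildModel(vocab, vocab, mc)
        t0 <- proc.time()[["elapsed"]]
        m <- trainModel(m, tokTrain, tokVal, trainCfg)
        elapsed <- proc.time()[["elapsed"]] - t0
        rep <- evaluateModel(m, tokTest)
        list(m = m, elapsed = elapsed, rep = rep)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$Error <- conditionMessage(res)
        warning(sprintf("grid cell (cores=%d, k=%d) failed: %s", nc, k,
                        conditionMessage(res)))
      } else {
        row$`Number of Parameters to Train` <- nParams(res$m)
        row$`Total Training Time (sec)` <- res$elapsed
        row$Precision <- res$rep@precision
        row$Recall <- res$rep@recall
        row$`F1 Score` <- res$rep@f1
        row$Accuracy <- res$rep@accuracy
        if (verbose)
          message(sprintf("cores=%d k=%d: params=%d acc=%.3f", nc, k,
                          nParams(res$m), res$rep@accuracy))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$`Core Number`, out$`Maximum k-mer Size`), ]
  rownames(out) <- NULL
  out
}
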