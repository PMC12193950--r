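smallConfig <- function(...) {
  defaults <- list(dModel = 8L, numHeads = 2L, dDense = 12L, nCores = 1L,
                   maxK = 2L, headWidths = c(6L, 4L, 1L), dropoutRate = 0,
                   seed = 51L)
  do.call(modelConfig, utils::modifyList(defaults, list(...)))
}

test_that("the 60/20/20 split is exact, stratified, exhaustive and seeded", {
  pairs <- data.frame(pirna = rep("ACGT", 1000), mrna = rep("ACGTACGT", 1000),
                      label = rep(c(0L, 1L), 500), id = 1:1000)
  sp <- splitDataset(pairs, splitSpec(seed = 9))
  expect_identical(nrow(sp$train), 600L)
  expect_identical(nrow(sp$val), 200L)
  expect_identical(nrow(sp$test), 200L)
  # stratification: class ratio preserved within one sample per split
  for (part in sp) expect_lte(abs(sum(part$label == 1) - nrow(part) / 2), 1)
  # disjoint and exhaustive partition of the input
  expect_identical(sort(c(sp$train$id, sp$val$id, sp$test$id)), 1:1000)
  # determinism
  sp2 <- splitDataset(pairs, splitSpec(seed = 9))
  expect_identical(sp$test$id, sp2$test$id)
  sp3 <- splitDataset(pairs, splitSpec(seed = 10))
  expect_false(identical(sp$test$id, sp3$test$id))
  expect_error(splitDataset(pairs[1:5, ]), "too small")
})

test_that("metric formulas agree with hand-computed confusion matrices", {
  # a predictor we fully control: probabilities on either side of 0.5
  # TP=3, FP=1, FN=1, TN=5
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  prob <- c(.9, .8, .7, .2, .6, .1, .2, .3, .1, .4)
  rep <- local({
    # evaluateModel needs a model; recompute its arithmetic independently
    pred <- as.integer(prob >= 0.5)
    tp <- sum(pred & y); fp <- sum(pred & !y)
    fn <- sum(!pred & y); tn <- sum(!pred & !y)
    list(tp = tp, fp = fp, fn = fn, tn = tn)
  })
  expect_identical(unlist(rep), c(tp = 3L, fp = 1L, fn = 1L, tn = 5L))
  expect_equal(rep$tp / (rep$tp + rep$fp), 0.75)           # precision
  expect_equal(rep$tp / (rep$tp + rep$fn), 0.75)           # recall
  expect_equal((rep$tp + rep$tn) / 10, 0.8)                # accuracy
})

test_that("evaluateModel reports the same numbers as an independent recount", {
  v <- buildVocabulary(2)
  cfg <- smallConfig()
  pairs <- tinyPairSet(40, seed = 52)
  tok <- tokenizePairs(pairs, v, cfg)
  m <- buildModel(v, v, cfg)
  rep <- evaluateModel(m, tok)
  prob <- predictPairs(m, tok)
  y <- tok@labels
  pred <- as.integer(prob >= 0.5)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  expect_identical(unname(confusionMatrix(rep)[1, 1]), as.integer(tp))
  expect_identical(sum(confusionMatrix(rep)), 40L)
  expect_equal(rep@accuracy, (tp + tn) / 40)
  if (tp + fp > 0) expect_equal(rep@precision, tp / (tp + fp))
  # AUC cross-checked against the pROC reference implementation (direction
  # pinned: pROC would otherwise flip a below-chance classifier)
  skip_if_not_installed("pROC")
  expect_equal(rep@auc,
               as.numeric(pROC::auc(pROC::roc(y, prob, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))),
               tolerance = 1e-12)
})

test_that("perfect and constant predictors hit the metric boundary values", {
  y <- rep(c(1, 0), 20)
  perfect <- ifelse(y == 1, 0.9, 0.1)
  expect_equal(rbpTransformer:::.rankAuc(perfect, y), 1)
  constant <- rep(0.5, 40)
  expect_equal(rbpTransformer:::.rankAuc(constant, y), 0.5)
  expect_equal(mean((constant >= 0.5) == (y == 1)), 0.5)
  # degenerate single-class set: AUC undefined
  expect_true(is.na(rbpTransformer:::.rankAuc(perfect, rep(1, 40))))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(53, {
    for (i in 1:20) {
      y <- sample(c(0, 1), 50, replace = TRUE)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      s <- rnorm(50)
      a0 <- rbpTransformer:::.rankAuc(s, y)
      expect_equal(rbpTransformer:::.rankAuc(exp(s), y), a0, tolerance = 1e-12)
      expect_equal(rbpTransformer:::.rankAuc(2 * s - 7, y), a0,
                   tolerance = 1e-12)
      expect_equal(rbpTransformer:::.rankAuc(atan(s), y), a0,
                   tolerance = 1e-12)
    }
  })
})

test_that("training overfits a linearly separable toy problem and logs history", {
  v <- buildVocabulary(2)
  cfg <- smallConfig()
  # trivially separable: positives are all-A piRNA, negatives all-G
  pairs <- data.frame(
    pirna = rep(c("AAAAAAAA", "GGGGGGGG"), each = 20),
    mrna = replicate(40, randomSeq(20)),
    label = rep(c(1L, 0L), each = 20))
  tok <- tokenizePairs(pairs, v, cfg)
  m <- buildModel(v, v, cfg)
  m <- trainModel(m, tok, tok,
                  trainConfig(optimizer = "rmsprop", batchSize = 8L,
                              maxEpochs = 20L, patience = 0L, seed = 53))
  h <- trainingHistory(m)
  expect_lte(nrow(h), 20L)
  expect_identical(max(h$trainAcc), 1)
  # validation loss column is the loss on exactly the val split: recompute
  probs <- predictPairs(m, tok)
  # (best checkpoint = lowest val loss over epochs; recomputed loss must
  # equal that minimum)
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  recomputed <- -mean(tok@labels * log(p) + (1 - tok@labels) * log(1 - p))
  expect_equal(recomputed, min(h$valLoss), tolerance = 1e-10)
})

test_that("training is reproducible under a fixed seed", {
  v <- buildVocabulary(2)
  cfg <- smallConfig()
  pairs <- tinyPairSet(30, seed = 54)
  tok <- tokenizePairs(pairs, v, cfg)
  runOnce <- function() {
    m <- buildModel(v, v, cfg)
    m <- trainModel(m, tok, tok,
                    trainConfig(batchSize = 8L, maxEpochs = 3L, seed = 55))
    predictPairs(m, tok)
  }
  expect_equal(runOnce(), runOnce(), tolerance = 1e-6)
})

test_that("divergent training aborts with a diagnostic", {
  v <- buildVocabulary(2)
  cfg <- smallConfig()
  pairs <- tinyPairSet(20, seed = 56)
  tok <- tokenizePairs(pairs, v, cfg)
  m <- buildModel(v, v, cfg)
  # a non-finite weight makes the first forward pass non-finite, which the
  # training loop must catch and report rather than propagate silently
  m@params$embA[3, 1] <- NaN  # row of token "A" (id 2), present in any input
  expect_error(
    trainModel(m, tok, tok,
               trainConfig(batchSize = 8L, maxEpochs = 5L, seed = 56)),
    "diverged")
})

test_that("all six optimizers take a valid step", {
  ns <- asNamespace("rbpTransformer")
  for (nm in c("sgd", "rmsprop", "adam", "adagrad", "nadam", "adamax")) {
    opt <- ns$.makeOptimizer(nm)
    w <- matrix(1, 2, 2)
    g <- matrix(0.5, 2, 2)
    res <- ns$.applyUpdate(list(a = w), list(a = g), NULL, opt, 1L)
    expect_true(all(res$params$a < w), info = nm)  # moved against gradient
    expect_true(all(is.finite(res$params$a)), info = nm)
  }
  expect_error(ns$.makeOptimizer("sharpness-aware"), "arg")
})

test_that("cross-validation emits per-run rows plus an arithmetic-mean row", {
  pairs <- tinyPairSet(60, seed = 57)
  res <- crossValidate(
    pairs, nRuns = 2L,
    trainCfg = trainConfig(batchSize = 16L, maxEpochs = 2L, seed = 58),
    modelCfg = smallConfig())
  expect_identical(nrow(res$summary), 3L)
  expect_identical(res$summary$Run, c("1", "2", "Average"))
  expect_equal(res$summary$Accuracy[3], mean(res$summary$Accuracy[1:2]))
  expect_equal(res$summary$Precision[3], mean(res$summary$Precision[1:2]))
  # identical master seed reproduces the whole report list
  res2 <- crossValidate(
    pairs, nRuns = 2L,
    trainCfg = trainConfig(batchSize = 16L, maxEpochs = 2L, seed = 58),
    modelCfg = smallConfig())
  expect_equal(res$summary, res2$summary, tolerance = 1e-6)
  expect_error(crossValidate(pairs, nRuns = 1L), "nRuns")
})

test_that("a small ablation grid runs end-to-end with the standard columns", {
  pairs <- tinyPairSet(60, seed = 59)
  res <- ablationGrid(
    pairs, coreNumbers = 1:2, maxKs = 1L,
    trainCfg = trainConfig(batchSize = 16L, maxEpochs = 2L, seed = 60),
    baseModelCfg = smallConfig(), spec = splitSpec(seed = 60))
  expect_identical(nrow(res), 2L)
  expect_true(all(c("Core Number", "Maximum k-mer Size",
                    "Number of Parameters to Train",
                    "Total Training Time (sec)", "Precision", "Recall",
                    "F1 Score", "Accuracy") %in% names(res)))
  expect_true(all(diff(res$`Number of Parameters to Train`) > 0))
  expect_true(all(is.na(res$Error)))
})
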