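# structural and numerical properties of the assembled network

tinyConfig <- function(...) {
  defaults <- list(dModel = 8L, numHeads = 2L, dDense = 12L, nCores = 1L,
                   maxK = 2L, headWidths = c(6L, 4L, 1L), dropoutRate = 0,
                   seed = 5L)
  do.call(modelConfig, utils::modifyList(defaults, list(...)))
}

test_that("model outputs are probabilities and deterministic under a seed", {
  v <- buildVocabulary(2)
  pairs <- tinyPairSet(20, seed = 31)
  cfg <- tinyConfig()
  tok <- tokenizePairs(pairs, v, cfg)
  m1 <- buildModel(v, v, cfg)
  m2 <- buildModel(v, v, cfg)
  p1 <- predictPairs(m1, tok)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, predictPairs(m2, tok))  # same seed, same weights
  m3 <- buildModel(v, v, tinyConfig(seed = 6L))
  expect_false(identical(p1, predictPairs(m3, tok)))
})

test_that("parameter count increases strictly with core count and with maxK", {
  v2 <- buildVocabulary(2)
  counts <- vapply(1:4, function(nc)
    nParams(buildModel(v2, v2, tinyConfig(nCores = nc))), numeric(1))
  expect_true(all(diff(counts) > 0))
  # each extra core adds an identical parameter block
  expect_true(length(unique(diff(counts))) == 1L)
  kCounts <- vapply(1:3, function(k) {
    vk <- buildVocabulary(k)
    nParams(buildModel(vk, vk, tinyConfig(maxK = k)))
  }, numeric(1))
  expect_true(all(diff(kCounts) > 0))
})

test_that("the cross-attention-only variant drops the self-attention blocks", {
  v <- buildVocabulary(2)
  full <- buildModel(v, v, tinyConfig())
  bare <- buildModel(v, v, tinyConfig(useSelfAttention = FALSE))
  coreF <- full@params$cores[[1]]
  coreB <- bare@params$cores[[1]]
  # full core: 3 attention modules and 4 add&normalize stages
  expect_identical(sum(names(coreF) %in% c("selfA", "selfB", "cross")), 3L)
  expect_identical(sum(startsWith(names(coreF), "ln")), 4L)
  # variant: exactly 1 attention module and 2 add&normalize stages
  expect_identical(sum(names(coreB) %in% c("selfA", "selfB", "cross")), 1L)
  expect_identical(sum(startsWith(names(coreB), "ln")), 2L)
  expect_lt(nParams(bare), nParams(full))
})

test_that("model output is invariant to the amount of padding", {
  v <- buildVocabulary(2)
  pairs <- tinyPairSet(10, seed = 32)
  cfg1 <- tinyConfig()
  cfg2 <- tinyConfig(maxLenA = 40L, maxLenB = 80L)  # much longer padding
  m <- buildModel(v, v, cfg1)
  p1 <- predictPairs(m, tokenizePairs(pairs, v, cfg1))
  p2 <- predictPairs(m, tokenizePairs(pairs, v, cfg2))
  expect_lt(max(abs(p1 - p2)), 1e-5)
  # also under max pooling, which only sees real tokens
  cfgM1 <- tinyConfig(pooling = "global_max")
  cfgM2 <- tinyConfig(pooling = "global_max", maxLenA = 40L, maxLenB = 80L)
  mM <- buildModel(v, v, cfgM1)
  expect_lt(max(abs(predictPairs(mM, tokenizePairs(pairs, v, cfgM1)) -
                    predictPairs(mM, tokenizePairs(pairs, v, cfgM2)))), 1e-5)
})

test_that("analytic gradients match finite differences for every variant", {
  ns <- asNamespace("rbpTransformer")
  v <- buildVocabulary(2)
  runCheck <- function(cfg, nProbe = 60) {
    pairs <- tinyPairSet(4, seed = 33)
    tok <- tokenizePairs(pairs, v, cfg)
    m <- buildModel(v, v, cfg)
    peA <- positionalEncoding(ncol(tok@a@ids), cfg@dModel)
    peB <- positionalEncoding(ncol(tok@b@ids), cfg@dModel)
    y <- tok@labels
    lossOf <- function(params) {
      fw <- ns$.forwardPass(params, cfg, tok@a@ids, tok@a@mask,
                            tok@b@ids, tok@b@mask, peA, peB)
      p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    }
    fw <- ns$.forwardPass(m@params, cfg, tok@a@ids, tok@a@mask,
                          tok@b@ids, tok@b@mask, peA, peB,
                          keepCaches = TRUE)
    gr <- ns$.backwardPass((fw$prob - y) / length(y), m@params, cfg,
                           tok@a@mask, tok@b@mask, fw$caches)
    flat <- function(x) if (is.list(x)) unlist(lapply(x, flat))
                        else as.numeric(x)
    gvec <- flat(gr)
    pvec <- flat(m@params)
    setScalar <- function(params, i, val) {
      k <- 0
      rec <- function(x) {
        if (is.list(x)) {
          for (n in seq_along(x)) x[[n]] <- rec(x[[n]])
          x
        } else {
          ln <- length(x)
          if (i > k && i <= k + ln) x[i - k] <- val
          k <<- k + ln
          x
        }
      }
      rec(params)
    }
    idx <- sort(sample(length(pvec), nProbe))
    eps <- 1e-5
    num <- vapply(idx, function(i)
      (lossOf(setScalar(m@params, i, pvec[i] + eps)) -
       lossOf(setScalar(m@params, i, pvec[i] - eps))) / (2 * eps),
      numeric(1))
    max(abs(num - gvec[idx]) / pmax(1e-6, abs(num) + abs(gvec[idx])))
  }
  withr::with_seed(34, {
    expect_lt(runCheck(tinyConfig(nCores = 2L)), 1e-4)
    expect_lt(runCheck(tinyConfig(useSelfAttention = FALSE)), 1e-4)
    expect_lt(runCheck(tinyConfig(symmetricCores = TRUE,
                                  pooling = "global_max")), 1e-4)
  })
})

test_that("invalid configurations are rejected at build time", {
  expect_error(modelConfig(dModel = 9L), "even")
  expect_error(modelConfig(dModel = 10L, numHeads = 4L), "divisible")
  expect_error(modelConfig(dropoutRate = 1), "dropoutRate")
  expect_error(modelConfig(nCores = 0L), "nCores")
  expect_error(modelConfig(pooling = "sum"), "pooling")
})

test_that("checkpoints round-trip through save/load", {
  v <- buildVocabulary(2)
  m <- buildModel(v, v, tinyConfig())
  dir <- file.path(tempdir(), "ckpt-test")
  saveModel(m, dir)
  m2 <- loadModel(dir)
  pairs <- tinyPairSet(8, seed = 35)
  tok <- tokenizePairs(pairs, v, tinyConfig())
  expect_identical(predictPairs(m, tok), predictPairs(m2, tok))
  expect_identical(nParams(m2), nParams(m))
  unlink(dir, recursive = TRUE)
})
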