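test_that("normalization uppercases, maps U to T, and rejects bad characters", {
  expect_identical(normalizeSequence("uagu"), "TAGT")
  expect_identical(normalizeSequence("ACGT"), "ACGT")
  expect_identical(normalizeSequence(" ac g\tU "), "ACGT")
  expect_error(normalizeSequence("ACNGT"), "invalid character N at position 3")
  expect_error(normalizeSequence("   "), "empty")
})

test_that("complement is base-wise, order-preserving, and an involution", {
  expect_identical(complementSequence("TAGTTTCT"), "ATCAAAGA")
  expect_identical(complementSequence("AAAA"), "TTTT")
  withr::with_seed(7, {
    for (i in 1:1000) {
      s <- randomSeq(sample(1:40, 1))
      cs <- complementSequence(s)
      expect_identical(nchar(cs), nchar(s))
      expect_identical(complementSequence(cs), s)
    }
  })
})

test_that("hierarchical k-mer enumeration reproduces the worked examples", {
  # the 8-mer example: all windows, grouped by ascending k
  expect_identical(
    extractKmers("GCATTACG", 3),
    c("G", "C", "A", "T", "T", "A", "C", "G",
      "GC", "CA", "AT", "TT", "TA", "AC", "CG",
      "GCA", "CAT", "ATT", "TTA", "TAC", "ACG"))
  expect_identical(
    extractKmers("ATGCA", 3),
    c("A", "T", "G", "C", "A", "AT", "TG", "GC", "CA", "ATG", "TGC", "GCA"))
  expect_identical(
    extractKmers("ATGCA", 3, includeBackward = TRUE),
    c("A", "T", "G", "C", "A",
      "AT", "TA", "TG", "GT", "GC", "CG", "CA", "AC",
      "ATG", "GTA", "TGC", "CGT", "GCA", "ACG"))
  expect_identical(extractKmers("A", 3), "A")
  expect_error(extractKmers("", 3), "non-empty")
})

test_that("forward enumeration equals the brute-force oracle on random cases", {
  withr::with_seed(11, {
    for (i in 1:500) {
      s <- randomSeq(sample(1:30, 1))
      k <- sample(1:4, 1)
      expect_identical(extractKmers(s, k), bruteForceKmers(s, k))
    }
  })
})

test_that("backward list length adds one reversed copy per k-mer longer than 1", {
  withr::with_seed(12, {
    for (i in 1:100) {
      s <- randomSeq(sample(2:25, 1))
      k <- sample(2:4, 1)
      fwd <- extractKmers(s, k)
      bwd <- extractKmers(s, k, includeBackward = TRUE)
      expect_identical(length(bwd), length(fwd) + sum(nchar(fwd) > 1L))
    }
  })
})

test_that("vocabulary is total, bijective, and deterministically ordered", {
  for (k in 1:3) {
    v <- buildVocabulary(k)
    expect_identical(vocabSize(v), as.integer(2 + sum(4^(1:k))))
  }
  v <- buildVocabulary(3)
  expect_identical(vocabSize(v) - 2L, 84L)  # 4 + 16 + 64 content tokens
  ids <- v@tokenIds
  expect_false(anyDuplicated(ids) > 0)
  expect_identical(unname(ids[c("<PAD>", "<UNK>")]), c(0L, 1L))
  # round-trip over every content token
  toks <- setdiff(names(ids), c("<PAD>", "<UNK>"))
  expect_identical(decodeIds(encodeKmers(toks, v), v), toks)
  # two builds agree exactly
  expect_identical(buildVocabulary(3)@tokenIds, ids)
  expect_error(buildVocabulary(0), "1..6")
  expect_error(buildVocabulary(7), "1..6")
})

test_that("encoding preserves order and substitutes <UNK> with a warning", {
  v <- buildVocabulary(2)
  expect_identical(encodeKmers(c("A", "A", "A"), v),
                   rep(encodeKmers("A", v), 3))
  expect_identical(length(encodeKmers(extractKmers("GCATTACG", 2), v)), 15L)
  expect_warning(ids <- encodeKmers(c("A", "XYZ"), v), "1 k-mer")
  expect_identical(ids[2], 1L)
})

test_that("base-pairing k-mers share an id once one side is complemented", {
  v <- buildVocabulary(3)
  # ACG pairs base-wise with TGC; complementing the second side maps it
  # back onto ACG, so both get the same integer
  expect_identical(encodeKmers("ACG", v),
                   encodeKmers(complementSequence("TGC"), v))
  withr::with_seed(13, {
    for (i in 1:50) {
      km <- randomSeq(sample(1:3, 1))
      partner <- complementSequence(km)  # the k-mer that base-pairs with km
      expect_identical(encodeKmers(km, v),
                       encodeKmers(complementSequence(partner), v))
    }
  })
})

test_that("padding truncates tails, masks pads, and row sums match n_real", {
  tb <- padBatch(list(c(5L, 6L, 7L)), 5)
  expect_identical(tb@ids[1, ], c(5L, 6L, 7L, 0L, 0L))
  expect_identical(tb@mask[1, ], c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # already-rectangular input is untouched
  tb2 <- padBatch(list(1:4, 5:8), 4)
  expect_identical(tb2@ids, rbind(1:4, 5:8))
  expect_true(all(tb2@mask))
  expect_message(tb3 <- padBatch(list(1:10, 1:2), 6), "truncated")
  expect_identical(tb3@ids[1, ], 1:6)
  withr::with_seed(14, {
    for (i in 1:100) {
      lens <- sample(1:12, sample(2:6, 1), replace = TRUE)
      maxLen <- sample(1:12, 1)
      streams <- lapply(lens, function(l) sample(2:20, l, replace = TRUE))
      tb <- suppressMessages(padBatch(streams, maxLen))
      expect_identical(unname(rowSums(tb@mask)),
                       as.numeric(pmin(lens, maxLen)))
    }
  })
})

test_that("tokenization is deterministic and the vocabulary serializes", {
  v <- buildVocabulary(2)
  s <- "GCATTACG"
  expect_identical(encodeKmers(extractKmers(s, 2), v),
                   encodeKmers(extractKmers(s, 2), v))
  path <- tempfile(fileext = ".tsv")
  writeVocabulary(v, path)
  v2 <- readVocabulary(path)
  expect_identical(v2@tokenIds, v@tokenIds)
  expect_identical(v2@maxK, v@maxK)
})
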