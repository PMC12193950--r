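# rbpTransformer

Predicts whether a PIWI-interacting RNA (piRNA) and an mRNA fragment
bind, from sequence alone. piRNAs silence transposons and regulate
messages by base-pairing with their targets; given labeled interaction
pairs — e.g. from CLASH-style chimeric-read assays, which yield balanced
sets of binding and non-binding (piRNA, mRNA) pairs — the package trains
a dual-stream attention classifier and reproduces the full evaluation
protocol around it.

## The model in brief

One input (the piRNA by default) is converted to its base-wise
complement, **order preserved** (`TAGTTTCT -> ATCAAAGA`), so a k-mer and
the k-mer it can base-pair with are spelled — and tokenized —
identically. Both sequences are then decomposed into hierarchical k-mers
(all windows of length 1..k, grouped by ascending k), encoded against a
total k-mer vocabulary, padded and masked.

Each stream is embedded and summed with the sinusoidal positional
encoding

    PE(pos, 2i)   = sin(pos / 10000^(2i/d_model))
    PE(pos, 2i+1) = cos(pos / 10000^(2i/d_model))

and passed through N cascadable **core** blocks: self-attention on each
stream, cross-attention (piRNA queries against mRNA keys/values,
`softmax(QK'/sqrt(d_k) + M) V` with a padding-only mask — no look-ahead
mask), and a position-wise dense projection, each step followed by
add-&-layer-normalize. The final query stream is pooled over its real
tokens, passed through dropout and three dense layers, and a sigmoid
emits the binding probability. The network, its hand-derived
backpropagation (verified against finite differences in the test suite)
and the six-optimizer menu (RMSProp, Adam, SGD, Adagrad, Nadam, Adamax)
are implemented in R matrix code with compiled attention kernels — no
external deep-learning framework.

The protocol utilities implement stratified 60/20/20 splits, repeated
random-split cross-validation with an "Average" row, an ablation grid
over core number x maximum k-mer size, and readers/writers for the
pair-TSV dialect (`pirna<TAB>mrna<TAB>label`) and paired FASTA. A
synthetic generator emulates CLASH-like data with a planted
complementary seed region and ships with an exact brute-force oracle, so
the whole stack is testable offline.

## Worked example

```r
library(rbpTransformer)

# tokenization
extractKmers("ATGCA", 3)
#>  [1] "A"   "T"   "G"   "C"   "A"   "AT"  "TG"  "GC"  "CA"  "ATG" "TGC" "GCA"

# synthetic CLASH-like pairs: 21-nt piRNAs vs 60-nt mRNA fragments,
# positives carry a perfect 10-nt planted complementary region
cfg   <- syntheticConfig(nPairs = 6000, seedLen = 10, seed = 1)
pairs <- generateDataset(cfg)
mean(oracleClassify(pairs, runThreshold = 10) == pairs$label)
#> [1] 1

# 60/20/20 protocol, small dual-stream model, RMSProp
sp    <- splitDataset(pairs, splitSpec(seed = 1))
vocab <- buildVocabulary(2)
mcfg  <- modelConfig(dModel = 32, numHeads = 2, dDense = 64, nCores = 1,
                     maxK = 2, headWidths = c(32, 16, 1), seed = 1)
model <- buildModel(vocab, vocab, mcfg)
model
#> RbpTransformer: 1 core(s), d_model=32, 2 head(s), maxK=2
#>   self-attention: TRUE | backward k-mers: FALSE | pooling: global_average
#>   trainable parameters: 20129 | trained: FALSE

model <- trainModel(model, tokenizePairs(sp$train, vocab, mcfg),
                    tokenizePairs(sp$val, vocab, mcfg),
                    trainConfig(optimizer = "rmsprop", learningRate = 0.003,
                                batchSize = 32, maxEpochs = 10,
                                objective = "auc", seed = 1))
evaluateModel(model, tokenizePairs(sp$test, vocab, mcfg))
#> EvalReport (cores=1 maxK=2 dModel=32 heads=2 selfAttn=TRUE; n = 1200, threshold = 0.50)
#>   precision 0.500 | recall 1.000 | F1 0.667 | accuracy 0.500 | AUC 0.502
#>      predicted
#> truth   1 0
#>     1 600 0
#>     0 600 0
```

The report prints precision, recall, F1, accuracy at threshold 0.5, the
threshold-free AUC, and the 2x2 confusion matrix. Note what this example
shows: `oracleClassify()` certifies that the generated classes are
*perfectly* separable by the planted rule, while the network itself stays
near chance at this desk scale — the complement conversion makes the
synthetic classes differ only relationally (a shared substring, with no
compositional signal), and the matching circuit that detects such a rule
needs far more optimizer updates than a ten-epoch CPU budget provides.
The methods vignette discusses this benchmark property in detail; on real
interaction data, which carry abundant first-order sequence signals, the
training dynamics are a different matter.

A thin command-line launcher over the same functions is bundled:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/rbptransformer.R", package="rbpTransformer"))') \
    simulate --n-pairs 1000 --seed 7 --out pairs.tsv
```

(subcommands: `tokenize`, `simulate`, `train`, `evaluate`, `cv`, `grid`,
`ablate`).

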