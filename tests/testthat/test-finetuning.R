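test_that("attention pooling matches the softmax(w' tanh(h)) closed forms", {
  ## singleton: alpha = 1, pooled = the row
  h1 <- matrix(rnorm(8), 1)
  p1 <- attentionPool(h1, rnorm(8))
  expect_equal(p1@alpha, 1)
  expect_equal(p1@pooled, as.vector(h1))

  ## identical rows: uniform weights
  H <- matrix(rep(rnorm(6), each = 5), 5)
  pU <- attentionPool(H, rnorm(6))
  expect_equal(pU@alpha, rep(0.2, 5), tolerance = 1e-12)

  ## d = 1 worked example: rows 0 and 1, w = 1
  Hw <- matrix(c(0, 1), 2, 1)
  pw <- attentionPool(Hw, 1)
  s <- c(tanh(0), tanh(1))
  alphaRef <- exp(s) / sum(exp(s))
  expect_equal(pw@alpha, alphaRef, tolerance = 1e-6)
  expect_equal(pw@alpha[2], 0.6816, tolerance = 1e-3)
  expect_equal(pw@pooled, sum(alphaRef * c(0, 1)), tolerance = 1e-6)

  expect_error(attentionPool(matrix(0, 0, 3), rnorm(3)), "at least one")
})

test_that("alpha is a strict simplex vector and pooling stays in the hull", {
  for (seed in 1:20) {
    H <- withLocalSeed(seed, matrix(rnorm(7 * 5, 0, 3), 7))
    w <- withLocalSeed(seed + 100, rnorm(5))
    p <- attentionPool(H, w)
    expect_equal(sum(p@alpha), 1, tolerance = 1e-6)
    expect_true(all(p@alpha > 0))
    ## convex combination: pooled within the row-wise min/max box
    expect_true(all(p@pooled >= apply(H, 2, min) - 1e-12))
    expect_true(all(p@pooled <= apply(H, 2, max) + 1e-12))
  }
})

test_that("prediction is deterministic, bounded, and modality-strict", {
  rec <- fixCorpus[[5]]
  pr <- predictMolecule(rec, tinyParams, fixVocab, tinyBB)
  expect_gte(pr, 0); expect_lte(pr, 1)
  expect_identical(pr, predictMolecule(rec, tinyParams, fixVocab, tinyBB))
  for (r in fixCorpus[1:6]) {
    p <- predictMolecule(r, tinyParams, fixVocab, tinyBB, use3d = TRUE)
    expect_gte(p, 0); expect_lte(p, 1)
  }
  noConf <- moleculeRecord("nc", "CCO")
  expect_error(predictMolecule(noConf, tinyParams, fixVocab, tinyBB,
                               use3d = TRUE), "conformer")
})

test_that("attention export equals the pooling weights of the same pass", {
  rec <- fixCorpus[[6]]
  att <- exportSubstructureAttention(rec, tinyParams, fixVocab, tinyBB,
                                     use3d = TRUE)
  tok <- tokenizeSmiles(molSmiles(rec), fixVocab)
  e <- length(fragments(tok)); n <- tok@nAtoms
  expect_equal(nrow(att), e + 2L * n)
  expect_equal(sum(att$alpha), 1, tolerance = 1e-6)
  expect_identical(att$modality, c(rep("1D", e), rep("2D", n), rep("3D", n)))
  expect_identical(att$label[seq_len(e)], fragments(tok))

  ## exactly the alpha of attentionPool on the same fused rows
  prep <- prepareCorpus(list(rec), fixVocab, NULL)[[1]]
  tp <- newTape(tinyParams)
  fw <- molfuse:::forwardPoolT(tp, prep, tinyBB, use3d = TRUE)
  H <- nodeValue(tp, fw$fused)
  ref <- attentionPool(H, as.vector(tinyParams[["head.watt"]]))
  expect_equal(att$alpha, ref@alpha, tolerance = 1e-12)

  att2 <- exportSubstructureAttention(rec, tinyParams, fixVocab, tinyBB,
                                      use3d = FALSE)
  expect_equal(nrow(att2), e + n)
})

test_that("AUROC agrees with the exhaustive pairwise oracle", {
  labels <- c(0, 0, 1, 1)
  scores <- c(0.1, 0.6, 0.4, 0.9)
  ## oracle: fraction of (pos, neg) pairs ranked correctly, ties = 1/2
  pairAuc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(aurocScore(labels, scores), pairAuc(labels, scores))
  expect_equal(aurocScore(labels, scores), 0.75)
  expect_equal(aurocScore(c(0, 1), c(0.2, 0.8)), 1)
  expect_true(is.na(aurocScore(c(1, 1), c(0.2, 0.8))))
  for (seed in 1:10) {
    y <- withLocalSeed(seed, rbinom(12, 1, 0.5))
    if (length(unique(y)) < 2) next
    s <- withLocalSeed(seed + 50, runif(12))
    expect_equal(aurocScore(y, s), pairAuc(y, s), tolerance = 1e-12)
  }
})

test_that("zero-epoch fine-tuning reports the frozen checkpoint metrics", {
  recs <- fixCorpus[1:10]
  split <- new("DatasetSplit",
               train = vapply(recs[1:6], molId, character(1)),
               valid = vapply(recs[7:8], molId, character(1)),
               test = vapply(recs[9:10], molId, character(1)))
  ckpt <- new("Checkpoint", params = tinyParams,
              config = pretrainConfig(seed = 1L, backbone = tinyBB),
              vocabFingerprint = fixVocab@fingerprint, step = 0L)
  ft <- finetuneConfig("classification", "halogenated", epochs = 0L,
                       seed = 4L)
  res <- runFinetune(recs, split, ckpt, fixVocab, ft)
  expect_identical(res$params, tinyParams)
  ## test metric equals a direct forward-pass evaluation
  direct <- vapply(recs[9:10], function(r)
    predictMolecule(r, tinyParams, fixVocab, tinyBB), numeric(1))
  y <- vapply(recs[9:10], function(r) molLabels(r)$halogenated, numeric(1))
  expect_equal(res$report$testMetric, aurocScore(y, direct))
  expect_error(runFinetune(recs, split, ckpt, fixVocab,
                           finetuneConfig("classification", "absent",
                                          epochs = 0L, seed = 1L)),
               "missing")
})

test_that("head-only training moves only head parameters", {
  recs <- fixCorpus[1:6]
  ids <- vapply(recs, molId, character(1))
  split <- new("DatasetSplit", train = ids, valid = character(0),
               test = character(0))
  ckpt <- new("Checkpoint", params = tinyParams,
              config = pretrainConfig(seed = 1L, backbone = tinyBB),
              vocabFingerprint = fixVocab@fingerprint, step = 0L)
  ft <- finetuneConfig("classification", "halogenated", epochs = 1L,
                       seed = 4L, freezeEncoders = TRUE)
  res <- runFinetune(recs, split, ckpt, fixVocab, ft)
  for (nm in names(tinyParams)) {
    if (startsWith(nm, "head.")) next
    expect_identical(res$params[[nm]], tinyParams[[nm]])
  }
  expect_false(identical(res$params[["head.W1"]], tinyParams[["head.W1"]]))
})
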