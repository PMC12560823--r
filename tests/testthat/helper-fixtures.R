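## Shared fixtures, built once per test run. Everything is generated in
## code; nothing is read from disk.

## internal machinery exercised directly by the tests
newTape <- molfuse:::newTape
adParam <- molfuse:::adParam
adConst <- molfuse:::adConst
backward <- molfuse:::backward
nodeValue <- molfuse:::nodeValue
loss1dCeT <- molfuse:::loss1dCeT
loss2dSceT <- molfuse:::loss2dSceT
loss3dMseT <- molfuse:::loss3dMseT
loss3dCosT <- molfuse:::loss3dCosT
withLocalSeed <- molfuse:::withLocalSeed
parseSmiles <- molfuse:::parseSmiles
attentionPoolT <- molfuse:::attentionPoolT
prepareCorpus <- molfuse:::prepareCorpus

## permute a graph's atoms: new atom k is old atom perm[k]
permuteGraph <- function(g, perm) {
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  ed <- g@edges
  new("MolecularGraph", n = g@n,
      nodeFeatures = g@nodeFeatures[perm, , drop = FALSE],
      edges = cbind(inv[ed[, 1]], inv[ed[, 2]]),
      edgeFeatures = g@edgeFeatures,
      symbols = g@symbols[perm])
}

fixCorpus <- generateFixtureSet(24, seed = 42)
fixSmiles <- vapply(fixCorpus, molSmiles, character(1))
fixVocab <- buildVocab(fixSmiles, minFrequency = 2L, maxSize = 30L)

## a tiny backbone everything structural can run on quickly
tinyBB <- backboneConfig(d = 16L, n1dLayers = 1L, nHeads = 2L,
                         n2dLayers = 2L, n3dBlocks = 1L, nRbf = 4L,
                         nAbf = 3L, cutoff = 5, nFusionBlocks = 1L,
                         maxLen = 64L)
tinyParams <- initBackbone(tinyBB, fixVocab, seed = 7L)

## vocabulary with no merges: tokenization at atom level (e = n), handy for
## controlling fragment counts exactly
atomVocab <- buildVocab(c("C", "N", "O"), minFrequency = 99L, maxSize = 10L)

## ten molecules with ten distinct Bemis-Murcko scaffolds
tenScaffoldSmiles <- c("Cc1ccccc1", "c1ccncc1", "C1CCCCC1", "C1CCCC1",
                       "c1ccc2ccccc2c1", "C1CC1", "C1CCC1", "c1ccoc1",
                       "c1ccsc1", "C1CCNCC1")
tenScaffoldRecords <- lapply(seq_along(tenScaffoldSmiles), function(i)
  moleculeRecord(sprintf("scf%02d", i), tenScaffoldSmiles[i]))

## finite-difference gradient of a scalar-valued tape computation with
## respect to selected parameter entries
fdGrad <- function(lossFn, params, pname, entries, h = 1e-6) {
  vapply(entries, function(i) {
    p <- params; p[[pname]][i] <- p[[pname]][i] + h
    up <- lossFn(p)
    p[[pname]][i] <- p[[pname]][i] - 2 * h
    dn <- lossFn(p)
    (up - dn) / (2 * h)
  }, numeric(1))
}
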