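## A five-fragment molecule under the atom-level vocabulary (no merges)
tokE5 <- tokenizeSmiles("CCCCC", atomVocab)

test_that("selection counts follow the floor/availability law in order", {
  tok <- tokenizeSmiles(fixSmiles[1], fixVocab)
  p0 <- planPerturbation(tok, perturbRatios(0, 0, 0), seed = 1)
  expect_length(p0@sel1d, 0L); expect_length(p0@sel2d, 0L)
  expect_length(p0@sel3d, 0L)

  ## e = 3, ratios 1/3 each: one index per modality, all distinct
  tok3 <- tokenizeSmiles("CCO", atomVocab)
  p3 <- planPerturbation(tok3, perturbRatios(1/3, 1/3, 1/3), seed = 5)
  expect_length(p3@sel1d, 1L); expect_length(p3@sel2d, 1L)
  expect_length(p3@sel3d, 1L)
  expect_setequal(c(p3@sel1d, p3@sel2d, p3@sel3d), 1:3)

  ## oversubscribed ratios truncate by availability
  pf <- planPerturbation(tokE5, perturbRatios(1, 1, 1), seed = 2)
  expect_length(pf@sel1d, 5L)
  expect_length(pf@sel2d, 0L)
  expect_length(pf@sel3d, 0L)
})

test_that("plans are disjoint, deterministic and uniformly distributed", {
  ## non-overlap + count law over many random cases
  for (seed in 1:250) {
    tok <- tokenizeSmiles(fixSmiles[(seed %% length(fixSmiles)) + 1L],
                          fixVocab)
    e <- length(fragments(tok))
    r <- withLocalSeed(seed, runif(3, 0, 0.6))
    pl <- planPerturbation(tok, perturbRatios(r[1], r[2], r[3]), seed)
    sel <- c(pl@sel1d, pl@sel2d, pl@sel3d)
    expect_equal(anyDuplicated(sel), 0L)
    avail <- e; ks <- integer(3)
    for (j in 1:3) {
      ks[j] <- min(floor(r[j] * e), avail)
      avail <- avail - ks[j]
    }
    expect_length(pl@sel1d, ks[1])
    expect_length(pl@sel2d, ks[2])
    expect_length(pl@sel3d, ks[3])
  }
  expect_identical(planPerturbation(tokE5, perturbRatios(), 77),
                   planPerturbation(tokE5, perturbRatios(), 77))
})

test_that("1D selection is uniform over substructures (frequency oracle)", {
  ## e = 5, r1d = 0.2: one of five indices per seed, P(i) = 0.2 each
  nSeeds <- 10000L
  counts <- integer(5)
  for (s in seq_len(nSeeds)) {
    pl <- planPerturbation(tokE5, perturbRatios(0.2, 0, 0), s)
    counts[pl@sel1d] <- counts[pl@sel1d] + 1L
  }
  tol <- 3 * sqrt(0.2 * 0.8 / nSeeds)
  expect_true(all(abs(counts / nSeeds - 0.2) <= tol))
})

test_that("1D masking touches exactly the selected positions", {
  tok <- tokenizeSmiles(fixSmiles[2], fixVocab)
  plEmpty <- planPerturbation(tok, perturbRatios(0, 0, 0), 1)
  expect_identical(apply1d(tok, plEmpty, fixVocab)$tokens, tokenIds(tok))

  tok5 <- tokE5
  pl <- new("PerturbationPlan", sel1d = 2L, sel2d = integer(0),
            sel3d = integer(0), seed = 0L)
  out <- apply1d(tok5, pl, atomVocab)
  expect_identical(out$tokens[2L], atomVocab@specialIds[["mask"]])
  expect_identical(out$tokens[-2L], tokenIds(tok5)[-2L])
  expect_identical(out$mask, 2L)

  for (s in 1:50) {
    pl <- planPerturbation(tok, perturbRatios(0.4, 0.2, 0.2), s)
    out <- apply1d(tok, pl, fixVocab)
    keep <- setdiff(seq_along(tokenIds(tok)), pl@sel1d)
    expect_identical(out$tokens[keep], tokenIds(tok)[keep])
  }
})

test_that("2D masking replaces exactly the covered feature rows", {
  rec <- fixCorpus[[3]]
  tok <- tokenizeSmiles(molSmiles(rec), fixVocab)
  g <- moleculeGraph(rec)
  plEmpty <- planPerturbation(tok, perturbRatios(0, 0, 0), 1)
  expect_identical(apply2d(g, tok, plEmpty)$graph@nodeFeatures,
                   g@nodeFeatures)
  pl <- planPerturbation(tok, perturbRatios(0, 0.5, 0), 3)
  out <- apply2d(g, tok, pl)
  atoms <- atomsOfSubstructures(tok, pl@sel2d)
  expect_identical(out$maskedAtoms, atoms)
  nf <- out$graph@nodeFeatures
  maskRow <- c(rep(0, molfuse:::NODE_FEATURE_DIM - 1L), 1)
  for (a in atoms) expect_equal(unname(nf[a, ]), maskRow)
  keep <- setdiff(seq_len(g@n), atoms)
  expect_identical(nf[keep, ], g@nodeFeatures[keep, ])
  expect_identical(out$graph@edges, g@edges)
  expect_identical(out$graph@edgeFeatures, g@edgeFeatures)
})

test_that("3D noising is local, deterministic and moment-correct", {
  rec <- fixCorpus[[1]]
  tok <- tokenizeSmiles(molSmiles(rec), fixVocab)
  coords <- molConformer(rec)
  plEmpty <- planPerturbation(tok, perturbRatios(0, 0, 0), 1)
  expect_identical(apply3d(coords, tok, plEmpty, 0.1, 9)$coords, coords)
  pl <- planPerturbation(tok, perturbRatios(0, 0, 0.5), 4)
  expect_identical(apply3d(coords, tok, pl, 0, 9)$coords, coords)
  out <- apply3d(coords, tok, pl, 0.1, 9)
  atoms <- out$noisedAtoms
  keep <- setdiff(seq_len(nrow(coords)), atoms)
  expect_identical(out$coords[keep, ], coords[keep, ])
  expect_false(any(out$coords[atoms, ] == coords[atoms, ]))
  expect_identical(out$coords, apply3d(coords, tok, pl, 0.1, 9)$coords)
  expect_error(apply3d(coords, tok, pl, -1, 9), "nonnegative")

  ## moment oracle: one atom, sigma = 0.1, many seeds
  tok1 <- tokenizeSmiles("C", atomVocab)
  c1 <- matrix(0, 1, 3)
  pl1 <- new("PerturbationPlan", sel1d = integer(0), sel2d = integer(0),
             sel3d = 1L, seed = 0L)
  disp <- t(vapply(seq_len(10000L), function(s)
    apply3d(c1, tok1, pl1, 0.1, s)$coords[1, ], numeric(3)))
  expect_true(all(abs(colMeans(disp)) <= 3 * 0.1 / sqrt(10000)))
  expect_true(all(abs(apply(disp, 2, var) - 0.01) <= 0.05 * 0.01))
})

test_that("perturbMolecule assembles consistent views", {
  rec <- fixCorpus[[2]]
  tok <- tokenizeSmiles(molSmiles(rec), fixVocab)
  pv <- perturbMolecule(rec, tok, fixVocab, perturbRatios(0.4, 0.3, 0.3),
                        sigma = 0.1, seed = 11)
  expect_identical(pv@mask1d, sort(pv@mask1d))
  expect_length(pv@mask1d, sum(pv@tokensMasked == fixVocab@specialIds[["mask"]]))
  expect_identical(pv@maskedAtoms,
                   which(pv@graphMasked@nodeFeatures[, molfuse:::NODE_FEATURE_DIM] == 1))
  pv2 <- perturbMolecule(rec, tok, fixVocab, perturbRatios(0.4, 0.3, 0.3),
                         sigma = 0.1, seed = 11)
  expect_identical(pv@coordsNoised, pv2@coordsNoised)
  expect_identical(pv@tokensMasked, pv2@tokensMasked)
})
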