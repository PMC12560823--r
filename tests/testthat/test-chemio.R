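test_that("CSV reading builds one record per row and rejects bad SMILES", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,activity", "C,1", "CCO,0"), tf)
  recs <- readSmilesTable(tf, "smiles", "activity")
  expect_length(recs, 2L)
  expect_equal(molLabels(recs[[1]])$activity, 1)
  expect_equal(molSmiles(recs[[2]]), "CCO")

  writeLines(c("smiles,activity", "C,1", "notasmiles,0", "CCO,1"), tf)
  expect_warning(recs <- readSmilesTable(tf, "smiles", "activity"),
                 "rows 2")
  expect_length(recs, 2L)

  ## duplicate SMILES stay distinct records with distinct ids
  writeLines(c("smiles", "CC", "CC"), tf)
  recs <- suppressWarnings(readSmilesTable(tf, "smiles"))
  expect_length(recs, 2L)
  expect_false(molId(recs[[1]]) == molId(recs[[2]]))

  expect_error(readSmilesTable(tf, "nope"), "not present")
  writeLines(c("smiles", "junkrow!"), tf)
  expect_error(suppressWarnings(readSmilesTable(tf, "smiles")), "no valid")
})

test_that("SDF reading attaches block coordinates; round trip preserves them", {
  ## methane with explicit hydrogens: 5 atoms, coords kept as read
  block <- c("methane", "  test", "",
             "  5  4  0  0  0  0  0  0  0  0999 V2000",
             "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
             "    0.6300    0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
             "   -0.6300   -0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
             "   -0.6300    0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
             "    0.6300   -0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
             "  1  2  1  0  0  0  0", "  1  3  1  0  0  0  0",
             "  1  4  1  0  0  0  0", "  1  5  1  0  0  0  0",
             "M  END", "$$$$")
  tf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(block, tf)
  recs <- readSDF(tf)
  expect_length(recs, 1L)
  expect_equal(dim(recs[[1]]@coords), c(5L, 3L))      # explicit H retained
  expect_equal(dim(molConformer(recs[[1]])), c(1L, 3L))  # heavy atoms only

  writeLines("", tf)
  expect_length(readSDF(tf), 0L)

  ## write-then-read round trip: coordinates to SDF precision (4 dp)
  fx <- generateFixtureSet(6, seed = 5)
  writeSDF(fx, tf)
  back <- readSDF(tf)
  expect_length(back, 6L)
  for (i in seq_along(fx)) {
    expect_identical(molSmiles(back[[i]]), molSmiles(fx[[i]]))
    expect_lt(max(abs(molConformer(back[[i]]) - molConformer(fx[[i]]))),
              1e-4 + 1e-8)
  }
})

test_that("fixture generation is deterministic and emits valid molecules", {
  expect_length(generateFixtureSet(0, seed = 1), 0L)
  a <- generateFixtureSet(10, seed = 3)
  b <- generateFixtureSet(10, seed = 3)
  expect_identical(vapply(a, molSmiles, ""), vapply(b, molSmiles, ""))
  expect_identical(lapply(a, molConformer), lapply(b, molConformer))
  d <- generateFixtureSet(10, seed = 4)
  expect_false(identical(vapply(a, molSmiles, ""), vapply(d, molSmiles, "")))
  ## every SMILES re-parses and round-trips to the same canonical form
  for (r in a) {
    expect_identical(canonicalSmiles(molSmiles(r)), molSmiles(r))
    n <- nrow(parseSmiles(molSmiles(r))$atoms)
    expect_gte(n, 3L); expect_lte(n, 20L)
    expect_equal(nrow(molConformer(r)), n)
    expect_true(all(is.finite(molConformer(r))))
  }
})

test_that("scaffold split follows the greedy-fill rule and is scaffold-pure", {
  sp <- scaffoldSplit(tenScaffoldRecords, c(0.8, 0.1, 0.1))
  expect_length(trainIds(sp), 8L)
  expect_length(validIds(sp), 1L)
  expect_length(testIds(sp), 1L)

  ## all one scaffold: indivisible group goes to train, warning emitted
  one <- lapply(1:5, function(i)
    moleculeRecord(sprintf("b%d", i), "c1ccccc1"))
  expect_warning(sp1 <- scaffoldSplit(one), "empty")
  expect_length(trainIds(sp1), 5L)
  expect_length(validIds(sp1), 0L)

  expect_error(scaffoldSplit(list()), "empty")
  expect_error(scaffoldSplit(tenScaffoldRecords, c(0.5, 0.5, 0.5)),
               "fractions")
})

test_that("splits are disjoint, exhaustive and scaffold-pure on random sets", {
  for (seed in c(11, 12, 13)) {
    recs <- generateFixtureSet(30, seed = seed, withConformers = FALSE)
    sp <- suppressWarnings(scaffoldSplit(recs))
    ids <- vapply(recs, molId, character(1))
    got <- c(trainIds(sp), validIds(sp), testIds(sp))
    expect_setequal(got, ids)
    expect_equal(anyDuplicated(got), 0L)
    keys <- vapply(recs, function(r) murckoScaffold(molSmiles(r)),
                   character(1))
    names(keys) <- ids
    for (part in list(trainIds(sp), validIds(sp), testIds(sp)))
      for (other in list(trainIds(sp), validIds(sp), testIds(sp)))
        if (!identical(part, other))
          expect_length(intersect(keys[part], keys[other]), 0L)
  }
})

test_that("split JSON round-trips", {
  sp <- scaffoldSplit(tenScaffoldRecords)
  tf <- withr::local_tempfile(fileext = ".json")
  writeSplit(sp, tf)
  sp2 <- readSplit(tf)
  expect_identical(trainIds(sp), trainIds(sp2))
  expect_identical(validIds(sp), validIds(sp2))
  expect_identical(testIds(sp), testIds(sp2))
})

test_that("acyclic molecules group by their own canonical SMILES", {
  expect_identical(murckoScaffold("CCO"), canonicalSmiles("CCO"))
  expect_identical(murckoScaffold("Cc1ccccc1"), canonicalSmiles("c1ccccc1"))
  ## shared benzene scaffold regardless of substituent
  expect_identical(murckoScaffold("CCc1ccccc1"), murckoScaffold("Oc1ccccc1"))
})
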