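## Readers/writers for molecular inputs, deterministic synthetic fixtures,
## and scaffold-based dataset splitting.

#' Construct a MoleculeRecord from a SMILES string
#'
#' The SMILES is canonicalized once here; all downstream modules (tokenizer,
#' graph builder, conformer alignment) work in the canonical-parse atom
#' order, which keeps atom indices consistent across the 1D/2D/3D views.
#'
#' @param id molecule identifier.
#' @param smiles SMILES string (any valid form; canonicalized internally).
#' @param labels optional named list of task labels.
#' @param coords optional n x 3 conformer matrix in canonical-parse atom
#'   order (n = heavy atom count).
#' @return a \linkS4class{MoleculeRecord}.
#' @export
moleculeRecord <- function(id, smiles, labels = list(), coords = NULL) {
  can <- canonicalSmiles(smiles)
  if (is.na(can)) stopf("invalid SMILES for record '%s': %s", id, smiles)
  n <- nrow(parseSmiles(can)$atoms)
  if (is.null(coords)) {
    coords <- matrix(numeric(0), 0L, 3L)
    heavyIdx <- integer(0)
  } else {
    coords <- as.matrix(coords)
    if (nrow(coords) != n)
      stopf("conformer has %d rows but molecule has %d heavy atoms",
            nrow(coords), n)
    heavyIdx <- seq_len(n)
  }
  new("MoleculeRecord", id = as.character(id), smiles = can,
      labels = labels, coords = coords, heavyIdx = heavyIdx)
}

#' Build the attributed heavy-atom graph of a molecule
#'
#' @param x a \linkS4class{MoleculeRecord} or a canonical SMILES string.
#' @return a \linkS4class{MolecularGraph}.
#' @export
moleculeGraph <- function(x) {
  s <- if (is(x, "MoleculeRecord")) molSmiles(x) else x
  parsed <- parseSmiles(s)
  new("MolecularGraph",
      n = nrow(parsed$atoms),
      nodeFeatures = nodeFeatureMatrix(parsed),
      edges = cbind(parsed$bonds$a1, parsed$bonds$a2),
      edgeFeatures = edgeFeatureMatrix(parsed),
      symbols = parsed$atoms$symbol)
}

#' Read molecules and labels from a CSV table
#'
#' Rows whose SMILES do not parse are skipped with a warning reporting the
#' offending row numbers.
#'
#' @param path CSV file with a header row.
#' @param smilesColumn name of the SMILES column.
#' @param labelColumns character vector of label column names.
#' @return list of \linkS4class{MoleculeRecord}.
#' @export
readSmilesTable <- function(path, smilesColumn = "smiles",
                            labelColumns = character(0)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c(smilesColumn, labelColumns), names(tab))
  if (length(missing))
    stopf("column(s) not present in %s: %s", path,
          paste(missing, collapse = ", "))
  cans <- canonicalSmiles(tab[[smilesColumn]])
  bad <- which(is.na(cans))
  if (length(bad))
    warnf("skipping %d row(s) with unparseable SMILES: rows %s",
          length(bad), paste(bad, collapse = ", "))
  keep <- which(!is.na(cans))
  if (!length(keep)) stopf("no valid SMILES rows in %s", path)
  lapply(keep, function(i) {
    labels <- lapply(labelColumns, function(cn) tab[[cn]][i])
    names(labels) <- labelColumns
    moleculeRecord(sprintf("mol%05d", i), cans[i], labels = labels)
  })
}

## Extract symbols/coords/bonds from one ChemmineR SDF entry.
sdfEntryToGraph <- function(entry) {
  ab <- ChemmineR::atomblock(entry)
  bb <- ChemmineR::bondblock(entry)
  syms <- sub("_[0-9]+$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0),
               aromatic = logical(0))
  } else {
    type <- as.numeric(bb[, 3L])
    data.frame(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]),
               order = ifelse(type == 4, 1.5, type),
               aromatic = type == 4)
  }
  list(symbols = syms, coords = coords, bonds = bonds)
}

#' Read molecules with conformers from an SDF (V2000) file
#'
#' Each molfile block yields a record whose conformer holds the block's
#' coordinates. Coordinates are stored in block order; the heavy atoms are
#' matched onto the canonical-SMILES atom order by a deterministic subgraph
#' isomorphism, so \code{\link{molConformer}} returns coordinates aligned
#' with the tokenizer and graph builder. Malformed blocks are skipped with a
#' warning.
#'
#' @param path SDF file path.
#' @return list of \linkS4class{MoleculeRecord}.
#' @export
readSDF <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0L ||
      !any(nzchar(trimws(readLines(path, warn = FALSE)))))
    return(list())
  sdfset <- ChemmineR::read.SDFset(path)
  out <- list()
  for (k in seq_along(sdfset)) {
    rec <- tryCatch({
      g <- sdfEntryToGraph(sdfset[[k]])
      heavy <- which(g$symbols != "H")
      if (!length(heavy)) stop("no heavy atoms")
      ## induced heavy-atom graph in SDF order
      hmap <- match(seq_along(g$symbols), heavy)
      hb <- g$bonds[g$symbols[g$bonds$a1] != "H" &
                    g$symbols[g$bonds$a2] != "H", , drop = FALSE]
      hb$a1 <- hmap[hb$a1]; hb$a2 <- hmap[hb$a2]
      pseudo <- list(
        atoms = data.frame(symbol = g$symbols[heavy],
                           aromatic = vapply(seq_along(heavy), function(i)
                             any(hb$aromatic[hb$a1 == i | hb$a2 == i]),
                             logical(1)),
                           charge = 0L, token = g$symbols[heavy],
                           start = seq_along(heavy),
                           stringsAsFactors = FALSE),
        bonds = hb)
      raw <- writeSmilesGraph(pseudo)$smiles
      can <- canonicalSmiles(raw)
      if (is.na(can)) stop("could not canonicalize connection table")
      cp <- parseSmiles(can)
      map <- matchAtoms(cp$atoms$symbol, cp$bonds,
                        pseudo$atoms$symbol, pseudo$bonds)
      if (is.null(map)) stop("atom order could not be matched")
      new("MoleculeRecord", id = sprintf("sdf%05d", k), smiles = can,
          labels = list(), coords = g$coords,
          heavyIdx = heavy[map])
    }, error = function(e) {
      warnf("skipping SDF block %d: %s", k, conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  out
}

#' Write records with conformers to an SDF (V2000) file
#'
#' Atoms are written in canonical-parse order with their heavy-atom
#' coordinates, bonds from the parsed SMILES (aromatic bonds as type 4).
#'
#' @param records list of \linkS4class{MoleculeRecord} with conformers.
#' @param path output file path.
#' @export
writeSDF <- function(records, path) {
  lines <- character(0)
  for (rec in records) {
    coords <- molConformer(rec)
    if (is.null(coords))
      stopf("record '%s' has no conformer", molId(rec))
    parsed <- parseSmiles(molSmiles(rec))
    n <- nrow(parsed$atoms); m <- nrow(parsed$bonds)
    lines <- c(lines,
      molId(rec), "  molfuse", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              coords[, 1L], coords[, 2L], coords[, 3L],
              parsed$atoms$symbol),
      if (m > 0L) sprintf("%3d%3d%3d  0  0  0  0", parsed$bonds$a1,
                          parsed$bonds$a2,
                          ifelse(parsed$bonds$aromatic, 4L,
                                 as.integer(parsed$bonds$order))),
      "M  END", "$$$$")
  }
  writeLines(lines, path)
  invisible(path)
}

## Deterministic 3D embedding: seeded random initialization relaxed by
## gradient steps on a spring energy (bonded pairs pulled to type-specific
## lengths, non-bonded pairs repelled below 2.2 A). This produces plausible
## desk-scale geometry, not a physical conformer ensemble.
embedConformer <- function(parsed, seed, iters = 250L) {
  n <- nrow(parsed$atoms)
  bd <- parsed$bonds
  target <- ifelse(bd$order == 1.5, 1.39,
            ifelse(bd$order == 2, 1.34,
            ifelse(bd$order == 3, 1.20, 1.50)))
  x <- withLocalSeed(seed, matrix(runif(n * 3L, -1, 1) * max(1, n^(1/3)),
                                  n, 3L))
  if (n == 1L) return(x * 0)
  lr <- 0.08
  for (it in seq_len(iters)) {
    grad <- matrix(0, n, 3L)
    for (e in seq_len(nrow(bd))) {
      i <- bd$a1[e]; j <- bd$a2[e]
      dv <- x[i, ] - x[j, ]
      d <- sqrt(sum(dv^2)) + 1e-9
      g <- (d - target[e]) * dv / d
      grad[i, ] <- grad[i, ] + g
      grad[j, ] <- grad[j, ] - g
    }
    dm <- as.matrix(dist(x))
    close <- which(dm < 2.2 & upper.tri(dm), arr.ind = TRUE)
    bonded <- paste(pmin(bd$a1, bd$a2), pmax(bd$a1, bd$a2))
    for (r in seq_len(nrow(close))) {
      i <- close[r, 1L]; j <- close[r, 2L]
      if (paste(min(i, j), max(i, j)) %in% bonded) next
      dv <- x[i, ] - x[j, ]
      d <- sqrt(sum(dv^2)) + 1e-9
      g <- 0.5 * (d - 2.2) * dv / d
      grad[i, ] <- grad[i, ] + g
      grad[j, ] <- grad[j, ] - g
    }
    x <- x - lr * grad
  }
  sweep(x, 2L, colMeans(x))
}

## Template families for synthetic fixtures. Acyclic molecules are built by
## a compositional chain generator that interleaves C/O/N backbone atoms
## with carbonyl and halogen decorations (ethers, alcohols, amines, amides,
## esters, ketones, halogenated variants); ring families add aromatic and
## heteroaromatic systems. The heteroatom diversity mirrors drug-like
## corpora and keeps the substructure vocabulary from collapsing whole
## molecules into single fragments. Sizes span 3-20 heavy atoms.
randomChainSmiles <- function(k, haloProb = 0.5) {
  atoms <- character(k)
  prevHet <- TRUE                         # never start with O/N adjacency
  for (i in seq_len(k)) {
    a <- if (prevHet) "C" else sample(c("C", "C", "C", "O", "N"), 1L)
    atoms[i] <- a
    prevHet <- a != "C"
  }
  ## carbonyl on one interior carbon (ketone/amide/ester motifs)
  cs <- which(atoms == "C")
  cs <- cs[cs > 1L & cs < k]
  if (length(cs) && runif(1) < 0.5) {
    j <- cs[sample.int(length(cs), 1L)]
    atoms[j] <- "C(=O)"
  }
  out <- paste(atoms, collapse = "")
  if (runif(1) < haloProb)
    out <- paste0(out, sample(c("F", "Cl", "Br"), 1L))
  out
}

fixtureSmilesTemplate <- function() {
  chain <- function(k) strrep("C", k)
  ringSub <- function() sample(c("C", "CC", "O", "N", "F", "Cl", "Br"), 1L)
  list(
    function(k) randomChainSmiles(k, haloProb = 0),
    function(k) randomChainSmiles(k, haloProb = 1),
    function(k) randomChainSmiles(k),
    function(k) paste0(randomChainSmiles(max(1L, k - 3L), 0), "C(C)C"),
    function(k) paste0("C=C", randomChainSmiles(max(1L, k - 2L))),
    function(k) paste0("C#C", chain(max(1L, k - 2L))),
    function(k) paste0(ringSub(), "c1ccccc1"),                 # benzene + sub
    function(k) paste0(ringSub(), "c1ccc(", ringSub(), ")cc1"),
    function(k) paste0(ringSub(), "c1ccncc1"),                 # pyridine
    function(k) paste0("Oc1ccccc1", chain(max(0L, k - 7L))),   # phenol
    function(k) "c1ccc2ccccc2c1"                               # naphthalene
  )
}

#' Generate a deterministic synthetic molecule set
#'
#' Draws molecules from parameterized templates (alkanes, branched alkanes,
#' ethers, alcohols, amines, alkenes/alkynes, halogenated variants and
#' aromatic systems) spanning 3-20 heavy atoms. Each record carries a
#' deterministic conformer (seeded spring-relaxed embedding) and two labels:
#' \code{halogenated} (1 if the molecule contains F/Cl/Br/I) and
#' \code{size} (heavy-atom count). Identical seeds reproduce the set
#' bit-for-bit; the generator stands in for a pretraining corpus at desk
#' scale.
#'
#' @param nMolecules number of molecules to generate (may be 0).
#' @param seed integer seed.
#' @param withConformers attach deterministic conformers (default TRUE).
#' @return list of \linkS4class{MoleculeRecord}.
#' @export
generateFixtureSet <- function(nMolecules, seed, withConformers = TRUE) {
  stopifnot(nMolecules >= 0L)
  if (nMolecules == 0L) return(list())
  templates <- fixtureSmilesTemplate()
  smls <- withLocalSeed(mixSeed(seed, 1L), {
    vapply(seq_len(nMolecules), function(i) {
      fam <- sample(length(templates), 1L)
      k <- sample(3:14, 1L)
      templates[[fam]](k)
    }, character(1))
  })
  lapply(seq_len(nMolecules), function(i) {
    can <- canonicalSmiles(smls[i])
    parsed <- parseSmiles(can)
    n <- nrow(parsed$atoms)
    halo <- as.integer(any(parsed$atoms$symbol %in% c("F", "Cl", "Br", "I")))
    coords <- if (withConformers)
      embedConformer(parsed, mixSeed(seed, 2L, i)) else NULL
    moleculeRecord(sprintf("fix%04d", i), can,
                   labels = list(halogenated = halo, size = n),
                   coords = coords)
  })
}

#' Scaffold-based train/validation/test split
#'
#' Groups molecules by Bemis-Murcko scaffold (acyclic molecules by their own
#' canonical SMILES) and assigns whole groups greedily, largest first, to the
#' part currently furthest below its target count. No scaffold ever spans two
#' parts, preventing structural leakage between them.
#'
#' @param records list of \linkS4class{MoleculeRecord}.
#' @param fractions length-3 positive fractions summing to 1
#'   (train, valid, test); default \code{c(0.8, 0.1, 0.1)}.
#' @param shuffleSeed optional seed; when given, equal-size scaffold groups
#'   are tie-broken in seeded order instead of lexicographic key order.
#' @return a \linkS4class{DatasetSplit}.
#' @export
scaffoldSplit <- function(records, fractions = c(0.8, 0.1, 0.1),
                          shuffleSeed = NULL) {
  if (!length(records)) stopf("cannot split an empty record list")
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stopf("fractions must be 3 positive numbers summing to 1")
  ids <- vapply(records, molId, character(1))
  keys <- vapply(records, function(r) murckoScaffold(molSmiles(r)),
                 character(1))
  groups <- split(ids, keys)
  sizes <- lengths(groups)
  tie <- if (is.null(shuffleSeed)) {
    rank(names(groups))                  # content-based, deterministic
  } else {
    withLocalSeed(shuffleSeed, sample(length(groups)))
  }
  ord <- order(-sizes, tie)
  groups <- groups[ord]
  ntot <- length(ids)
  target <- fractions * ntot
  counts <- c(0, 0, 0)
  parts <- list(character(0), character(0), character(0))
  for (g in groups) {
    deficit <- target - counts
    part <- which.max(deficit)           # ties resolve train > valid > test
    parts[[part]] <- c(parts[[part]], g)
    counts[part] <- counts[part] + length(g)
  }
  if (!length(parts[[2L]]) || !length(parts[[3L]]))
    warnf("scaffold groups too coarse: validation and/or test part is empty")
  new("DatasetSplit", train = parts[[1L]], valid = parts[[2L]],
      test = parts[[3L]])
}

#' Write / read a DatasetSplit as a JSON document
#'
#' @param split a \linkS4class{DatasetSplit}.
#' @param path JSON file path.
#' @export
writeSplit <- function(split, path) {
  jsonlite::write_json(list(train = trainIds(split), valid = validIds(split),
                            test = testIds(split)), path)
  invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  asChr <- function(v) if (length(v)) as.character(v) else character(0)
  new("DatasetSplit", train = asChr(x$train), valid = asChr(x$valid),
      test = asChr(x$test))
}
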