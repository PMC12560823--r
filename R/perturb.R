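## Non-overlapping substructure selection and the three modality-specific
## perturbations: token masking (1D), node-feature masking (2D), and
## coordinate noising (3D). Selection runs in the order 1D -> 2D -> 3D with
## each later pool excluding earlier selections, so the perturbed regions of
## the three views never coincide and cross-modal redundancy of the
## corrupted signal is minimized.

#' Perturbation ratios per modality
#'
#' @param r1d,r2d,r3d fraction of substructures to perturb in each modality,
#'   each in [0, 1]. The realized counts are floor(r * e), truncated by the
#'   number of still-unselected substructures.
#' @return a validated list of class \code{PerturbRatios}.
#' @export
perturbRatios <- function(r1d = 0.25, r2d = 0.25, r3d = 0.25) {
  r <- c(r1d = r1d, r2d = r2d, r3d = r3d)
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
    stopf("perturbation ratios must lie in [0, 1]")
  structure(as.list(r), class = "PerturbRatios")
}

#' Plan a non-overlapping substructure perturbation
#'
#' Draws the substructure index sets to perturb in the 1D, 2D and 3D views.
#' Target counts are floor(ratio * e); selection is uniform without
#' replacement in the order 1D, 2D, 3D, each modality drawing from the pool
#' of substructures not selected by an earlier one. Deterministic given the
#' seed.
#'
#' @param tok a \linkS4class{TokenizedMolecule}.
#' @param ratios a \code{\link{perturbRatios}} object.
#' @param seed integer seed.
#' @return a \linkS4class{PerturbationPlan} with pairwise-disjoint sets.
#' @export
planPerturbation <- function(tok, ratios, seed) {
  e <- length(fragments(tok))
  stopifnot(e >= 1L)
  if (!inherits(ratios, "PerturbRatios"))
    ratios <- do.call(perturbRatios, as.list(ratios))
  withLocalSeed(seed, {
    pool <- seq_len(e)
    take <- function(r) {
      k <- min(floor(r * e), length(pool))
      if (k == 0L) return(integer(0))
      sel <- pool[sample.int(length(pool), k)]
      pool <<- setdiff(pool, sel)
      sort(sel)
    }
    s1 <- take(ratios$r1d); s2 <- take(ratios$r2d); s3 <- take(ratios$r3d)
    new("PerturbationPlan", sel1d = as.integer(s1), sel2d = as.integer(s2),
        sel3d = as.integer(s3), seed = as.integer(seed))
  })
}

#' Mask token ids of the selected 1D substructures
#'
#' @param tok a \linkS4class{TokenizedMolecule}.
#' @param plan a \linkS4class{PerturbationPlan}.
#' @param vocab the vocabulary supplying the mask id.
#' @return list(tokens = masked id sequence, mask = masked positions).
#' @export
apply1d <- function(tok, plan, vocab) {
  ids <- tokenIds(tok)
  if (length(plan@sel1d) && max(plan@sel1d) > length(ids))
    stopf("plan does not fit this molecule")
  ids[plan@sel1d] <- vocab@specialIds[["mask"]]
  list(tokens = ids, mask = plan@sel1d)
}

#' Mask node features of atoms in the selected 2D substructures
#'
#' Feature rows of the covered atoms are zeroed and their mask flag set; the
#' 2D encoder substitutes a learned mask embedding for flagged rows. Edges,
#' edge features and topology are untouched.
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @param tok a \linkS4class{TokenizedMolecule} with matching atom count.
#' @param plan a \linkS4class{PerturbationPlan}.
#' @return list(graph = masked graph, maskedAtoms = atom indices).
#' @export
apply2d <- function(graph, tok, plan) {
  if (graph@n != tok@nAtoms)
    stopf("graph has %d atoms but tokenization has %d", graph@n, tok@nAtoms)
  atoms <- atomsOfSubstructures(tok, plan@sel2d)
  nf <- graph@nodeFeatures
  if (length(atoms)) {
    nf[atoms, ] <- 0
    nf[atoms, NODE_FEATURE_DIM] <- 1
  }
  g <- graph
  g@nodeFeatures <- nf
  list(graph = g, maskedAtoms = atoms)
}

#' Add Gaussian noise to coordinates of the selected 3D substructures
#'
#' Atoms covered by the 3D selection receive i.i.d. N(0, sigma^2) noise per
#' axis; all other coordinates are bit-identical to the input. Deterministic
#' given the seed.
#'
#' @param coords n x 3 conformer matrix.
#' @param tok a \linkS4class{TokenizedMolecule} with matching atom count.
#' @param plan a \linkS4class{PerturbationPlan}.
#' @param sigma noise standard deviation in Angstrom (>= 0).
#' @param seed integer seed.
#' @return list(coords = noised matrix, noisedAtoms = atom indices).
#' @export
apply3d <- function(coords, tok, plan, sigma, seed) {
  if (!is.finite(sigma) || sigma < 0)
    stopf("sigma must be a nonnegative number")
  if (nrow(coords) != tok@nAtoms)
    stopf("conformer has %d atoms but tokenization has %d",
          nrow(coords), tok@nAtoms)
  atoms <- atomsOfSubstructures(tok, plan@sel3d)
  if (length(atoms) && sigma > 0) {
    noise <- withLocalSeed(seed,
      matrix(rnorm(length(atoms) * 3L, 0, sigma), length(atoms), 3L))
    coords[atoms, ] <- coords[atoms, , drop = FALSE] + noise
  }
  list(coords = coords, noisedAtoms = atoms)
}

#' Build all three perturbed views of a molecule
#'
#' Convenience wrapper producing the contrastive views (T', G', C') and
#' their mask sets from one plan. When the record has no conformer the
#' noised coordinates are a 0-row matrix.
#'
#' @param record a \linkS4class{MoleculeRecord}.
#' @param tok its \linkS4class{TokenizedMolecule}.
#' @param vocab the \linkS4class{SubstructureVocab}.
#' @param ratios a \code{\link{perturbRatios}} object.
#' @param sigma 3D noise standard deviation in Angstrom.
#' @param seed integer seed (plan and noise derive their streams from it).
#' @return a \linkS4class{PerturbedViews}.
#' @export
perturbMolecule <- function(record, tok, vocab, ratios = perturbRatios(),
                            sigma = 0.1, seed = 1L) {
  plan <- planPerturbation(tok, ratios, mixSeed(seed, "plan"))
  graph <- moleculeGraph(record)
  v1 <- apply1d(tok, plan, vocab)
  v2 <- apply2d(graph, tok, plan)
  coords <- molConformer(record)
  if (is.null(coords)) {
    v3 <- list(coords = matrix(numeric(0), 0L, 3L), noisedAtoms = integer(0))
  } else {
    v3 <- apply3d(coords, tok, plan, sigma, mixSeed(seed, "noise"))
  }
  new("PerturbedViews", tokensMasked = v1$tokens, mask1d = v1$mask,
      graphMasked = v2$graph, maskedAtoms = as.integer(v2$maskedAtoms),
      coordsNoised = v3$coords, noisedAtoms = as.integer(v3$noisedAtoms))
}
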