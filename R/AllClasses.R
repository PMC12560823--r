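## Central S4 containers. One class per key data structure of the pipeline:
## molecules with optional conformers, attributed graphs, the substructure
## vocabulary and tokenization (the cross-modal alignment key), perturbation
## plans/views, scaffold splits, fused embeddings, and checkpoints.

#' MoleculeRecord: one molecule with optional labels and conformer
#'
#' Stores the canonical SMILES, an optional named list of task labels, and an
#' optional conformer. Coordinates are kept as read (possibly including
#' explicit hydrogens); \code{heavyIdx} maps the heavy atoms of the parsed
#' SMILES (in canonical-parse order) to rows of \code{coords}, so the
#' modelling modules always see an n-heavy-atom by 3 matrix aligned with the
#' SMILES and graph atom order.
#'
#' @slot id character molecule identifier.
#' @slot smiles canonical SMILES string.
#' @slot labels named list of task labels (numeric or 0/1).
#' @slot coords numeric matrix of 3D coordinates in Angstrom (0 rows if no
#'   conformer is present).
#' @slot heavyIdx integer vector: row of \code{coords} for each heavy atom.
#' @export
setClass("MoleculeRecord",
  representation(id = "character", smiles = "character", labels = "list",
                 coords = "matrix", heavyIdx = "integer"),
  validity = function(object) {
    if (length(object@id) != 1L || !nzchar(object@id))
      return("id must be a single non-empty string")
    if (length(object@smiles) != 1L || !nzchar(object@smiles))
      return("smiles must be a single non-empty string")
    if (nrow(object@coords) > 0L) {
      if (ncol(object@coords) != 3L) return("coords must have 3 columns")
      if (!all(is.finite(object@coords))) return("coords must be finite")
      if (!length(object@heavyIdx)) return("heavyIdx required with coords")
      if (any(object@heavyIdx < 1L | object@heavyIdx > nrow(object@coords)))
        return("heavyIdx out of range")
    }
    TRUE
  })

#' MolecularGraph: heavy-atom attributed graph
#'
#' @slot n atom count.
#' @slot nodeFeatures numeric matrix n x 17 (element one-hot, degree, formal
#'   charge, aromaticity, hybridization one-hot, mask flag).
#' @slot edges integer matrix m x 2 of undirected bonds.
#' @slot edgeFeatures numeric matrix m x 3 (bond order, conjugation, ring).
#' @slot symbols element symbols, for reporting.
#' @export
setClass("MolecularGraph",
  representation(n = "integer", nodeFeatures = "matrix", edges = "matrix",
                 edgeFeatures = "matrix", symbols = "character"),
  validity = function(object) {
    n <- object@n
    if (nrow(object@nodeFeatures) != n) return("nodeFeatures rows != n")
    if (!all(is.finite(object@nodeFeatures))) return("non-finite node features")
    if (nrow(object@edges) != nrow(object@edgeFeatures))
      return("edges and edgeFeatures disagree")
    if (nrow(object@edges) > 0L) {
      if (any(object@edges < 1L | object@edges > n))
        return("edge endpoint out of range")
      if (any(object@edges[, 1L] == object@edges[, 2L]))
        return("self-loops not allowed")
    }
    TRUE
  })

#' SubstructureVocab: frequency-learned substructure vocabulary
#'
#' @slot baseTokens atom-level base units seen in the corpus.
#' @slot merges data.frame(rank, left, right, merged, frequency) in learned
#'   merge order.
#' @slot tokenToId named integer map, ids dense in 1..size.
#' @slot specialIds named integer (mask, pad, unknown).
#' @slot fingerprint content hash, checked when loading checkpoints.
#' @export
setClass("SubstructureVocab",
  representation(baseTokens = "character", merges = "data.frame",
                 tokenToId = "integer", specialIds = "integer",
                 fingerprint = "character"),
  validity = function(object) {
    ids <- c(object@specialIds, object@tokenToId)
    if (!setequal(names(object@specialIds), c("mask", "pad", "unknown")))
      return("specialIds must name mask, pad, unknown")
    if (anyDuplicated(ids)) return("token ids must be unique")
    if (!setequal(ids, seq_along(ids))) return("ids must be dense in 1..size")
    TRUE
  })

#' TokenizedMolecule: fragments, token ids and aligned atom sets
#'
#' The atom sets partition 1..nAtoms: they are pairwise disjoint and jointly
#' exhaustive, which is what lets the three modalities perturb the same
#' substructures without overlap.
#'
#' @slot fragments substructure fragment strings (length e).
#' @slot tokenIds integer ids into the vocabulary (length e).
#' @slot atomSets list of integer vectors, atom indices per fragment.
#' @slot nAtoms heavy atom count.
#' @export
setClass("TokenizedMolecule",
  representation(fragments = "character", tokenIds = "integer",
                 atomSets = "list", nAtoms = "integer"),
  validity = function(object) {
    e <- length(object@fragments)
    if (length(object@tokenIds) != e || length(object@atomSets) != e)
      return("fragments, tokenIds, atomSets must have equal length")
    all_atoms <- unlist(object@atomSets)
    if (length(all_atoms) != object@nAtoms ||
        !setequal(all_atoms, seq_len(object@nAtoms)))
      return("atomSets must partition 1..nAtoms")
    TRUE
  })

#' PerturbationPlan: per-modality selected substructures
#'
#' Selected substructure index sets for the 1D, 2D and 3D views. The class
#' invariant is the non-overlap guarantee: the three sets are pairwise
#' disjoint.
#'
#' @slot sel1d,sel2d,sel3d integer vectors of substructure indices.
#' @slot seed integer seed the plan was drawn with.
#' @export
setClass("PerturbationPlan",
  representation(sel1d = "integer", sel2d = "integer", sel3d = "integer",
                 seed = "integer"),
  validity = function(object) {
    s <- c(object@sel1d, object@sel2d, object@sel3d)
    if (anyDuplicated(s)) return("perturbation sets must be pairwise disjoint")
    if (length(s) && any(s < 1L)) return("indices must be >= 1")
    TRUE
  })

#' PerturbedViews: the three perturbed views of one molecule
#'
#' @slot tokensMasked token-id sequence with masked positions.
#' @slot mask1d masked token positions (equals the 1D selection).
#' @slot graphMasked graph with node features masked.
#' @slot maskedAtoms atoms whose features were masked (2D selection atoms).
#' @slot coordsNoised conformer with Gaussian coordinate noise.
#' @slot noisedAtoms atoms whose coordinates were noised (3D selection atoms).
#' @export
setClass("PerturbedViews",
  representation(tokensMasked = "integer", mask1d = "integer",
                 graphMasked = "MolecularGraph", maskedAtoms = "integer",
                 coordsNoised = "matrix", noisedAtoms = "integer"))

#' DatasetSplit: scaffold-pure train/valid/test partition
#'
#' @slot train,valid,test character vectors of molecule ids.
#' @export
setClass("DatasetSplit",
  representation(train = "character", valid = "character", test = "character"),
  validity = function(object) {
    ids <- c(object@train, object@valid, object@test)
    if (anyDuplicated(ids)) return("split parts must be disjoint")
    TRUE
  })

#' FusedEmbeddings: fusion output and its modality decomposition
#'
#' Rows are concatenated in the order [1D tokens, 2D atoms, 3D atoms]; the
#' decomposition slices are views of the fused matrix in that order.
#'
#' @slot fused (e + n [+ n]) x d matrix.
#' @slot x1d e x d slice; @slot x2d n x d slice; @slot x3d n x d slice (0
#'   rows when the 3D branch is disabled).
#' @export
setClass("FusedEmbeddings",
  representation(fused = "matrix", x1d = "matrix", x2d = "matrix",
                 x3d = "matrix"),
  validity = function(object) {
    if (nrow(object@fused) !=
        nrow(object@x1d) + nrow(object@x2d) + nrow(object@x3d))
      return("decomposition rows must sum to fused rows")
    TRUE
  })

#' Checkpoint: trainable parameters, config and vocabulary fingerprint
#'
#' @slot params named list of parameter matrices.
#' @slot config model/training configuration snapshot.
#' @slot vocabFingerprint fingerprint of the vocabulary the model was
#'   trained with; verified on load.
#' @slot step training step the checkpoint was taken at.
#' @export
setClass("Checkpoint",
  representation(params = "list", config = "list",
                 vocabFingerprint = "character", step = "integer"))

#' PooledRepresentation: attention-pooled molecular embedding
#'
#' @slot H matrix k x d of fused rows entering pooling.
#' @slot alpha length-k attention simplex vector (positive, sums to 1).
#' @slot pooled length-d pooled vector, the convex combination of rows.
#' @export
setClass("PooledRepresentation",
  representation(H = "matrix", alpha = "numeric", pooled = "numeric"),
  validity = function(object) {
    if (length(object@alpha) != nrow(object@H)) return("alpha length != k")
    if (abs(sum(object@alpha) - 1) > 1e-6) return("alpha must sum to 1")
    if (any(object@alpha <= 0)) return("alpha must be strictly positive")
    TRUE
  })

setMethod("show", "MoleculeRecord", function(object) {
  cat("MoleculeRecord", object@id, ":", object@smiles,
      if (nrow(object@coords)) sprintf("[conformer %d x 3]",
                                       nrow(object@coords)) else "[no conformer]",
      "\n")
  if (length(object@labels))
    cat("  labels:", paste(names(object@labels), unlist(object@labels),
                           sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SubstructureVocab", function(object) {
  cat(sprintf("SubstructureVocab: %d base tokens, %d merges, %d ids (fingerprint %s)\n",
              length(object@baseTokens), nrow(object@merges),
              length(object@tokenToId) + length(object@specialIds),
              object@fingerprint))
})

setMethod("show", "TokenizedMolecule", function(object) {
  cat(sprintf("TokenizedMolecule: e=%d fragments over %d atoms\n",
              length(object@fragments), object@nAtoms))
  cat(" ", paste(object@fragments, collapse = " | "), "\n")
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: train=%d valid=%d test=%d\n",
              length(object@train), length(object@valid),
              length(object@test)))
})

setMethod("show", "PerturbationPlan", function(object) {
  cat(sprintf("PerturbationPlan (seed %d): 1D {%s} 2D {%s} 3D {%s}\n",
              object@seed,
              paste(object@sel1d, collapse = ","),
              paste(object@sel2d, collapse = ","),
              paste(object@sel3d, collapse = ",")))
})

## ---- accessors ----

#' @rdname MoleculeRecord-class
#' @param object a MoleculeRecord.
#' @export
setGeneric("molId", function(object) standardGeneric("molId"))
#' @rdname MoleculeRecord-class
#' @export
setMethod("molId", "MoleculeRecord", function(object) object@id)

#' @rdname MoleculeRecord-class
#' @export
setGeneric("molSmiles", function(object) standardGeneric("molSmiles"))
#' @rdname MoleculeRecord-class
#' @export
setMethod("molSmiles", "MoleculeRecord", function(object) object@smiles)

#' @rdname MoleculeRecord-class
#' @export
setGeneric("molLabels", function(object) standardGeneric("molLabels"))
#' @rdname MoleculeRecord-class
#' @export
setMethod("molLabels", "MoleculeRecord", function(object) object@labels)

#' Heavy-atom conformer of a record
#'
#' Returns the n x 3 coordinate matrix of the heavy atoms in canonical-parse
#' atom order (explicit hydrogens from SDF input are dropped), or NULL when
#' no conformer is stored.
#' @param object a MoleculeRecord.
#' @export
setGeneric("molConformer", function(object) standardGeneric("molConformer"))
#' @rdname molConformer
#' @export
setMethod("molConformer", "MoleculeRecord", function(object) {
  if (!nrow(object@coords)) return(NULL)
  object@coords[object@heavyIdx, , drop = FALSE]
})

#' @rdname TokenizedMolecule-class
#' @param object a TokenizedMolecule.
#' @export
setGeneric("fragments", function(object) standardGeneric("fragments"))
#' @rdname TokenizedMolecule-class
#' @export
setMethod("fragments", "TokenizedMolecule", function(object) object@fragments)

#' @rdname TokenizedMolecule-class
#' @export
setGeneric("tokenIds", function(object) standardGeneric("tokenIds"))
#' @rdname TokenizedMolecule-class
#' @export
setMethod("tokenIds", "TokenizedMolecule", function(object) object@tokenIds)

#' @rdname TokenizedMolecule-class
#' @export
setGeneric("atomSets", function(object) standardGeneric("atomSets"))
#' @rdname TokenizedMolecule-class
#' @export
setMethod("atomSets", "TokenizedMolecule", function(object) object@atomSets)

#' @rdname DatasetSplit-class
#' @param object a DatasetSplit.
#' @export
setGeneric("trainIds", function(object) standardGeneric("trainIds"))
#' @rdname DatasetSplit-class
#' @export
setMethod("trainIds", "DatasetSplit", function(object) object@train)
#' @rdname DatasetSplit-class
#' @export
setGeneric("validIds", function(object) standardGeneric("validIds"))
#' @rdname DatasetSplit-class
#' @export
setMethod("validIds", "DatasetSplit", function(object) object@valid)
#' @rdname DatasetSplit-class
#' @export
setGeneric("testIds", function(object) standardGeneric("testIds"))
#' @rdname DatasetSplit-class
#' @export
setMethod("testIds", "DatasetSplit", function(object) object@test)
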