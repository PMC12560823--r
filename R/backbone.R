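## The three modality encoders, modality-identity offsets, shared fusion
## transformer, positional decomposition, and the three decoder heads.
## Tape-level functions (suffix T) are composed end to end during training;
## the exported wrappers evaluate them on a fresh tape and return plain
## matrices.

## ---- 1D: token sequence encoder ----

encode1dT <- function(tp, tokens, cfg) {
  e <- length(tokens)
  if (e > cfg$maxLen)
    stopf("token sequence length %d exceeds maxLen %d", e, cfg$maxLen)
  x <- adAdd(tp, adRows(tp, adParam(tp, "tokEmb"), tokens),
             adRows(tp, adParam(tp, "posEmb"), seq_len(e)))
  for (l in seq_len(cfg$n1dLayers))
    x <- blockT(tp, x, sprintf("enc1d.L%d", l), cfg$nHeads)
  x
}

## ---- 2D: graph isomorphism encoder ----

## Input embedding with learned mask row: atoms whose mask flag is set get
## the dedicated mask embedding instead of their (zeroed) feature embedding,
## so masking never collides with a legitimate feature encoding.
node2dInputT <- function(tp, graph) {
  nf <- graph@nodeFeatures
  x <- adAddVec(tp, adMM(tp, adConst(tp, nf), adParam(tp, "feat2d.W")),
                adParam(tp, "feat2d.b"))
  flag <- nf[, NODE_FEATURE_DIM]
  if (any(flag > 0)) {
    keep <- adMulColConst(tp, x, 1 - flag)
    maskPart <- adMM(tp, adConst(tp, matrix(flag, ncol = 1L)),
                     adParam(tp, "feat2d.mask"))
    x <- adAdd(tp, keep, maskPart)
  }
  x
}

encode2dT <- function(tp, graph, cfg) {
  gt <- graphTensors(graph)
  h <- node2dInputT(tp, graph)
  for (l in seq_len(cfg$n2dLayers))
    h <- ginLayerT(tp, h, gt, sprintf("gin2d.L%d", l), graph@n)
  h
}

## ---- 3D: directional message passing encoder ----

## Geometry of a conformer: directed edges within the cutoff with a Gaussian
## radial basis over distances, and edge-pair triplets (k->j, j->i, k != i)
## with a cosine angular basis at the shared atom j. All quantities depend
## only on interatomic distances and angles, so the encoder is invariant to
## rigid motions by construction.
geom3d <- function(coords, cutoff, nRbf, nAbf) {
  n <- nrow(coords)
  dm <- as.matrix(dist(coords))
  pairs <- which(dm <= cutoff & upper.tri(dm), arr.ind = TRUE)
  src <- c(pairs[, 1L], pairs[, 2L])
  dst <- c(pairs[, 2L], pairs[, 1L])
  dd <- dm[cbind(src, dst)]
  centers <- seq(0, cutoff, length.out = nRbf)
  width <- cutoff / nRbf
  rbf <- exp(-((matrix(dd, length(dd), nRbf) -
                matrix(centers, length(dd), nRbf, byrow = TRUE)) / width)^2)
  nE <- length(src)
  t1 <- t2 <- integer(0)
  if (nE) {
    byDst <- split(seq_len(nE), dst)
    t1l <- vector("list", nE); t2l <- vector("list", nE)
    for (e2 in seq_len(nE)) {         # e2 = (j -> i)
      j <- src[e2]; i <- dst[e2]
      cand <- byDst[[as.character(j)]]      # edges (k -> j)
      cand <- cand[src[cand] != i]
      if (length(cand)) { t1l[[e2]] <- cand; t2l[[e2]] <- rep(e2, length(cand)) }
    }
    t1 <- unlist(t1l); t2 <- unlist(t2l)
    if (is.null(t1)) { t1 <- integer(0); t2 <- integer(0) }
  }
  sbf <- matrix(0, length(t1), nRbf * nAbf)
  if (length(t1)) {
    jj <- src[t2]; ii <- dst[t2]; kk <- src[t1]
    u <- coords[kk, , drop = FALSE] - coords[jj, , drop = FALSE]
    v <- coords[ii, , drop = FALSE] - coords[jj, , drop = FALSE]
    cosang <- rowSums(u * v) /
      pmax(sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)), 1e-9)
    theta <- acos(pmin(pmax(cosang, -1), 1))
    abf <- sapply(seq_len(nAbf) - 1L, function(l) cos(l * theta))
    if (is.null(dim(abf))) abf <- matrix(abf, nrow = 1L)
    rkj <- rbf[t1, , drop = FALSE]
    for (a in seq_len(nAbf))
      sbf[, ((a - 1L) * nRbf + 1L):(a * nRbf)] <- rkj * abf[, a]
  }
  iso <- as.numeric(!(seq_len(n) %in% dst))
  list(src = src, dst = dst, rbf = rbf, t1 = t1, t2 = t2, sbf = sbf,
       iso = iso, n = n)
}

encode3dT <- function(tp, graph, coords, cfg, geom = NULL) {
  if (nrow(coords) != graph@n)
    stopf("conformer has %d atoms but graph has %d", nrow(coords), graph@n)
  if (is.null(geom)) geom <- geom3d(coords, cfg$cutoff, cfg$nRbf, cfg$nAbf)
  h0 <- adAddVec(tp, adMM(tp, adConst(tp, graph@nodeFeatures),
                          adParam(tp, "feat3d.W")),
                 adParam(tp, "feat3d.b"))
  n <- graph@n
  if (any(geom$iso > 0))
    warnf("%d atom(s) have no neighbour within the %g A cutoff; using self-feature fallback",
          sum(geom$iso > 0), cfg$cutoff)
  if (length(geom$src)) {
    pairFeat <- adConcatCols(tp, list(adRows(tp, h0, geom$src),
                                      adRows(tp, h0, geom$dst)))
    m <- adRelu(tp, adAdd(tp,
           adAddVec(tp, adMM(tp, pairFeat, adParam(tp, "enc3d.Wm0")),
                    adParam(tp, "enc3d.bm0")),
           adMM(tp, adConst(tp, geom$rbf), adParam(tp, "enc3d.Wrbf"))))
    for (b in seq_len(cfg$n3dBlocks)) {
      nm <- function(s) sprintf("enc3d.B%d.%s", b, s)
      upd <- linearT(tp, m, nm("Wt"), nm("bt"))
      if (length(geom$t1)) {
        tmsg <- adMul(tp, adRows(tp, m, geom$t1),
                      adMM(tp, adConst(tp, geom$sbf), adParam(tp, nm("Wsbf"))))
        tagg <- adScatterRows(tp, tmsg, geom$t2, length(geom$src))
        upd <- adAdd(tp, upd, linearT(tp, tagg, nm("Wagg"), nm("bagg")))
      }
      m <- adAdd(tp, m, adRelu(tp, linearT(tp, adRelu(tp, upd),
                                           nm("Wupd"), nm("bupd"))))
    }
    gated <- adMul(tp, m, adMM(tp, adConst(tp, geom$rbf),
                               adParam(tp, "enc3d.Wrbf2")))
    hsum <- adScatterRows(tp, gated, geom$dst, n)
    h <- adAddVec(tp, adMM(tp, hsum, adParam(tp, "enc3d.Wout")),
                  adParam(tp, "enc3d.bout"))
  } else {
    h <- adConst(tp, matrix(0, n, cfg$d))
  }
  if (any(geom$iso > 0)) {
    selfF <- adAddVec(tp, adMM(tp, h0, adParam(tp, "enc3d.Wself")),
                      adParam(tp, "enc3d.bself"))
    h <- adAdd(tp, h, adMulColConst(tp, selfF, geom$iso))
  }
  h
}

## ---- fusion ----

fuseT <- function(tp, x1d, x2d, x3d, cfg) {
  e <- nrow(nodeValue(tp, x1d)); n <- nrow(nodeValue(tp, x2d))
  parts <- list(adAddVec(tp, x1d, adParam(tp, "mod.a1d")),
                adAddVec(tp, x2d, adParam(tp, "mod.a2d")))
  n3 <- 0L
  if (!is.null(x3d)) {
    parts <- c(parts, list(adAddVec(tp, x3d, adParam(tp, "mod.a3d"))))
    n3 <- nrow(nodeValue(tp, x3d))
  }
  x <- adConcatRows(tp, parts)
  for (l in seq_len(cfg$nFusionBlocks))
    x <- blockT(tp, x, sprintf("fuse.L%d", l), cfg$nHeads)
  list(fused = x,
       x1d = adRows(tp, x, seq_len(e)),
       x2d = adRows(tp, x, e + seq_len(n)),
       x3d = if (n3) adRows(tp, x, e + n + seq_len(n3)) else NULL)
}

## ---- decoders ----

decode1dT <- function(tp, x) {
  h <- adRelu(tp, linearT(tp, x, "dec1d.W", "dec1d.b"))
  h <- lnAffineT(tp, h, "dec1d.lng", "dec1d.lnb")
  linearT(tp, h, "dec1d.Wv", "dec1d.bv")
}

decode2dT <- function(tp, x, graph) {
  gt <- graphTensors(graph)
  h <- ginLayerT(tp, x, gt, "dec2d.L1", graph@n)
  linearT(tp, h, "dec2d.Wout", "dec2d.bout")
}

decode3dT <- function(tp, x, graph) {
  gt <- graphTensors(graph)
  h <- ginLayerT(tp, x, gt, "dec3d.L1", graph@n)
  linearT(tp, h, "dec3d.Wout", "dec3d.bout")
}

## ---- exported plain-matrix wrappers ----

#' Encode a token-id sequence into substructure embeddings
#'
#' Token and positional embeddings are summed and passed through the 1D
#' self-attention encoder; output row i corresponds to token position i.
#'
#' @param tokens integer token-id vector (length e, e <= maxLen).
#' @param params backbone parameter list.
#' @param cfg a \code{\link{backboneConfig}}.
#' @return e x d matrix.
#' @export
encode1d <- function(tokens, params, cfg) {
  tp <- newTape(params)
  nodeValue(tp, encode1dT(tp, tokens, cfg))
}

#' Encode a molecular graph into per-atom embeddings
#'
#' Graph-isomorphism style message passing with edge-feature injection; row
#' i corresponds to atom i, and the encoder is permutation-equivariant.
#'
#' @param graph a \linkS4class{MolecularGraph} (possibly feature-masked).
#' @inheritParams encode1d
#' @return n x d matrix.
#' @export
encode2d <- function(graph, params, cfg) {
  tp <- newTape(params)
  nodeValue(tp, encode2dT(tp, graph, cfg))
}

#' Encode a conformer into per-atom embeddings
#'
#' Directional message passing over interatomic distances (radial basis)
#' and angles between neighbour pairs (angular basis) within the cutoff.
#' Invariant to global translations and rotations. Atoms with no neighbour
#' within the cutoff fall back to a self-feature embedding with a warning.
#'
#' @param graph a \linkS4class{MolecularGraph} (atom features).
#' @param coords n x 3 coordinate matrix.
#' @inheritParams encode1d
#' @return n x d matrix.
#' @export
encode3d <- function(graph, coords, params, cfg) {
  tp <- newTape(params)
  nodeValue(tp, encode3dT(tp, graph, coords, cfg))
}

#' Fuse modality embeddings through the shared transformer
#'
#' Adds the learned modality-identity offset to each modality's rows,
#' concatenates rows in the order [1D, 2D, 3D], applies the fusion blocks,
#' and decomposes the output by slicing the same row ranges.
#'
#' @param x1d e x d matrix; @param x2d n x d matrix.
#' @param x3d optional n x d matrix (NULL disables the 3D rows).
#' @inheritParams encode1d
#' @return a \linkS4class{FusedEmbeddings}.
#' @export
fuseEmbeddings <- function(x1d, x2d, x3d = NULL, params, cfg) {
  if (ncol(x1d) != cfg$d || ncol(x2d) != cfg$d ||
      (!is.null(x3d) && ncol(x3d) != cfg$d))
    stopf("modality embedding width must equal d = %d", cfg$d)
  tp <- newTape(params)
  f <- fuseT(tp, adConst(tp, x1d), adConst(tp, x2d),
             if (is.null(x3d)) NULL else adConst(tp, x3d), cfg)
  new("FusedEmbeddings",
      fused = nodeValue(tp, f$fused),
      x1d = nodeValue(tp, f$x1d),
      x2d = nodeValue(tp, f$x2d),
      x3d = if (is.null(f$x3d)) matrix(0, 0L, cfg$d)
            else nodeValue(tp, f$x3d))
}

#' Decode fused 1D rows into vocabulary logits
#'
#' Dense layer, nonlinearity and normalization followed by a projection
#' onto the full vocabulary (specials included); per-position unnormalized
#' scores.
#'
#' @param x1dOut e x d matrix of fused 1D rows.
#' @inheritParams encode1d
#' @return e x |vocab| logits matrix.
#' @export
decode1d <- function(x1dOut, params, cfg) {
  tp <- newTape(params)
  nodeValue(tp, decode1dT(tp, adConst(tp, x1dOut)))
}

#' Decode fused 2D rows into per-node prediction embeddings
#'
#' @param x2dOut n x d matrix of fused 2D rows.
#' @param graph the molecule's \linkS4class{MolecularGraph}.
#' @inheritParams encode1d
#' @return n x d matrix compared against the clean node-feature embedding.
#' @export
decode2d <- function(x2dOut, graph, params, cfg) {
  tp <- newTape(params)
  nodeValue(tp, decode2dT(tp, adConst(tp, x2dOut), graph))
}

#' Decode fused 3D rows into per-atom coordinates
#'
#' @param x3dOut n x d matrix of fused 3D rows.
#' @param graph the molecule's \linkS4class{MolecularGraph}.
#' @inheritParams encode1d
#' @return n x 3 coordinate matrix.
#' @export
decode3d <- function(x3dOut, graph, params, cfg) {
  tp <- newTape(params)
  nodeValue(tp, decode3dT(tp, adConst(tp, x3dOut), graph))
}

## target node embedding for the 2D reconstruction loss: the input-layer
## feature embedding of the CLEAN graph under current parameters, treated
## as a constant (gradient-stopped).
clean2dTarget <- function(graph, params) {
  nf <- graph@nodeFeatures
  sweep(nf %*% params[["feat2d.W"]], 2L,
        as.vector(params[["feat2d.b"]]), "+")
}

## ---- checkpointing ----

#' Save / load a model checkpoint
#'
#' A checkpoint holds the full parameter list, the configuration snapshot
#' and the vocabulary fingerprint. Loading verifies the fingerprint against
#' the supplied vocabulary and errors on mismatch; the parameter payload
#' round-trips bit-exactly.
#'
#' @param params named parameter list.
#' @param cfg configuration list.
#' @param vocab the \linkS4class{SubstructureVocab} used for training.
#' @param path file path.
#' @param step training step the checkpoint was taken at.
#' @return (load) a \linkS4class{Checkpoint}.
#' @export
saveCheckpoint <- function(params, cfg, vocab, path, step = 0L) {
  obj <- new("Checkpoint", params = params, config = cfg,
             vocabFingerprint = vocab@fingerprint, step = as.integer(step))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path, vocab = NULL) {
  obj <- readRDS(path)
  if (!is(obj, "Checkpoint")) stopf("not a checkpoint file: %s", path)
  if (!is.null(vocab) && !identical(obj@vocabFingerprint, vocab@fingerprint))
    stopf("checkpoint was trained with a different vocabulary (fingerprint %s != %s)",
          obj@vocabFingerprint, vocab@fingerprint)
  obj
}
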