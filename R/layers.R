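## Parameter initialization and the shared layer vocabulary: linear maps,
## affine layer normalization, multi-head self-attention and pre-norm
## transformer blocks, all expressed as tape ops so one backward pass
## differentiates the whole model.

#' Backbone configuration
#'
#' Desk-scale defaults: the model trains on CPU in minutes while keeping the
#' architecture of each branch (self-attention over tokens, GIN message
#' passing, directional distance+angle message passing, shared fusion
#' transformer).
#'
#' @param d shared embedding width.
#' @param n1dLayers,nHeads 1D encoder depth and attention heads.
#' @param n2dLayers GIN layer count of the 2D encoder.
#' @param n3dBlocks directional interaction blocks of the 3D encoder.
#' @param nRbf,nAbf radial and angular basis sizes of the 3D encoder.
#' @param cutoff neighbour cutoff in Angstrom for the 3D encoder.
#' @param nFusionBlocks fusion transformer depth.
#' @param maxLen maximum token-sequence length.
#' @param ffnMult feed-forward width multiplier inside transformer blocks.
#' @param use3d whether the 3D branch participates.
#' @return a configuration list.
#' @export
backboneConfig <- function(d = 64L, n1dLayers = 2L, nHeads = 4L,
                           n2dLayers = 3L, n3dBlocks = 2L, nRbf = 8L,
                           nAbf = 4L, cutoff = 5, nFusionBlocks = 2L,
                           maxLen = 128L, ffnMult = 2L, use3d = TRUE) {
  stopifnot(d %% nHeads == 0L, d > 0L, maxLen > 0L)
  list(d = as.integer(d), n1dLayers = as.integer(n1dLayers),
       nHeads = as.integer(nHeads), n2dLayers = as.integer(n2dLayers),
       n3dBlocks = as.integer(n3dBlocks), nRbf = as.integer(nRbf),
       nAbf = as.integer(nAbf), cutoff = cutoff,
       nFusionBlocks = as.integer(nFusionBlocks),
       maxLen = as.integer(maxLen), ffnMult = as.integer(ffnMult),
       use3d = isTRUE(use3d))
}

## transformer block parameter group
## fan-in-scaled (Xavier-style) weight init: matches layer output scale
## to input scale, so decoder outputs reach their target magnitudes
## without spending optimizer steps on growing scales
wInit <- function(r, c) matrix(rnorm(r * c, 0, 1 / sqrt(r)), r, c)

initBlockParams <- function(params, prefix, d, ffnMult, sd) {
  nm <- function(s) paste0(prefix, ".", s)
  params[[nm("ln1g")]] <- matrix(1, 1L, d)
  params[[nm("ln1b")]] <- matrix(0, 1L, d)
  for (w in c("Wq", "Wk", "Wv", "Wo"))
    params[[nm(w)]] <- wInit(d, d)
  for (b in c("bq", "bk", "bv", "bo"))
    params[[nm(b)]] <- matrix(0, 1L, d)
  params[[nm("ln2g")]] <- matrix(1, 1L, d)
  params[[nm("ln2b")]] <- matrix(0, 1L, d)
  h <- d * ffnMult
  params[[nm("W1")]] <- wInit(d, h)
  params[[nm("b1")]] <- matrix(0, 1L, h)
  params[[nm("W2")]] <- wInit(h, d)
  params[[nm("b2")]] <- matrix(0, 1L, d)
  params
}

initGinParams <- function(params, prefix, d, sd) {
  nm <- function(s) paste0(prefix, ".", s)
  params[[nm("Wedge")]] <- wInit(EDGE_FEATURE_DIM, d)
  params[[nm("bedge")]] <- matrix(0, 1L, d)
  params[[nm("Wm1")]] <- wInit(d, d)
  params[[nm("bm1")]] <- matrix(0, 1L, d)
  params[[nm("Wm2")]] <- wInit(d, d)
  params[[nm("bm2")]] <- matrix(0, 1L, d)
  params[[nm("lng")]] <- matrix(1, 1L, d)
  params[[nm("lnb")]] <- matrix(0, 1L, d)
  params
}

#' Initialize all trainable parameters of the backbone
#'
#' @param cfg a \code{\link{backboneConfig}}.
#' @param vocab the \linkS4class{SubstructureVocab} fixing the embedding
#'   table and 1D decoder sizes.
#' @param seed integer seed for the random initialization.
#' @return named list of parameter matrices.
#' @export
initBackbone <- function(cfg, vocab, seed = 1L) {
  d <- cfg$d; sd <- 0.02
  V <- vocabSize(vocab)
  withLocalSeed(mixSeed(seed, "init"), {
    p <- list()
    p[["tokEmb"]] <- matrix(rnorm(V * d, 0, sd), V, d)
    p[["posEmb"]] <- matrix(rnorm(cfg$maxLen * d, 0, sd), cfg$maxLen, d)
    for (l in seq_len(cfg$n1dLayers))
      p <- initBlockParams(p, sprintf("enc1d.L%d", l), d, cfg$ffnMult, sd)
    p[["feat2d.W"]] <- wInit(NODE_FEATURE_DIM, d)
    p[["feat2d.b"]] <- matrix(0, 1L, d)
    p[["feat2d.mask"]] <- matrix(rnorm(d, 0, sd), 1L, d)
    for (l in seq_len(cfg$n2dLayers))
      p <- initGinParams(p, sprintf("gin2d.L%d", l), d, sd)
    p[["feat3d.W"]] <- wInit(NODE_FEATURE_DIM, d)
    p[["feat3d.b"]] <- matrix(0, 1L, d)
    p[["enc3d.Wm0"]] <- wInit(2L * d, d)
    p[["enc3d.bm0"]] <- matrix(0, 1L, d)
    p[["enc3d.Wrbf"]] <- wInit(cfg$nRbf, d)
    for (b in seq_len(cfg$n3dBlocks)) {
      nm <- function(s) sprintf("enc3d.B%d.%s", b, s)
      p[[nm("Wsbf")]] <- wInit(cfg$nRbf * cfg$nAbf, d)
      p[[nm("Wt")]] <- wInit(d, d)
      p[[nm("bt")]] <- matrix(0, 1L, d)
      p[[nm("Wagg")]] <- wInit(d, d)
      p[[nm("bagg")]] <- matrix(0, 1L, d)
      p[[nm("Wupd")]] <- wInit(d, d)
      p[[nm("bupd")]] <- matrix(0, 1L, d)
    }
    p[["enc3d.Wrbf2"]] <- wInit(cfg$nRbf, d)
    p[["enc3d.Wout"]] <- wInit(d, d)
    p[["enc3d.bout"]] <- matrix(0, 1L, d)
    p[["enc3d.Wself"]] <- wInit(d, d)
    p[["enc3d.bself"]] <- matrix(0, 1L, d)
    ## modality-identity offsets, broadcast over each modality's rows
    p[["mod.a1d"]] <- matrix(rnorm(d, 0, sd), 1L, d)
    p[["mod.a2d"]] <- matrix(rnorm(d, 0, sd), 1L, d)
    p[["mod.a3d"]] <- matrix(rnorm(d, 0, sd), 1L, d)
    for (l in seq_len(cfg$nFusionBlocks))
      p <- initBlockParams(p, sprintf("fuse.L%d", l), d, cfg$ffnMult, sd)
    ## decoders
    p[["dec1d.W"]] <- wInit(d, d)
    p[["dec1d.b"]] <- matrix(0, 1L, d)
    p[["dec1d.lng"]] <- matrix(1, 1L, d)
    p[["dec1d.lnb"]] <- matrix(0, 1L, d)
    p[["dec1d.Wv"]] <- wInit(d, V)
    p[["dec1d.bv"]] <- matrix(0, 1L, V)
    p <- initGinParams(p, "dec2d.L1", d, sd)
    p[["dec2d.Wout"]] <- wInit(d, d)
    p[["dec2d.bout"]] <- matrix(0, 1L, d)
    p <- initGinParams(p, "dec3d.L1", d, sd)
    p[["dec3d.Wout"]] <- wInit(d, 3L)
    p[["dec3d.bout"]] <- matrix(0, 1L, 3L)
    ## fine-tuning head (attention pooling + MLP)
    dh <- max(2L, d %/% 2L)
    p[["head.watt"]] <- matrix(rnorm(d, 0, sd), 1L, d)
    p[["head.W1"]] <- wInit(d, dh)
    p[["head.b1"]] <- matrix(0, 1L, dh)
    p[["head.W2"]] <- wInit(dh, 1L)
    p[["head.b2"]] <- matrix(0, 1L, 1L)
    p
  })
}

## ---- tape-level layers ----

linearT <- function(tp, x, Wname, bname) {
  adAddVec(tp, adMM(tp, x, adParam(tp, Wname)), adParam(tp, bname))
}

lnAffineT <- function(tp, x, gname, bname) {
  adAddVec(tp, adMulVec(tp, adLayerNormRows(tp, x), adParam(tp, gname)),
           adParam(tp, bname))
}

mhsaT <- function(tp, x, prefix, nheads) {
  nm <- function(s) paste0(prefix, ".", s)
  d <- ncol(nodeValue(tp, x))
  dh <- d %/% nheads
  q <- linearT(tp, x, nm("Wq"), nm("bq"))
  k <- linearT(tp, x, nm("Wk"), nm("bk"))
  v <- linearT(tp, x, nm("Wv"), nm("bv"))
  heads <- lapply(seq_len(nheads), function(h) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    qh <- adCols(tp, q, cols); kh <- adCols(tp, k, cols)
    vh <- adCols(tp, v, cols)
    att <- adSoftmaxRows(tp, adScaleConst(tp, adMMNT(tp, qh, kh),
                                          1 / sqrt(dh)))
    adMM(tp, att, vh)
  })
  linearT(tp, adConcatCols(tp, heads), nm("Wo"), nm("bo"))
}

## pre-norm transformer block: x + Att(LN(x)); then x + FFN(LN(x)).
## With zeroed attention output and FFN second-layer weights the block is
## the identity, which the fusion residual-path test exploits.
blockT <- function(tp, x, prefix, nheads) {
  nm <- function(s) paste0(prefix, ".", s)
  a <- lnAffineT(tp, x, nm("ln1g"), nm("ln1b"))
  x <- adAdd(tp, x, mhsaT(tp, a, prefix, nheads))
  f <- lnAffineT(tp, x, nm("ln2g"), nm("ln2b"))
  ff <- linearT(tp, adRelu(tp, linearT(tp, f, nm("W1"), nm("b1"))),
                nm("W2"), nm("b2"))
  adAdd(tp, x, ff)
}

ginLayerT <- function(tp, h, gt, prefix, n) {
  nm <- function(s) paste0(prefix, ".", s)
  if (length(gt$src)) {
    eemb <- adAddVec(tp, adMM(tp, adConst(tp, gt$ef), adParam(tp, nm("Wedge"))),
                     adParam(tp, nm("bedge")))
    msg <- adRelu(tp, adAdd(tp, adRows(tp, h, gt$src), eemb))
    agg <- adScatterRows(tp, msg, gt$dst, n)
    z <- adAdd(tp, h, agg)
  } else z <- h
  out <- linearT(tp, adRelu(tp, linearT(tp, z, nm("Wm1"), nm("bm1"))),
                 nm("Wm2"), nm("bm2"))
  lnAffineT(tp, out, nm("lng"), nm("lnb"))
}

## directed-edge tensors of a MolecularGraph (both directions)
graphTensors <- function(graph) {
  ed <- graph@edges
  if (nrow(ed) == 0L)
    return(list(src = integer(0), dst = integer(0),
                ef = matrix(0, 0L, EDGE_FEATURE_DIM)))
  list(src = c(ed[, 1L], ed[, 2L]),
       dst = c(ed[, 2L], ed[, 1L]),
       ef = rbind(graph@edgeFeatures, graph@edgeFeatures))
}
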