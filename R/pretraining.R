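## Self-supervised pretraining: perturbation -> encoders -> fusion ->
## decoders -> losses, with seeded determinism, JSON-lines logging and
## checkpointing. Molecules in a batch are processed on separate tapes and
## their gradients averaged, which is mathematically identical to padded
## batching with masked losses.

#' Pretraining configuration
#'
#' @param ratios a \code{\link{perturbRatios}} object (default 0.15 per
#'   modality).
#' @param sigma 3D coordinate noise standard deviation in Angstrom.
#' @param gamma SCE sharpness exponent.
#' @param lambdaL2,lambdaCos 3D denoising weights.
#' @param backbone a \code{\link{backboneConfig}}.
#' @param lr,beta1,beta2,adamEps Adam optimizer settings; the default
#'   learning rate is sized so a desk-scale corpus approaches convergence
#'   within a few hundred steps.
#' @param batchSize molecules per optimizer step.
#' @param steps optimizer steps to run.
#' @param seed mandatory integer seed governing initialization, batch
#'   composition and per-molecule augmentation streams.
#' @param logEvery write a loss-log line every this many steps.
#' @return a configuration list.
#' @export
pretrainConfig <- function(ratios = perturbRatios(), sigma = 0.1,
                           gamma = 2, lambdaL2 = 1, lambdaCos = 1,
                           backbone = backboneConfig(), lr = 3e-3,
                           beta1 = 0.9, beta2 = 0.999, adamEps = 1e-8,
                           batchSize = 16L, steps = 200L, seed,
                           logEvery = 10L) {
  if (missing(seed)) stopf("pretrainConfig requires an explicit seed")
  stopifnot(sigma >= 0, lambdaL2 >= 0, lambdaCos >= 0, batchSize >= 1L)
  list(ratios = ratios, sigma = sigma, gamma = gamma, lambdaL2 = lambdaL2,
       lambdaCos = lambdaCos, backbone = backbone, lr = lr, beta1 = beta1,
       beta2 = beta2, adamEps = adamEps, batchSize = as.integer(batchSize),
       steps = as.integer(steps), seed = as.integer(seed),
       logEvery = as.integer(logEvery))
}

## ---- Adam ----

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

## Precompute per-molecule static quantities (tokenization, graph, clean
## coordinate frame) once per corpus.
prepareCorpus <- function(records, vocab, cfg) {
  lapply(records, function(rec) {
    tok <- tokenizeSmiles(molSmiles(rec), vocab)
    list(record = rec, tok = tok, graph = moleculeGraph(rec),
         coords = molConformer(rec))
  })
}

## Forward pass + loss nodes for one molecule on one tape.
moleculeLossT <- function(tp, prep, vocab, cfg, molSeed) {
  bb <- cfg$backbone
  tok <- prep$tok; graph <- prep$graph
  use3d <- bb$use3d && !is.null(prep$coords)
  plan <- planPerturbation(tok, cfg$ratios, mixSeed(molSeed, "plan"))
  v1 <- apply1d(tok, plan, vocab)
  v2 <- apply2d(graph, tok, plan)
  x1 <- encode1dT(tp, v1$tokens, bb)
  x2 <- encode2dT(tp, v2$graph, bb)
  x3 <- NULL
  if (use3d) {
    v3 <- apply3d(prep$coords, tok, plan, cfg$sigma, mixSeed(molSeed, "noise"))
    x3 <- encode3dT(tp, graph, v3$coords, bb)
  }
  f <- fuseT(tp, x1, x2, x3, bb)
  logits <- decode1dT(tp, f$x1d)
  ce <- loss1dCeT(tp, logits, tokenIds(tok), v1$mask)
  pred2 <- decode2dT(tp, f$x2d, graph)
  target2 <- clean2dTarget(graph, tp$params)
  sce <- loss2dSceT(tp, pred2, target2, v2$maskedAtoms, cfg$gamma)
  if (use3d) {
    pred3 <- decode3dT(tp, f$x3d, graph)
    mseN <- loss3dMseT(tp, pred3, prep$coords)
    cosN <- loss3dCosT(tp, pred3, prep$coords)
    den <- adAdd(tp, adScaleConst(tp, mseN, cfg$lambdaL2),
                 adScaleConst(tp, cosN, cfg$lambdaCos))
    total <- adAdd(tp, adAdd(tp, ce, sce), den)
  } else {
    mseN <- cosN <- NULL
    total <- adAdd(tp, ce, sce)
  }
  list(total = total, ce = ce, sce = sce, mse = mseN, cos = cosN,
       counts = list(m1d = length(v1$mask), m2d = length(v2$maskedAtoms),
                     n = graph@n),
       use3d = use3d, logits = logits, mask = v1$mask)
}

#' One pretraining step over a batch of molecules
#'
#' For each molecule: tokenize, draw a perturbation plan, build the three
#' views, encode, fuse, decompose, decode, and evaluate the reconstruction
#' losses; parameters are then updated by one optimizer step on the
#' batch-averaged total. Augmentation seeds derive from (stepSeed, molecule
#' id), so batch order cannot change the views.
#'
#' @param batch list of prepared molecules (see internals) or
#'   \linkS4class{MoleculeRecord}s.
#' @param params parameter list.
#' @param state Adam state from \code{adamInit}.
#' @param vocab the vocabulary.
#' @param cfg a \code{\link{pretrainConfig}}.
#' @param stepSeed integer seed for this step's augmentations.
#' @return list(params, state, report = averaged \code{LossReport}).
#' @export
pretrainStep <- function(batch, params, state, vocab, cfg, stepSeed) {
  if (length(batch) && is(batch[[1L]], "MoleculeRecord"))
    batch <- prepareCorpus(batch, vocab, cfg)
  grads <- NULL
  comp <- c(ce = 0, sce = 0, mse = 0, cos = 0, total = 0)
  cnt <- c(m1d = 0, m2d = 0, n = 0)
  any3d <- FALSE
  B <- length(batch)
  for (prep in batch) {
    e <- length(fragments(prep$tok))
    if (e > cfg$backbone$maxLen) {
      warnf("skipping %s: %d tokens exceed maxLen", molId(prep$record), e)
      B <- B - 1L
      next
    }
    tp <- newTape(params)
    ml <- suppressWarnings(
      moleculeLossT(tp, prep, vocab, cfg, mixSeed(stepSeed, molId(prep$record))))
    backward(tp, ml$total)
    g <- tp$pgrads
    grads <- if (is.null(grads)) g else {
      for (nm in names(g))
        grads[[nm]] <- if (is.null(grads[[nm]])) g[[nm]] else grads[[nm]] + g[[nm]]
      grads
    }
    comp["ce"] <- comp["ce"] + nodeValue(tp, ml$ce)[1L]
    comp["sce"] <- comp["sce"] + nodeValue(tp, ml$sce)[1L]
    if (ml$use3d) {
      comp["mse"] <- comp["mse"] + nodeValue(tp, ml$mse)[1L]
      comp["cos"] <- comp["cos"] + nodeValue(tp, ml$cos)[1L]
      any3d <- TRUE
    }
    comp["total"] <- comp["total"] + nodeValue(tp, ml$total)[1L]
    cnt <- cnt + unlist(ml$counts)
  }
  if (B < 1L) stopf("no usable molecules in batch")
  grads <- lapply(grads, function(g) g / B)
  upd <- adamStep(params, grads, state, cfg$lr, cfg$beta1, cfg$beta2,
                  cfg$adamEps)
  report <- totalLoss(comp[["ce"]] / B, comp[["sce"]] / B,
                      comp[["mse"]] / B, comp[["cos"]] / B,
                      cfg$lambdaL2, cfg$lambdaCos,
                      counts = as.list(cnt / B), use3d = any3d)
  if (!is.finite(report$total))
    stopf("non-finite loss encountered at seed %d", stepSeed)
  list(params = upd$params, state = upd$state, report = report)
}

#' Run self-supervised pretraining
#'
#' Executes \code{cfg$steps} optimizer steps over seeded random batches of
#' the corpus, writes a JSON-lines loss log, and returns (and optionally
#' writes) the final checkpoint. The loss trajectory is identical across
#' runs with the same seed, corpus and config.
#'
#' @param corpus list of \linkS4class{MoleculeRecord}.
#' @param vocab the \linkS4class{SubstructureVocab}.
#' @param cfg a \code{\link{pretrainConfig}}.
#' @param checkpointPath optional path for the final checkpoint.
#' @param logPath optional path for the JSON-lines training log.
#' @param params optional initial parameters (default: fresh
#'   initialization from \code{cfg$seed}).
#' @return list(checkpoint = \linkS4class{Checkpoint},
#'   log = data.frame of per-step losses).
#' @export
runPretraining <- function(corpus, vocab, cfg, checkpointPath = NULL,
                           logPath = NULL, params = NULL) {
  if (!length(corpus)) stopf("pretraining corpus is empty")
  if (is.null(params)) params <- initBackbone(cfg$backbone, vocab, cfg$seed)
  state <- adamInit(params)
  preps <- prepareCorpus(corpus, vocab, cfg)
  logRows <- vector("list", cfg$steps)
  logCon <- if (!is.null(logPath)) file(logPath, open = "w") else NULL
  on.exit(if (!is.null(logCon)) close(logCon))
  for (s in seq_len(cfg$steps)) {
    idx <- withLocalSeed(mixSeed(cfg$seed, "batch", s),
                         sample.int(length(preps),
                                    min(cfg$batchSize, length(preps))))
    res <- pretrainStep(preps[idx], params, state, vocab, cfg,
                        mixSeed(cfg$seed, "step", s))
    params <- res$params; state <- res$state
    rep <- res$report
    logRows[[s]] <- data.frame(step = s, total = rep$total, ce1d = rep$lCe1d,
                               sce2d = rep$lSce2d, mse3d = rep$lMse,
                               cos3d = rep$lCos)
    if (!is.null(logCon) && (s %% cfg$logEvery == 0L || s == cfg$steps))
      writeLines(jsonlite::toJSON(logRows[[s]], auto_unbox = TRUE,
                                  dataframe = "rows"), logCon)
  }
  ckpt <- new("Checkpoint", params = params, config = cfg,
              vocabFingerprint = vocab@fingerprint, step = cfg$steps)
  if (!is.null(checkpointPath)) saveRDS(ckpt, checkpointPath)
  list(checkpoint = ckpt, log = do.call(rbind, logRows))
}

#' Masked-token recovery accuracy of a trained model
#'
#' Re-applies seeded perturbations to each molecule and measures how often
#' the 1D decoder's argmax equals the true token at masked positions — the
#' overfit diagnostic for the reconstruction pathway.
#'
#' @param corpus list of \linkS4class{MoleculeRecord}.
#' @param params parameter list (e.g. from a checkpoint).
#' @param vocab the vocabulary.
#' @param cfg the \code{\link{pretrainConfig}} used in training.
#' @param seed seed for the evaluation perturbations.
#' @return fraction of masked positions recovered (top-1).
#' @export
maskedTokenRecovery <- function(corpus, params, vocab, cfg, seed = 1L) {
  preps <- prepareCorpus(corpus, vocab, cfg)
  hit <- tot <- 0L
  for (prep in preps) {
    tp <- newTape(params)
    ml <- suppressWarnings(
      moleculeLossT(tp, prep, vocab, cfg, mixSeed(seed, molId(prep$record))))
    if (!length(ml$mask)) next
    logits <- nodeValue(tp, ml$logits)
    pred <- max.col(logits[ml$mask, , drop = FALSE], ties.method = "first")
    hit <- hit + sum(pred == tokenIds(prep$tok)[ml$mask])
    tot <- tot + length(ml$mask)
  }
  if (tot == 0L) return(NA_real_)
  hit / tot
}
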