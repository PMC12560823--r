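## Fine-tuning: attention-pooled prediction head over the fused rows,
## training loop initialized from a checkpoint, prediction, and
## per-substructure attention export.
##
## Pooling runs over ALL fused rows — the e token rows, the n atom rows,
## and (when the 3D branch is enabled) the n 3D atom rows — so k = e + n
## (+ n). Attention weights alpha_i = softmax_i(w' tanh(h_i)) form a strict
## probability vector and the pooled vector is their convex combination of
## the rows.

#' Attention pooling of an embedding matrix
#'
#' Computes \eqn{\alpha_i = \mathrm{softmax}_i(w^\top \tanh(h_i))} and the
#' pooled vector \eqn{\sum_i \alpha_i h_i}.
#'
#' @param H k x d matrix of row embeddings (k >= 1).
#' @param w length-d weight vector.
#' @return a \linkS4class{PooledRepresentation}.
#' @export
attentionPool <- function(H, w) {
  H <- as.matrix(H)
  if (nrow(H) < 1L) stopf("attention pooling needs at least one row")
  scores <- as.vector(tanh(H) %*% as.vector(w))
  ex <- exp(scores - max(scores))
  alpha <- ex / sum(ex)
  new("PooledRepresentation", H = H, alpha = alpha,
      pooled = as.vector(crossprod(H, alpha)))
}

## tape version; returns list(alpha = 1 x k node, pooled = 1 x d node)
attentionPoolT <- function(tp, H) {
  scores <- adMMNT(tp, adTanh(tp, H), adParam(tp, "head.watt"))  # k x 1
  alpha <- adSoftmaxRows(tp, adT(tp, scores))                    # 1 x k
  list(alpha = alpha, pooled = adMM(tp, alpha, H))
}

#' Fine-tuning configuration
#'
#' @param taskType "classification" (binary, sigmoid output) or
#'   "regression" (mean absolute error).
#' @param labelName name of the label inside each record's label list.
#' @param use3d include the 3D branch (records must carry conformers).
#' @param epochs training epochs; 0 evaluates the checkpoint as-is.
#' @param lr learning rate; @param batchSize molecules per step.
#' @param seed mandatory integer seed.
#' @param freezeEncoders update only the head parameters when TRUE;
#'   default fine-tunes the full network.
#' @return a configuration list.
#' @export
finetuneConfig <- function(taskType = c("classification", "regression"),
                           labelName, use3d = FALSE, epochs = 30L,
                           lr = 1e-3, batchSize = 8L, seed,
                           freezeEncoders = FALSE) {
  if (missing(seed)) stopf("finetuneConfig requires an explicit seed")
  if (missing(labelName)) stopf("finetuneConfig requires labelName")
  list(taskType = match.arg(taskType), labelName = labelName,
       use3d = isTRUE(use3d), epochs = as.integer(epochs), lr = lr,
       batchSize = as.integer(batchSize), seed = as.integer(seed),
       freezeEncoders = isTRUE(freezeEncoders))
}

## clean (unperturbed) forward pass to the pooled representation
forwardPoolT <- function(tp, prep, bb, use3d) {
  x1 <- encode1dT(tp, tokenIds(prep$tok), bb)
  x2 <- encode2dT(tp, prep$graph, bb)
  x3 <- NULL
  if (use3d) {
    if (is.null(prep$coords))
      stopf("record '%s' has no conformer but use3d = TRUE",
            molId(prep$record))
    x3 <- encode3dT(tp, prep$graph, prep$coords, bb)
  }
  f <- fuseT(tp, x1, x2, x3, bb)
  pool <- attentionPoolT(tp, f$fused)
  c(pool, list(fused = f$fused))
}

## head MLP: d -> d/2 (tanh) -> 1
headT <- function(tp, pooled) {
  h <- adTanh(tp, linearT(tp, pooled, "head.W1", "head.b1"))
  linearT(tp, h, "head.W2", "head.b2")
}

#' Predict a property for one molecule
#'
#' Tokenizes without perturbation, encodes the available modalities, fuses,
#' pools with the attention head and applies the prediction MLP.
#' Classification outputs pass through a sigmoid into [0, 1].
#'
#' @param record a \linkS4class{MoleculeRecord}.
#' @param params parameter list (typically from a fine-tuned checkpoint).
#' @param vocab the \linkS4class{SubstructureVocab} (fingerprint must match
#'   the checkpoint the parameters came from).
#' @param bb the \code{\link{backboneConfig}}.
#' @param use3d include the 3D branch; errors if the record lacks a
#'   conformer (no silent fallback).
#' @param taskType "classification" or "regression".
#' @return a single numeric prediction.
#' @export
predictMolecule <- function(record, params, vocab, bb, use3d = FALSE,
                            taskType = "classification") {
  prep <- prepareCorpus(list(record), vocab, NULL)[[1L]]
  tp <- newTape(params)
  fw <- forwardPoolT(tp, prep, bb, use3d)
  z <- headT(tp, fw$pooled)
  out <- nodeValue(tp, z)[1L]
  if (taskType == "classification") 1 / (1 + exp(-out)) else out
}

#' Export per-substructure attention weights
#'
#' Returns the pooling weight alpha of every fused row of one molecule's
#' clean forward pass, labelled by modality and content (fragment string
#' for 1D rows, atom symbol for 2D/3D rows). Weights sum to 1 and equal the
#' alpha used by \code{\link{predictMolecule}} on the same pass.
#'
#' @inheritParams predictMolecule
#' @return data.frame(modality, index, label, alpha).
#' @export
exportSubstructureAttention <- function(record, params, vocab, bb,
                                        use3d = FALSE) {
  prep <- prepareCorpus(list(record), vocab, NULL)[[1L]]
  tp <- newTape(params)
  fw <- forwardPoolT(tp, prep, bb, use3d)
  alpha <- as.vector(nodeValue(tp, fw$alpha))
  e <- length(fragments(prep$tok)); n <- prep$graph@n
  desc <- data.frame(
    modality = c(rep("1D", e), rep("2D", n), if (use3d) rep("3D", n)),
    index = c(seq_len(e), seq_len(n), if (use3d) seq_len(n)),
    label = c(fragments(prep$tok), prep$graph@symbols,
              if (use3d) prep$graph@symbols),
    stringsAsFactors = FALSE)
  desc$alpha <- alpha
  desc
}

#' Area under the ROC curve
#'
#' Thin wrapper over \pkg{pROC} with fixed direction (higher score =
#' positive class). Returns NA when only one class is present.
#'
#' @param labels 0/1 vector. @param scores numeric scores.
#' @export
aurocScore <- function(labels, scores) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(labels, scores, direction = "<",
                                 levels = c(0, 1), quiet = TRUE)))
}

evalMetric <- function(preps, params, vocab, bb, ft) {
  scores <- vapply(preps, function(prep) {
    tp <- newTape(params)
    fw <- forwardPoolT(tp, prep, bb, ft$use3d)
    nodeValue(tp, headT(tp, fw$pooled))[1L]
  }, numeric(1))
  y <- vapply(preps, function(p) as.numeric(molLabels(p$record)[[ft$labelName]]),
              numeric(1))
  if (ft$taskType == "classification") {
    p <- 1 / (1 + exp(-scores))
    list(metric = aurocScore(y, p), accuracy = mean((p > 0.5) == (y > 0.5)),
         scores = p, labels = y)
  } else {
    list(metric = mean(abs(scores - y)), accuracy = NA_real_,
         scores = scores, labels = y)
  }
}

#' Fine-tune a pretrained checkpoint on labelled molecules
#'
#' Initializes encoders and fusion from the checkpoint, trains the
#' attention-pooled head (and, unless frozen, all parameters) with Adam on
#' binary cross-entropy (classification) or absolute error (regression),
#' selects the epoch by the validation metric, and reports the test metric
#' at the chosen epoch.
#'
#' @param records list of labelled \linkS4class{MoleculeRecord}.
#' @param split a \linkS4class{DatasetSplit} over the record ids.
#' @param ckpt a \linkS4class{Checkpoint} from pretraining.
#' @param vocab the vocabulary (fingerprint verified against the
#'   checkpoint).
#' @param ft a \code{\link{finetuneConfig}}.
#' @return list(params, report) where report carries per-epoch validation
#'   metrics, the chosen epoch, test/train metrics, seed and config.
#' @export
runFinetune <- function(records, split, ckpt, vocab, ft) {
  if (!identical(ckpt@vocabFingerprint, vocab@fingerprint))
    stopf("checkpoint/vocabulary fingerprint mismatch")
  bb <- ckpt@config$backbone
  haveLabel <- vapply(records, function(r)
    !is.null(molLabels(r)[[ft$labelName]]), logical(1))
  if (!all(haveLabel))
    stopf("label '%s' missing for %d record(s)", ft$labelName,
          sum(!haveLabel))
  preps <- prepareCorpus(records, vocab, NULL)
  ids <- vapply(preps, function(p) molId(p$record), character(1))
  pTrain <- preps[match(trainIds(split), ids)]
  pValid <- preps[stats::na.omit(match(validIds(split), ids))]
  pTest <- preps[stats::na.omit(match(testIds(split), ids))]
  params <- ckpt@params
  state <- adamInit(params)
  better <- if (ft$taskType == "classification") `>=` else `<=`
  best <- list(params = params, epoch = 0L, metric = NA_real_)
  validTrace <- numeric(0)
  for (ep in seq_len(ft$epochs)) {
    ord <- withLocalSeed(mixSeed(ft$seed, "epoch", ep),
                         sample(length(pTrain)))
    for (start in seq(1L, length(ord), by = ft$batchSize)) {
      idx <- ord[start:min(start + ft$batchSize - 1L, length(ord))]
      grads <- NULL
      for (prep in pTrain[idx]) {
        tp <- newTape(params)
        fw <- forwardPoolT(tp, prep, bb, ft$use3d)
        z <- headT(tp, fw$pooled)
        y <- as.numeric(molLabels(prep$record)[[ft$labelName]])
        lossN <- if (ft$taskType == "classification") {
          ## softplus(z) - y * z == -[y log p + (1-y) log(1-p)]
          adSub(tp, adSoftplus(tp, z), adScaleConst(tp, z, y))
        } else {
          adAbs(tp, adAddConst(tp, z, -y))
        }
        backward(tp, lossN)
        g <- tp$pgrads
        grads <- if (is.null(grads)) g else {
          for (nm in names(g))
            grads[[nm]] <- if (is.null(grads[[nm]])) g[[nm]]
                           else grads[[nm]] + g[[nm]]
          grads
        }
      }
      grads <- lapply(grads, function(g) g / length(idx))
      if (ft$freezeEncoders)
        grads <- grads[startsWith(names(grads), "head.")]
      upd <- adamStep(params, grads, state, ft$lr, 0.9, 0.999, 1e-8)
      params <- upd$params; state <- upd$state
    }
    vm <- if (length(pValid)) evalMetric(pValid, params, vocab, bb, ft)$metric
          else NA_real_
    validTrace <- c(validTrace, vm)
    ## without a validation part (or a degenerate one-class part) the last
    ## epoch is kept; otherwise the best validation epoch wins
    if (is.na(vm) || is.na(best$metric) || better(vm, best$metric))
      best <- list(params = params, epoch = ep, metric = vm)
  }
  if (ft$epochs == 0L) best <- list(params = params, epoch = 0L,
                                    metric = NA_real_)
  testEval <- if (length(pTest))
    evalMetric(pTest, best$params, vocab, bb, ft) else NULL
  trainEval <- evalMetric(pTrain, best$params, vocab, bb, ft)
  list(params = best$params,
       report = list(taskType = ft$taskType, label = ft$labelName,
                     validPerEpoch = validTrace, chosenEpoch = best$epoch,
                     validMetric = best$metric,
                     testMetric = if (is.null(testEval)) NA_real_
                                  else testEval$metric,
                     trainMetric = trainEval$metric,
                     trainAccuracy = trainEval$accuracy,
                     seed = ft$seed, config = ft))
}
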