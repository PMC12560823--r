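## Modality-specific reconstruction losses and their combination.
##
## 1D: cross-entropy of masked-token prediction, summed over masked
##     positions per molecule.
## 2D: structural contrastive embedding (SCE) penalty
##     sum_{i in M2D} (1 - cos(h_i, h_i^target))^gamma over masked atoms.
## 3D: coordinate denoising combining mean squared error and a cosine
##     similarity term over ALL atoms (the decoder must also keep clean
##     atoms in place), weighted by lambdaL2 and lambdaCos.
## The total pretraining objective is the plain sum of the three.

#' Cross-entropy loss for masked token prediction
#'
#' \eqn{-\sum_{i \in M} \log p(t_i)}, with probabilities from row-wise
#' softmax over the logits; the sum (not mean) runs over masked positions.
#' An empty mask yields 0 with a warning (the molecule had no 1D
#' perturbation).
#'
#' @param logits e x |vocab| score matrix.
#' @param targets length-e integer vector of true token ids.
#' @param mask integer vector of masked positions.
#' @return nonnegative scalar.
#' @export
loss1dCe <- function(logits, targets, mask) {
  if (!length(mask)) {
    warnf("empty 1D mask: cross-entropy loss is 0")
    return(0)
  }
  L <- logits[mask, , drop = FALSE]
  m <- apply(L, 1L, max)
  lse <- m + log(rowSums(exp(L - m)))
  sum(lse - L[cbind(seq_along(mask), targets[mask])])
}

#' Structural contrastive embedding loss for masked node features
#'
#' \eqn{\sum_{i \in M} (1 - \cos(h_i, h_i^{target}))^\gamma}. Rows with
#' (near-)zero norm are guarded by an epsilon in the denominator with a
#' warning.
#'
#' @param pred,target matrices of predicted and target node embeddings.
#' @param mask integer vector of masked atom indices.
#' @param gamma sharpness exponent (default 2).
#' @param eps numerical guard for zero-norm rows.
#' @return nonnegative scalar.
#' @export
loss2dSce <- function(pred, target, mask, gamma = 2, eps = 1e-8) {
  if (!length(mask)) return(0)
  p <- pred[mask, , drop = FALSE]; t <- target[mask, , drop = FALSE]
  np <- sqrt(rowSums(p^2)); nt <- sqrt(rowSums(t^2))
  if (any(np < eps) || any(nt < eps))
    warnf("zero-norm row in SCE loss; epsilon guard applied")
  cos <- rowSums(p * t) / (np * nt + eps)
  sum((1 - cos)^gamma)
}

#' Mean squared error between coordinate matrices
#'
#' \eqn{(1/n) \sum_i \lVert c_i - c_i^{target} \rVert_2^2} over all n atoms.
#'
#' @param pred,target n x 3 coordinate matrices.
#' @return nonnegative scalar.
#' @export
loss3dMse <- function(pred, target) {
  if (!all(dim(pred) == dim(target)))
    stopf("coordinate shapes differ: %s vs %s",
          paste(dim(pred), collapse = "x"),
          paste(dim(target), collapse = "x"))
  sum((pred - target)^2) / nrow(pred)
}

#' Cosine similarity loss between coordinate matrices
#'
#' \eqn{1 - (1/n) \sum_i \cos(c_i, c_i^{target})}; lies in [0, 2]. Zero-norm
#' rows are guarded by an epsilon with a warning.
#'
#' @inheritParams loss3dMse
#' @param eps numerical guard.
#' @return scalar in [0, 2].
#' @export
loss3dCos <- function(pred, target, eps = 1e-8) {
  np <- sqrt(rowSums(pred^2)); nt <- sqrt(rowSums(target^2))
  if (any(np < eps) || any(nt < eps))
    warnf("zero-norm row in cosine loss; epsilon guard applied")
  1 - mean(rowSums(pred * target) / (np * nt + eps))
}

#' Weighted 3D denoising loss
#'
#' \code{lambdaL2 * mse + lambdaCos * cos}, exactly.
#'
#' @param mse,cos component values.
#' @param lambdaL2,lambdaCos nonnegative weights.
#' @export
loss3dDenoise <- function(mse, cos, lambdaL2 = 1, lambdaCos = 1) {
  if (lambdaL2 < 0 || lambdaCos < 0)
    stopf("loss weights must be nonnegative")
  lambdaL2 * mse + lambdaCos * cos
}

#' Combine component losses into a LossReport
#'
#' The total is the plain sum of the three modality objectives (never a
#' mean of means); with the 3D modality disabled its term is 0 and flagged
#' in the counts.
#'
#' @param lCe1d,lSce2d 1D and 2D losses.
#' @param lMse,lCos 3D components (ignored when \code{use3d} is FALSE).
#' @param lambdaL2,lambdaCos 3D weights.
#' @param counts list with |M1D|, |M2D| and n.
#' @param use3d whether the 3D modality participated.
#' @return a list of class \code{LossReport} with fields lCe1d, lSce2d,
#'   lMse, lCos, lDenoise3d, total and counts.
#' @export
totalLoss <- function(lCe1d, lSce2d, lMse = 0, lCos = 0,
                      lambdaL2 = 1, lambdaCos = 1,
                      counts = list(m1d = NA, m2d = NA, n = NA),
                      use3d = TRUE) {
  lden <- if (use3d) loss3dDenoise(lMse, lCos, lambdaL2, lambdaCos) else 0
  structure(list(lCe1d = lCe1d, lSce2d = lSce2d,
                 lMse = if (use3d) lMse else 0,
                 lCos = if (use3d) lCos else 0,
                 lDenoise3d = lden,
                 total = lCe1d + lSce2d + lden,
                 counts = c(counts, list(use3d = use3d))),
            class = "LossReport")
}

#' @export
print.LossReport <- function(x, ...) {
  cat(sprintf("LossReport: total %.5f (1D ce %.5f | 2D sce %.5f | 3D denoise %.5f [mse %.5f cos %.5f])\n",
              x$total, x$lCe1d, x$lSce2d, x$lDenoise3d, x$lMse, x$lCos))
  invisible(x)
}

## ---- tape versions (used by the training loop) ----

loss1dCeT <- function(tp, logits, targets, mask) {
  if (!length(mask)) return(adConst(tp, matrix(0, 1L, 1L)))
  L <- adRows(tp, logits, mask)
  lse <- adSumAll(tp, adLogSumExpRows(tp, L))
  zt <- adSumAll(tp, adSelectElems(tp, L,
                                   cbind(seq_along(mask), targets[mask])))
  adSub(tp, lse, zt)
}

loss2dSceT <- function(tp, pred, target, mask, gamma = 2, eps = 1e-8) {
  if (!length(mask)) return(adConst(tp, matrix(0, 1L, 1L)))
  p <- adRows(tp, pred, mask)
  t <- target[mask, , drop = FALSE]
  dot <- adRowSums(tp, adMulConst(tp, p, t))
  np <- adSqrt(tp, adAddConst(tp, adRowSums(tp, adSquare(tp, p)), eps^2))
  nt <- matrix(sqrt(rowSums(t^2)) + eps, ncol = 1L)
  cos <- adDiv(tp, dot, adMulConst(tp, np, nt))
  one <- adAddConst(tp, adScaleConst(tp, cos, -1), 1)
  adSumAll(tp, adPowConst(tp, one, gamma))
}

loss3dMseT <- function(tp, pred, target) {
  n <- nrow(target)
  diff <- adAddConst(tp, pred, -target)
  adScaleConst(tp, adSumAll(tp, adSquare(tp, diff)), 1 / n)
}

loss3dCosT <- function(tp, pred, target, eps = 1e-8) {
  n <- nrow(target)
  dot <- adRowSums(tp, adMulConst(tp, pred, target))
  np <- adSqrt(tp, adAddConst(tp, adRowSums(tp, adSquare(tp, pred)), eps^2))
  nt <- matrix(sqrt(rowSums(target^2)) + eps, ncol = 1L)
  cos <- adDiv(tp, dot, adMulConst(tp, np, nt))
  adAddConst(tp, adScaleConst(tp, adSumAll(tp, cos), -1 / n), 1)
}
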