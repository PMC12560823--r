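## Minimal reverse-mode automatic differentiation on dense matrices.
##
## Every value on the tape is a numeric matrix (scalars are 1x1). A node
## records its value, its parent node ids, and a backward closure mapping
## the incoming gradient to parent gradients. Parameters are named matrices
## shared through the tape's parameter list; their gradients accumulate in
## tape$pgrads during backward(). The op set is exactly what the encoders,
## fusion transformer, decoders and losses need; gradients are validated by
## finite differences in the test suite.

newTape <- function(params = list()) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$params <- params
  tp$pnode <- list()
  tp$pgrads <- list()
  tp
}

addNode <- function(tp, value, parents = integer(0), bw = NULL,
                    pname = NULL) {
  ## force all promises first: evaluating an argument may itself create
  ## nodes (nested op calls), which must precede this node's slot
  force(value); force(parents); force(bw)
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", tp$n))
  tp$nodes[[tp$n]] <- list(value = value, parents = parents, bw = bw,
                           pname = pname)
  tp$n
}

nodeValue <- function(tp, id) {
  force(id)  # node-creating promises must run before the list is indexed
  tp$nodes[[id]]$value
}

adConst <- function(tp, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  addNode(tp, x)
}

adParam <- function(tp, name) {
  if (!is.null(tp$pnode[[name]])) return(tp$pnode[[name]])
  v <- tp$params[[name]]
  if (is.null(v)) stopf("unknown parameter '%s'", name)
  id <- addNode(tp, v, pname = name)
  tp$pnode[[name]] <- id
  id
}

backward <- function(tp, root, scale = 1) {
  grads <- vector("list", tp$n)
  rv <- tp$nodes[[root]]$value
  grads[[root]] <- matrix(scale, nrow(rv), ncol(rv))
  for (id in seq(tp$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tp$nodes[[id]]
    if (!is.null(nd$pname)) {
      cur <- tp$pgrads[[nd$pname]]
      tp$pgrads[[nd$pname]] <- if (is.null(cur)) g else cur + g
    }
    if (length(nd$parents)) {
      pg <- nd$bw(g)
      for (k in seq_along(nd$parents)) {
        p <- nd$parents[k]
        if (is.null(pg[[k]])) next
        grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
      }
    }
  }
  invisible(tp$pgrads)
}

## ---- arithmetic ----

adMM <- function(tp, a, b) {           # a %*% b
  A <- nodeValue(tp, a); B <- nodeValue(tp, b)
  addNode(tp, A %*% B, c(a, b),
          function(g) list(tcrossprod(g, B), crossprod(A, g)))
}

adMMNT <- function(tp, a, b) {         # a %*% t(b)
  A <- nodeValue(tp, a); B <- nodeValue(tp, b)
  addNode(tp, tcrossprod(A, B), c(a, b),
          function(g) list(g %*% B, crossprod(g, A)))
}

adAdd <- function(tp, a, b) {
  A <- nodeValue(tp, a); B <- nodeValue(tp, b)
  addNode(tp, A + B, c(a, b), function(g) list(g, g))
}

adSub <- function(tp, a, b) {
  A <- nodeValue(tp, a); B <- nodeValue(tp, b)
  addNode(tp, A - B, c(a, b), function(g) list(g, -g))
}

adAddVec <- function(tp, x, v) {       # broadcast a 1 x d row over rows of x
  X <- nodeValue(tp, x); V <- nodeValue(tp, v)
  n <- nrow(X)
  addNode(tp, X + rep(as.vector(V), each = n), c(x, v),
          function(g) list(g, matrix(colSums(g), 1L)))
}

adMulVec <- function(tp, x, v) {       # row-broadcast multiply by 1 x d
  X <- nodeValue(tp, x); V <- nodeValue(tp, v)
  n <- nrow(X)
  vb <- rep(as.vector(V), each = n)
  addNode(tp, X * vb, c(x, v),
          function(g) list(g * vb, matrix(colSums(g * X), 1L)))
}

adMul <- function(tp, a, b) {
  A <- nodeValue(tp, a); B <- nodeValue(tp, b)
  addNode(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

adDiv <- function(tp, a, b) {
  A <- nodeValue(tp, a); B <- nodeValue(tp, b)
  addNode(tp, A / B, c(a, b),
          function(g) list(g / B, -g * A / B^2))
}

adScaleConst <- function(tp, x, s) {
  addNode(tp, nodeValue(tp, x) * s, x, function(g) list(g * s))
}

adAddConst <- function(tp, x, c) {     # c scalar or conforming matrix
  addNode(tp, nodeValue(tp, x) + c, x, function(g) list(g))
}

adMulConst <- function(tp, x, M) {     # elementwise with constant
  addNode(tp, nodeValue(tp, x) * M, x, function(g) list(g * M))
}

adMulColConst <- function(tp, x, v) {  # scale row i of x by constant v[i]
  X <- nodeValue(tp, x)
  addNode(tp, X * as.vector(v), x, function(g) list(g * as.vector(v)))
}

## ---- nonlinearities ----

adTanh <- function(tp, x) {
  v <- tanh(nodeValue(tp, x))
  addNode(tp, v, x, function(g) list(g * (1 - v^2)))
}

adRelu <- function(tp, x) {
  X <- nodeValue(tp, x)
  addNode(tp, pmax(X, 0), x, function(g) list(g * (X > 0)))
}

adSigmoid <- function(tp, x) {
  v <- 1 / (1 + exp(-nodeValue(tp, x)))
  addNode(tp, v, x, function(g) list(g * v * (1 - v)))
}

adSquare <- function(tp, x) {
  X <- nodeValue(tp, x)
  addNode(tp, X^2, x, function(g) list(2 * g * X))
}

adSqrt <- function(tp, x) {
  v <- sqrt(nodeValue(tp, x))
  addNode(tp, v, x, function(g) list(g / (2 * v)))
}

adPowConst <- function(tp, x, p) {
  X <- nodeValue(tp, x)
  addNode(tp, X^p, x, function(g) list(g * p * X^(p - 1)))
}

## ---- row-wise normalizations ----

adSoftmaxRows <- function(tp, x) {
  X <- nodeValue(tp, x)
  m <- apply(X, 1L, max)
  ex <- exp(X - m)
  s <- ex / rowSums(ex)
  addNode(tp, s, x, function(g) list(s * (g - rowSums(g * s))))
}

adLayerNormRows <- function(tp, x, eps = 1e-5) {
  X <- nodeValue(tp, x)
  mu <- rowMeans(X)
  xc <- X - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  y <- xc / sd
  addNode(tp, y, x, function(g) {
    list((g - rowMeans(g) - y * rowMeans(g * y)) / sd)
  })
}

adLogSumExpRows <- function(tp, x) {
  X <- nodeValue(tp, x)
  m <- apply(X, 1L, max)
  ex <- exp(X - m)
  v <- matrix(m + log(rowSums(ex)), ncol = 1L)
  sm <- ex / rowSums(ex)
  addNode(tp, v, x, function(g) list(sm * as.vector(g)))
}

## ---- indexing / reshaping ----

adRows <- function(tp, x, idx) {
  X <- nodeValue(tp, x)
  idx <- as.integer(idx)
  addNode(tp, X[idx, , drop = FALSE], x, function(g) {
    out <- matrix(0, nrow(X), ncol(X))
    if (length(idx)) {
      rs <- rowsum(g, idx)
      out[as.integer(rownames(rs)), ] <- rs
    }
    list(out)
  })
}

adScatterRows <- function(tp, x, idx, nout) {
  X <- nodeValue(tp, x)
  idx <- as.integer(idx)
  out <- matrix(0, nout, ncol(X))
  if (length(idx)) {
    rs <- rowsum(X, idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  addNode(tp, out, x, function(g) list(g[idx, , drop = FALSE]))
}

adConcatRows <- function(tp, ids) {
  vals <- lapply(ids, nodeValue, tp = tp)
  nr <- vapply(vals, nrow, integer(1))
  addNode(tp, do.call(rbind, vals), as.integer(ids), function(g) {
    off <- cumsum(c(0L, nr))
    lapply(seq_along(nr), function(k)
      g[(off[k] + 1L):(off[k] + nr[k]), , drop = FALSE])
  })
}

adConcatCols <- function(tp, ids) {
  vals <- lapply(ids, nodeValue, tp = tp)
  nc <- vapply(vals, ncol, integer(1))
  addNode(tp, do.call(cbind, vals), as.integer(ids), function(g) {
    off <- cumsum(c(0L, nc))
    lapply(seq_along(nc), function(k)
      g[, (off[k] + 1L):(off[k] + nc[k]), drop = FALSE])
  })
}

adCols <- function(tp, x, cols) {
  X <- nodeValue(tp, x)
  cols <- as.integer(cols)
  addNode(tp, X[, cols, drop = FALSE], x, function(g) {
    out <- matrix(0, nrow(X), ncol(X))
    out[, cols] <- g
    list(out)
  })
}

adSumAll <- function(tp, x) {
  X <- nodeValue(tp, x)
  addNode(tp, matrix(sum(X), 1L, 1L), x,
          function(g) list(matrix(g[1L], nrow(X), ncol(X))))
}

adRowSums <- function(tp, x) {
  X <- nodeValue(tp, x)
  addNode(tp, matrix(rowSums(X), ncol = 1L), x,
          function(g) list(matrix(as.vector(g), nrow(X), ncol(X))))
}

adSelectElems <- function(tp, x, ij) {
  X <- nodeValue(tp, x)
  addNode(tp, matrix(X[ij], ncol = 1L), x, function(g) {
    out <- matrix(0, nrow(X), ncol(X))
    for (r in seq_len(nrow(ij)))
      out[ij[r, 1L], ij[r, 2L]] <- out[ij[r, 1L], ij[r, 2L]] + g[r, 1L]
    list(out)
  })
}

## transpose (used by the attention-pooling head)
adT <- function(tp, x) {
  addNode(tp, t(nodeValue(tp, x)), x, function(g) list(t(g)))
}

adSoftplus <- function(tp, x) {        # log(1 + exp(x)), stable
  X <- nodeValue(tp, x)
  v <- pmax(X, 0) + log1p(exp(-abs(X)))
  s <- 1 / (1 + exp(-X))
  addNode(tp, v, x, function(g) list(g * s))
}

adAbs <- function(tp, x) {
  X <- nodeValue(tp, x)
  addNode(tp, abs(X), x, function(g) list(g * sign(X)))
}
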