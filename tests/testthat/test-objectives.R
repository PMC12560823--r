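test_that("masked-token cross-entropy matches closed forms", {
  ## probability 1 on the true token at each masked position -> 0
  V <- 10L
  logits <- matrix(-1e6, 3, V)
  targets <- c(3L, 7L, 1L)
  for (i in 1:3) logits[i, targets[i]] <- 0
  expect_equal(loss1dCe(logits, targets, 1:3), 0, tolerance = 1e-6)

  ## uniform logits over a 10-token vocabulary, one masked position
  expect_equal(loss1dCe(matrix(0, 2, V), c(4L, 9L), 1L), log(10),
               tolerance = 1e-9)

  ## softmax shift invariance
  l1 <- matrix(rnorm(30), 3, V)
  l2 <- l1 + 5
  expect_equal(loss1dCe(l1, targets, c(1L, 3L)),
               loss1dCe(l2, targets, c(1L, 3L)), tolerance = 1e-9)

  ## sum (not mean) over masked positions; order within mask irrelevant
  expect_equal(loss1dCe(matrix(0, 2, V), c(1L, 2L), 1:2), 2 * log(10),
               tolerance = 1e-9)
  expect_equal(loss1dCe(l1, targets, c(3L, 1L)),
               loss1dCe(l1, targets, c(1L, 3L)))
  expect_warning(z <- loss1dCe(l1, targets, integer(0)), "empty")
  expect_identical(z, 0)
})

test_that("structural contrastive embedding loss matches scalar oracles", {
  ## identical rows -> 0; orthogonal rows contribute 1 each at gamma 2
  p <- rbind(c(1, 0), c(0, 2))
  expect_equal(loss2dSce(p, p, 1:2), 0, tolerance = 1e-9)
  q <- rbind(c(0, 1), c(3, 0))
  expect_equal(loss2dSce(p, q, 1:2, gamma = 2), 2, tolerance = 1e-6)
  ## (1 - cos((1,0),(1,1)))^2 = (1 - 1/sqrt(2))^2
  expect_equal(loss2dSce(matrix(c(1, 0), 1), matrix(c(1, 1), 1), 1L),
               (1 - 1 / sqrt(2))^2, tolerance = 1e-6)
  expect_equal(loss2dSce(matrix(c(1, 0), 1), matrix(c(1, 1), 1), 1L),
               0.085786, tolerance = 1e-5)
  expect_warning(loss2dSce(matrix(0, 1, 2), matrix(c(1, 1), 1), 1L),
                 "zero-norm")
})

test_that("3D losses match coordinate oracles and compose linearly", {
  tgt <- matrix(rnorm(12), 4, 3)
  expect_equal(loss3dMse(tgt, tgt), 0)
  expect_equal(loss3dMse(matrix(c(1, 2, 2), 1), matrix(0, 1, 3)), 9)
  ## common translation of both cancels
  shift <- matrix(rep(c(1, -2, 3), each = 4), 4)
  pred <- tgt + matrix(rnorm(12, 0, 0.1), 4)
  expect_equal(loss3dMse(pred + shift, tgt + shift), loss3dMse(pred, tgt),
               tolerance = 1e-9)
  expect_error(loss3dMse(tgt, tgt[1:2, ]), "differ")

  expect_equal(loss3dCos(tgt, tgt), 0, tolerance = 1e-6)
  expect_equal(loss3dCos(-tgt, tgt), 2, tolerance = 1e-6)
  expect_equal(loss3dCos(matrix(c(1, 0, 0), 1), matrix(c(0, 1, 0), 1)), 1,
               tolerance = 1e-9)

  expect_equal(loss3dDenoise(0, 0, 5, 7), 0)
  expect_equal(loss3dDenoise(9, 1, 1, 1), 10)
  expect_equal(loss3dDenoise(3.3, 1.7, 0, 1), 1.7)
  expect_error(loss3dDenoise(1, 1, -1, 1), "nonnegative")
})

test_that("the total objective is the sum of the modality terms", {
  rep0 <- totalLoss(0, 0, 0, 0)
  expect_equal(rep0$total, 0)
  r <- totalLoss(log(10), 1, 9, 1, lambdaL2 = 1, lambdaCos = 1)
  expect_equal(r$lDenoise3d, 10)
  expect_equal(r$total, log(10) + 1 + 10, tolerance = 1e-9)
  expect_equal(r$total, r$lCe1d + r$lSce2d + r$lDenoise3d)
  ## 3D disabled: its term vanishes and is flagged
  r2 <- totalLoss(2, 3, 100, 100, use3d = FALSE)
  expect_equal(r2$total, 5)
  expect_false(r2$counts$use3d)
})

test_that("tape losses agree with plain implementations and their gradients", {
  set.seed(31)
  V <- 8L; e <- 5L; n <- 6L
  params <- list(logits = matrix(rnorm(e * V), e, V),
                 pred2 = matrix(rnorm(n * 4), n, 4),
                 pred3 = matrix(rnorm(n * 3), n, 3))
  targets <- sample(V, e, replace = TRUE)
  mask <- c(2L, 4L)
  t2 <- matrix(rnorm(n * 4), n, 4)
  t3 <- matrix(rnorm(n * 3), n, 3)
  m2 <- c(1L, 3L, 5L)

  evalLosses <- function(p) {
    tp <- newTape(p)
    list(tp = tp,
         ce = loss1dCeT(tp, adParam(tp, "logits"), targets, mask),
         sce = loss2dSceT(tp, adParam(tp, "pred2"), t2, m2, 2),
         mse = loss3dMseT(tp, adParam(tp, "pred3"), t3),
         cos = loss3dCosT(tp, adParam(tp, "pred3"), t3))
  }
  r <- evalLosses(params)
  expect_equal(nodeValue(r$tp, r$ce)[1],
               loss1dCe(params$logits, targets, mask), tolerance = 1e-8)
  expect_equal(nodeValue(r$tp, r$sce)[1],
               loss2dSce(params$pred2, t2, m2, 2), tolerance = 1e-6)
  expect_equal(nodeValue(r$tp, r$mse)[1],
               loss3dMse(params$pred3, t3), tolerance = 1e-8)
  expect_equal(nodeValue(r$tp, r$cos)[1],
               loss3dCos(params$pred3, t3), tolerance = 1e-6)

  ## analytic gradients vs central finite differences, 1e-4 relative
  cases <- list(ce = c("logits", "ce"), sce = c("pred2", "sce"),
                mse = c("pred3", "mse"), cos = c("pred3", "cos"))
  for (cs in cases) {
    pname <- cs[1]; lname <- cs[2]
    rr <- evalLosses(params)
    backward(rr$tp, rr[[lname]])
    ana <- rr$tp$pgrads[[pname]]
    entries <- seq(1L, length(params[[pname]]), by = 7L)
    fd <- fdGrad(function(p) {
      ev <- evalLosses(p); nodeValue(ev$tp, ev[[lname]])[1]
    }, params, pname, entries)
    denom <- pmax(abs(fd), 1e-3)
    expect_lt(max(abs(ana[entries] - fd) / denom), 1e-4)
  }
})
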