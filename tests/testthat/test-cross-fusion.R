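test_that("padBroadcast replicates the channel vector spatially", {
  out <- padBroadcast(array(c(3, -1), c(2, 1, 1)), 2, 2)
  expect_identical(dim(out), c(2L, 2L, 2L))
  expect_true(all(out[1, , ] == 3))
  expect_true(all(out[2, , ] == -1))
  expect_equal(padBroadcast(c(4, 5), 1, 1)[, 1, 1], c(4, 5))
  x <- runif(3)
  expect_equal(sum(padBroadcast(x, 5, 7)), 5 * 7 * sum(x))
})

test_that("poolGrid computes per-channel spatial mean / max", {
  g <- array(c(0.5, 1.5, 1, 2), c(1, 2, 2))   # [[0.5, 1], [1.5, 2]]
  expect_equal(as.vector(poolGrid(g, "GAP")), 1.25)
  expect_equal(as.vector(poolGrid(g, "GMP")), 2)
  const <- array(7, c(3, 4, 4))
  expect_equal(as.vector(poolGrid(const, "GAP")), rep(7, 3))
  expect_equal(as.vector(poolGrid(const, "GMP")), rep(7, 3))
})

test_that("fuse reproduces the hand-derived scalar fixture", {
  xCls <- array(2, c(1, 1, 1))
  xSeg <- array(c(1, 3, 2, 4), c(1, 2, 2))    # [[1, 2], [3, 4]]
  pGAP <- fusionParams(matrix(0.5, 1, 1), "GAP")
  out <- fuseFeatures(xCls, xSeg, pGAP)
  expect_equal(as.vector(out$xCls), 3.25)
  expect_equal(out$xSeg, array(c(2, 4, 3, 5), c(1, 2, 2)))
  pGMP <- fusionParams(matrix(0.5, 1, 1), "GMP")
  expect_equal(as.vector(fuseFeatures(xCls, xSeg, pGMP)$xCls), 4)
})

test_that("fuse matches the independent nested-loop oracle", {
  set.seed(101)
  for (i in 1:120) {
    C1 <- sample(1:4, 1); C2 <- sample(1:4, 1)
    H <- sample(1:4, 1); W <- sample(1:4, 1)
    xCls <- array(rnorm(C1), c(C1, 1, 1))
    xSeg <- array(rnorm(C2 * H * W), c(C2, H, W))
    M <- matrix(rnorm(C1 * C2), C1, C2)
    mode <- if (i %% 2 == 0) "GAP" else "GMP"
    got <- fuseFeatures(xCls, xSeg, fusionParams(M, mode))
    want <- fuseOracle(as.vector(xCls), xSeg, M, mode)
    expect_lt(max(abs(as.vector(got$xCls) - want$xCls)), 1e-6)
    expect_lt(max(abs(got$xSeg - want$xSeg)), 1e-6)
  }
})

test_that("nonlinear activations are applied to the transformed term", {
  set.seed(7)
  xCls <- array(rnorm(2), c(2, 1, 1))
  xSeg <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  M <- matrix(rnorm(6), 2, 3)
  for (a in c("relu", "tanh")) {
    f <- switch(a, relu = function(z) pmax(z, 0), tanh = tanh)
    got <- fuseFeatures(xCls, xSeg, fusionParams(M, "GAP", a))
    want <- fuseOracle(as.vector(xCls), xSeg, M, "GAP", act = f)
    expect_lt(max(abs(as.vector(got$xCls) - want$xCls)), 1e-10)
    expect_lt(max(abs(got$xSeg - want$xSeg)), 1e-10)
  }
})

test_that("zero matrix gives an exact residual passthrough", {
  set.seed(33)
  for (i in 1:20) {
    C1 <- sample(1:5, 1); C2 <- sample(1:5, 1)
    H <- sample(1:5, 1); W <- sample(1:5, 1)
    xCls <- array(rnorm(C1), c(C1, 1, 1))
    xSeg <- array(rnorm(C2 * H * W), c(C2, H, W))
    mode <- if (i %% 2 == 0) "GAP" else "GMP"
    out <- fuseFeatures(xCls, xSeg,
                        fusionParams(matrix(0, C1, C2), mode))
    expect_lt(max(abs(out$xCls - xCls)), 1e-12)
    expect_lt(max(abs(out$xSeg - xSeg)), 1e-12)
    expect_identical(dim(out$xCls), dim(xCls))
    expect_identical(dim(out$xSeg), dim(xSeg))
    expect_equal(consistencyLoss(xCls, out$xCls), 0)
  }
})

test_that("fusion with identity activation is linear under GAP", {
  set.seed(55)
  xCls <- array(rnorm(3), c(3, 1, 1))
  xSeg <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  p <- fusionParams(matrix(rnorm(6), 3, 2), "GAP")
  base <- fuseFeatures(xCls, xSeg, p)
  s <- 2.7
  scaled <- fuseFeatures(xCls * s, xSeg * s, p)
  expect_equal(scaled$xCls, base$xCls * s, tolerance = 1e-12)
  expect_equal(scaled$xSeg, base$xSeg * s, tolerance = 1e-12)
})

test_that("one shared matrix serves both directions (parameter tying)", {
  withF <- buildMTCSN(c1 = 5L, c2 = 3L, fusionEnabled = TRUE, seed = 1)
  without <- buildMTCSN(c1 = 5L, c2 = 3L, fusionEnabled = FALSE, seed = 1)
  expect_identical(parameterCount(withF) - parameterCount(without), 15L)
  expect_identical(dim(withF@params$fusion.M), c(5L, 3L))
})

test_that("fusionGateReport summarises |M| and ignores orientation", {
  expect_equal(fusionGateReport(matrix(0, 3, 2)),
               list(meanAbs = 0, maxAbs = 0))
  M <- matrix(c(1, -1, 1, -1), 2, 2)
  expect_equal(fusionGateReport(M), list(meanAbs = 1, maxAbs = 1))
  M2 <- matrix(rnorm(12), 3, 4)
  expect_equal(fusionGateReport(M2), fusionGateReport(t(M2)))
})

test_that("batched fusion agrees with the single-sample path", {
  set.seed(77)
  C1 <- 3L; C2 <- 2L; H <- 3L; W <- 2L; N <- 4L
  M <- matrix(rnorm(C1 * C2), C1, C2)
  xClsB <- matrix(rnorm(C1 * N), C1, N)
  xSegB <- matrix(rnorm(C2 * H * W * N), C2, H * W * N)
  fb <- mtcsn:::fuseBatch(xClsB, xSegB, H * W, N, M, "GAP", "identity")
  for (n in seq_len(N)) {
    cols <- (n - 1) * H * W + seq_len(H * W)
    single <- fuseFeatures(array(xClsB[, n], c(C1, 1, 1)),
                           array(xSegB[, cols], c(C2, H, W)),
                           fusionParams(M, "GAP"))
    expect_equal(as.vector(single$xCls), as.vector(fb$xCls[, n]),
                 tolerance = 1e-12)
    expect_equal(as.vector(single$xSeg), as.vector(fb$xSeg[, cols]),
                 tolerance = 1e-12)
  }
})

test_that("fusion rejects mismatched or non-finite inputs", {
  xCls <- array(1, c(2, 1, 1))
  xSeg <- array(1, c(3, 2, 2))
  expect_error(fuseFeatures(xCls, xSeg, fusionParams(matrix(0, 2, 2))),
               "columns")
  expect_error(fuseFeatures(array(c(1, NaN), c(2, 1, 1)), xSeg,
                            fusionParams(matrix(0, 2, 3))), "finite")
})
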