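test_that("encoder output obeys the downsampling shape contract", {
  m <- buildMTCSN(seed = 4)
  img <- generateScene(synthConfig(imageHeight = 48L, imageWidth = 48L,
                                   nSamples = 1L, seed = 2L), 1)
  f <- encodeFeatures(m, imageArray(img))
  expect_identical(dim(f), c(64L, 6L, 6L))   # d = 8, Cs = 64
  expect_all_finite(f)
  # determinism
  expect_identical(f, encodeFeatures(m, imageArray(img)))
  # indivisible input dims are refused, naming the axis
  bad <- array(0, c(44, 48, 3))
  expect_error(encodeFeatures(m, bad), "height")
  expect_error(encodeFeatures(m, array(0, c(48, 44, 3))), "width")
})

test_that("encoder variants expose their depth and downsample factor", {
  for (v in c("tiny", "resnet-style-50", "resnet-style-101",
              "densenet-style-121")) {
    sp <- encoderSpec(v)
    expect_identical(prod(sp@strides), as.double(sp@downsampleFactor))
    expect_identical(sp@outputChannels,
                     sp@channels[length(sp@channels)])
  }
  expect_identical(encoderSpec("tiny")@downsampleFactor, 8L)
})

test_that("classification stem pools a constant grid to its value", {
  m <- buildMTCSN(seed = 1)
  # identity 1x1 transform on a single-channel grid
  m@params$clsStem.W <- matrix(1, 1, 1)
  m@params$clsStem.b <- 0
  g <- array(c(1, 5, 3, 7), c(1, 2, 2))   # [[1, 3], [5, 7]]
  out <- clsStem(m, g)
  expect_identical(dim(out), c(1L, 1L, 1L))
  expect_equal(as.vector(out), 4)
  const <- array(2.5, c(1, 3, 3))
  expect_equal(as.vector(clsStem(m, const)), 2.5)
})

test_that("stems and heads keep the declared shapes", {
  m <- buildMTCSN(seed = 6)
  f <- array(rnorm(64 * 6 * 6, sd = 0.5), c(64, 6, 6))
  xc <- clsStem(m, f)
  expect_identical(dim(xc), c(32L, 1L, 1L))
  xs <- segStem(m, f)
  expect_identical(dim(xs), c(16L, 12L, 12L))
  expect_all_finite(xs)
  logits <- clsHead(m, xc)
  expect_length(logits, 3)
  expect_all_finite(logits)
  seg <- segHead(m, xs, c(48, 48))
  expect_identical(dim(seg), c(8L, 48L, 48L))
  expect_all_finite(seg)
  # zero-weight head gives zero logits
  m@params$clsHead.W <- matrix(0, 3, 32)
  expect_equal(clsHead(m, xc), c(0, 0, 0))
})

test_that("end-to-end forward returns finite logits at full resolution", {
  m <- buildMTCSN(seed = 9)
  s <- generateScene(synthConfig(nSamples = 1L, seed = 14L), 1)
  fw <- forwardMTCSN(m, s)
  expect_identical(dim(fw$clsLogits), c(3L, 1L))
  expect_identical(dim(fw$segLogits[[1]]), c(8L, 96L, 96L))
  expect_all_finite(fw$clsLogits)
  expect_all_finite(fw$segLogits[[1]])
  expect_true(fw$clsPred[1] %in% 1:3)
  expect_true(all(fw$segPred[[1]] %in% 0:7))
})

test_that("perturbing M moves both heads; disabling fusion decouples them", {
  s <- generateScene(synthConfig(imageHeight = 48L, imageWidth = 48L,
                                 nSamples = 1L, seed = 20L), 1)
  m <- buildMTCSN(seed = 3)
  m@params$fusion.M <- matrix(0.05, 32, 16)
  base <- forwardMTCSN(m, s)
  m2 <- m
  m2@params$fusion.M <- m2@params$fusion.M + 0.05
  pert <- forwardMTCSN(m2, s)
  expect_gt(max(abs(pert$clsLogits - base$clsLogits)), 0)
  expect_gt(max(abs(pert$segLogits[[1]] - base$segLogits[[1]])), 0)

  # hard parameter sharing: classification-side weights cannot reach the
  # segmentation head and vice versa
  off <- buildMTCSN(fusionEnabled = FALSE, seed = 3)
  b0 <- forwardMTCSN(off, s)
  offC <- off
  offC@params$clsStem.W <- offC@params$clsStem.W * 2
  b1 <- forwardMTCSN(offC, s)
  expect_identical(b1$segLogits[[1]], b0$segLogits[[1]])
  expect_gt(max(abs(b1$clsLogits - b0$clsLogits)), 0)
  offS <- off
  offS@params$segStem1.W <- offS@params$segStem1.W * 2
  b2 <- forwardMTCSN(offS, s)
  expect_identical(b2$clsLogits, b0$clsLogits)
})

test_that("bilinear resize kernels match their dense-matrix reference", {
  set.seed(42)
  C <- 3L; H <- 5L; W <- 4L; N <- 2L
  x <- matrix(rnorm(C * H * W * N), C)
  for (dims in list(c(10L, 8L), c(3L, 2L), c(5L, 4L))) {
    uh <- mtcsn:::bilinearMatrix(H, dims[1])
    uw <- mtcsn:::bilinearMatrix(W, dims[2])
    want <- mtcsn:::resizeForward(x, H, W, N, uh, uw)
    got <- mtcsn:::resize_bilinear(x, H, W, N, dims[1], dims[2])
    expect_equal(got, want, tolerance = 1e-12)
    # the gradient kernel is the exact adjoint
    dy <- matrix(rnorm(C * dims[1] * dims[2] * N), C)
    dxWant <- mtcsn:::resizeBackward(dy, H, W, N, uh, uw)
    dxGot <- mtcsn:::resize_bilinear_grad(dy, H, W, N, dims[1], dims[2])
    expect_equal(dxGot, dxWant, tolerance = 1e-12)
  }
})
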