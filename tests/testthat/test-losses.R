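test_that("class cross-entropy matches softmax arithmetic", {
  expect_equal(crossEntropyClass(c(0, 0, 0), "invisible"), log(3),
               tolerance = 1e-12)
  expect_lt(crossEntropyClass(c(10, -10, -10), 1), 1e-8)
  expect_equal(crossEntropyClass(c(1, 2, 3), 3), 0.40760596, tolerance = 1e-6)
  # invariant to a common logit shift
  expect_equal(crossEntropyClass(c(1, 2, 3) + 100, 3),
               crossEntropyClass(c(1, 2, 3), 3), tolerance = 1e-9)
  expect_error(crossEntropyClass(c(0, 0, 0), "foggy"), "unknown")
})

test_that("consistency loss is the per-site mean squared gap, summed", {
  expect_equal(consistencyLoss(c(1, 2), c(1, 2)), 0)
  expect_equal(consistencyLoss(c(1, 2), c(2, 4)), 2.5)
  expect_equal(consistencyLoss(list(c(1, 2), c(1, 2)),
                               list(c(2, 4), c(2, 4))), 5)
  expect_error(consistencyLoss(list(1), list(1, 2)), "paired")
  expect_error(consistencyLoss(c(1, 2), c(1, 2, 3)), "shapes")
})

test_that("pixel-wise cross-entropy averages over non-ignored pixels", {
  uni <- array(0, c(8, 2, 2))
  expect_equal(crossEntropyPixelwise(uni, matrix(0L, 2, 2)), log(8),
               tolerance = 1e-12)
  # near-one-hot logits on the true classes
  msk <- matrix(c(0L, 3L, 7L, 5L), 2, 2)
  hot <- array(-20, c(8, 2, 2))
  for (i in 1:2) for (j in 1:2) hot[msk[i, j] + 1, i, j] <- 20
  expect_lt(crossEntropyPixelwise(hot, msk), 1e-6)
  # the ignored pixel is excluded from the mean
  lg <- matrix(0, 8, 2)
  expect_equal(crossEntropyPixelwise(lg, c(0L, 255L)), log(8),
               tolerance = 1e-12)
  expect_error(crossEntropyPixelwise(lg, c(255L, 255L)), "ignored")
  expect_error(crossEntropyPixelwise(lg, c(0L, 9L)), "range")
})

test_that("total loss combines components with the configured weights", {
  expect_error(lossConfig(0, 0), "positive")
  b <- totalLoss(0.3, 0, 0.7, lossConfig(1, 1, alpha = 0))
  expect_equal(b@total, 1.0)
  b2 <- totalLoss(0.3, 2.5, 0.7, lossConfig(1, 1, alpha = 0.1))
  expect_equal(b2@total, 1.25)
  expect_equal(b2@total,
               1 * (b2@clsCe + 0.1 * b2@consistency) + 1 * b2@segCe,
               tolerance = 1e-9)
  # monotone in alpha for fixed components
  totals <- vapply(c(0, 0.1, 0.5, 2),
                   function(a) totalLoss(0.3, 2.5, 0.7,
                                         lossConfig(alpha = a))@total,
                   numeric(1))
  expect_true(all(diff(totals) >= 0))
  expect_error(totalLoss(-0.1, 0, 0.7), "non-negative")
  # zero only when all weighted components are zero
  expect_equal(totalLoss(0, 0, 0)@total, 0)
  expect_gt(totalLoss(0, 0, 1e-3)@total, 0)
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(19)
  eps <- 1e-6
  # classification head gradient
  logits <- matrix(rnorm(3 * 4), 3, 4)
  labels <- sample(1:3, 4, replace = TRUE)
  an <- mtcsn:::clsLossGrad(logits, labels)
  for (i in sample(length(logits), 6)) {
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    fd <- (mtcsn:::clsLossGrad(lp, labels)$loss -
             mtcsn:::clsLossGrad(lm, labels)$loss) / (2 * eps)
    expect_equal(an$grad[i], fd, tolerance = 1e-4)
  }
  # pixel-wise gradient with ignored entries
  plog <- matrix(rnorm(8 * 10), 8, 10)
  pmask <- c(sample(0:7, 8, replace = TRUE), 255L, 255L)
  anp <- mtcsn:::pixelLossGrad(plog, pmask)
  expect_true(all(anp$grad[, 9:10] == 0))
  for (i in sample(which(rep(pmask, each = 8) != 255L), 6)) {
    lp <- plog; lp[i] <- lp[i] + eps
    lm <- plog; lm[i] <- lm[i] - eps
    fd <- (mtcsn:::pixelLossGrad(lp, pmask)$loss -
             mtcsn:::pixelLossGrad(lm, pmask)$loss) / (2 * eps)
    expect_equal(anp$grad[i], fd, tolerance = 1e-4)
  }
  # consistency gradient (both sides)
  before <- matrix(rnorm(6), 2, 3)
  after <- matrix(rnorm(6), 2, 3)
  cg <- mtcsn:::consistencyGrad(list(list(before = before, after = after)))
  for (i in 1:6) {
    bp <- before; bp[i] <- bp[i] + eps
    fdB <- (consistencyLoss(bp, after) - consistencyLoss(before, after)) / eps
    expect_equal(cg$grads[[1]]$before[i], fdB, tolerance = 1e-4)
    ap <- after; ap[i] <- ap[i] + eps
    fdA <- (consistencyLoss(before, ap) - consistencyLoss(before, after)) / eps
    expect_equal(cg$grads[[1]]$after[i], fdA, tolerance = 1e-4)
  }
})

test_that("end-to-end parameter gradients pass a finite-difference check", {
  set.seed(42)
  m <- buildMTCSN(c1 = 4L, c2 = 3L, seed = 2)
  m@params$fusion.M <- matrix(rnorm(12, sd = 0.3), 4, 3)
  H <- W <- 16L; N <- 2L
  x <- matrix(rnorm(3 * H * W * N, sd = 0.3), 3)
  labels <- c(1L, 3L)
  masks <- sample(0:7, H * W * N, replace = TRUE)
  lc <- lossConfig(0.7, 1.3, alpha = 0.1)
  lossOf <- function(model) {
    fw <- mtcsn:::mtcsnForwardBatch(model, x, H, W, N, keepCache = TRUE)
    cl <- mtcsn:::clsLossGrad(fw$clsLogits, labels)
    sl <- mtcsn:::pixelLossGrad(fw$segLogits, masks)
    cg <- mtcsn:::consistencyGrad(fw$consistencySites)
    list(total = lc@lambdaCls * (cl$loss + lc@alpha * cg$loss) +
           lc@lambdaSeg * sl$loss, fw = fw, cl = cl, sl = sl, cg = cg)
  }
  r <- lossOf(m)
  w <- lc@lambdaCls * lc@alpha
  dSite <- lapply(r$cg$grads, function(g)
    list(before = w * g$before, after = w * g$after))
  g <- mtcsn:::mtcsnBackwardBatch(m, r$fw$cache, lc@lambdaCls * r$cl$grad,
                                  lc@lambdaSeg * r$sl$grad, dSite)
  eps <- 1e-5
  for (pn in c("enc1.W", "clsStem.W", "segStem2.W", "clsHead.b",
               "segHead.W", "fusion.M")) {
    for (i in sample(length(m@params[[pn]]), 2)) {
      mp <- m; mp@params[[pn]][i] <- mp@params[[pn]][i] + eps
      mm <- m; mm@params[[pn]][i] <- mm@params[[pn]][i] - eps
      fd <- (lossOf(mp)$total - lossOf(mm)$total) / (2 * eps)
      expect_equal(g[[pn]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", pn, i))
    }
  }
})

test_that("consistency vanishes when fusion is disabled or M is zero", {
  s <- generateScene(synthConfig(imageHeight = 48L, imageWidth = 48L,
                                 nSamples = 1L, seed = 31L), 1)
  x <- mtcsn:::imageToTensor(imageArray(s))
  off <- buildMTCSN(fusionEnabled = FALSE, seed = 5)
  fw <- mtcsn:::mtcsnForwardBatch(off, x, 48L, 48L, 1L)
  expect_length(fw$consistencySites, 0)
  on0 <- buildMTCSN(fusionEnabled = TRUE, seed = 5)   # M initialised at 0
  fw0 <- mtcsn:::mtcsnForwardBatch(on0, x, 48L, 48L, 1L)
  expect_equal(mtcsn:::consistencyGrad(fw0$consistencySites)$loss, 0)
})
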