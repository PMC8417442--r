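# Model container, forward pass and manual backward pass.
#
# The network: shared conv encoder -> (classification stem: 1x1 conv +
# ReLU + GAP) and (segmentation stem: 1x1 conv + ReLU + 2x bilinear
# upsample + 3x3 conv + ReLU) -> cross fusion between the pooled
# classification vector and the segmentation grid -> (FC head -> 3
# clearness logits) and (1x1 conv head -> bilinear upsample to input
# resolution -> 8 per-pixel logits).

#' Construct a multi-task classification/segmentation model
#'
#' Builds the network with freshly initialised weights (He init, seeded).
#' The fusion matrix `M` starts at zero, i.e. training begins from exact
#' hard parameter sharing and the network learns the extent of
#' cross-branch sharing.
#'
#' @param encoder An [EncoderSpec-class]; default `encoderSpec("tiny")`.
#' @param c1 Channels of the classification branch feature.
#' @param c2 Channels of the segmentation branch feature.
#' @param nClearness Number of image-level classes (3).
#' @param nSegClasses Number of mask classes (8).
#' @param fusionEnabled Logical; `FALSE` gives the hard-parameter-sharing
#'   baseline (no `M`, branches independent given the encoder output).
#' @param fusionSites Number of consecutive applications of the fusion
#'   module (all sharing the same `M`); default 1.
#' @param poolMode,activation Passed to the fusion module; see
#'   [fusionParams()].
#' @param seed Integer seed for weight initialisation.
#' @return An [MTCSNModel-class].
#' @examples
#' m <- buildMTCSN(seed = 1)
#' parameterCount(m)
#' @export
buildMTCSN <- function(encoder = encoderSpec("tiny"), c1 = 32L, c2 = 16L,
                       nClearness = 3L, nSegClasses = 8L,
                       fusionEnabled = TRUE, fusionSites = 1L,
                       poolMode = "GAP", activation = "identity",
                       seed = 1L) {
  stopifnot(is(encoder, "EncoderSpec"))
  c1 <- as.integer(c1); c2 <- as.integer(c2)
  stopIf(c1 < 1L || c2 < 1L, "c1 and c2 must be positive")
  params <- withSeed(seed, {
    p <- list()
    cin <- 3L
    for (i in seq_along(encoder@channels)) {
      cout <- encoder@channels[i]
      p[[sprintf("enc%d.W", i)]] <- heInit(cout, cin * 9L)
      p[[sprintf("enc%d.b", i)]] <- numeric(cout)
      cin <- cout
    }
    cs <- encoder@outputChannels
    p[["clsStem.W"]] <- heInit(c1, cs)
    p[["clsStem.b"]] <- numeric(c1)
    p[["segStem1.W"]] <- heInit(c2, cs)
    p[["segStem1.b"]] <- numeric(c2)
    p[["segStem2.W"]] <- heInit(c2, c2 * 9L)
    p[["segStem2.b"]] <- numeric(c2)
    p[["clsHead.W"]] <- heInit(nClearness, c1)
    p[["clsHead.b"]] <- numeric(nClearness)
    p[["segHead.W"]] <- heInit(nSegClasses, c2)
    p[["segHead.b"]] <- numeric(nSegClasses)
    if (fusionEnabled) p[["fusion.M"]] <- matrix(0, c1, c2)
    p
  })
  new("MTCSNModel", encoder = encoder, c1 = c1, c2 = c2,
      nClearness = as.integer(nClearness),
      nSegClasses = as.integer(nSegClasses),
      fusionEnabled = fusionEnabled,
      fusionSites = as.integer(fusionSites),
      poolMode = poolMode, activation = activation,
      params = params, arch = list(segUpsample = 2L))
}

#' @rdname parameterCount
#' @export
setMethod("parameterCount", "MTCSNModel", function(object) {
  sum(vapply(object@params, length, integer(1)))
})

#' @noRd
checkDivisible <- function(H, W, d) {
  stopIf(H %% d != 0,
         sprintf("input height %d is not divisible by downsample factor %d",
                 H, d))
  stopIf(W %% d != 0,
         sprintf("input width %d is not divisible by downsample factor %d",
                 W, d))
}

# Full forward pass on a batch tensor x (3 x (H*W*N), intensities already
# normalised).  Returns logits and, when keepCache, every intermediate
# needed by mtcsnBackwardBatch.
#' @noRd
mtcsnForwardBatch <- function(model, x, H, W, N, keepCache = FALSE) {
  p <- model@params
  enc <- model@encoder
  checkDivisible(H, W, enc@downsampleFactor)
  cache <- list(x = x, H = H, W = W, N = N)
  cur <- x; curH <- H; curW <- W
  convs <- list()
  for (i in seq_along(enc@channels)) {
    cf <- convForward(cur, curH, curW, N, p[[sprintf("enc%d.W", i)]],
                      p[[sprintf("enc%d.b", i)]], 3L, 3L,
                      enc@strides[i], 1L)
    out <- reluForward(cf$out)
    convs[[i]] <- list(col = cf$col, preH = curH, preW = curW,
                       inMat = cur, out = out)
    cur <- out; curH <- cf$H; curW <- cf$W
  }
  feat <- cur                    # Cs x (hF*wF*N)
  hF <- curH; wF <- curW
  # classification stem
  clsA <- reluForward(p$clsStem.W %*% feat + p$clsStem.b)
  xCls0 <- globalPool(clsA, hF * wF, N, "GAP")            # C1 x N
  # segmentation stem
  seg1 <- reluForward(p$segStem1.W %*% feat + p$segStem1.b)
  up <- model@arch$segUpsample
  hS <- hF * up; wS <- wF * up
  seg1u <- resize_bilinear(seg1, hF, wF, N, hS, wS)
  cf2 <- convForward(seg1u, hS, wS, N, p$segStem2.W, p$segStem2.b,
                     3L, 3L, 1L, 1L)
  xSeg0 <- reluForward(cf2$out)                           # C2 x (hS*wS*N)
  # cross fusion
  xCls <- xCls0; xSeg <- xSeg0
  sites <- list()
  if (model@fusionEnabled) {
    for (s in seq_len(model@fusionSites)) {
      fb <- fuseBatch(xCls, xSeg, hS * wS, N, p$fusion.M,
                      model@poolMode, model@activation)
      sites[[s]] <- list(clsBefore = xCls, clsAfter = fb$xCls,
                         segBefore = xSeg, cache = fb$cache)
      xCls <- fb$xCls; xSeg <- fb$xSeg
    }
  }
  # heads
  clsLogits <- p$clsHead.W %*% xCls + p$clsHead.b         # 3 x N
  segPre <- p$segHead.W %*% xSeg + p$segHead.b            # 8 x (hS*wS*N)
  segLogits <- resize_bilinear(segPre, hS, wS, N, H, W)   # 8 x (H*W*N)
  out <- list(clsLogits = clsLogits, segLogits = segLogits,
              xClsBefore = xCls0, xClsAfter = xCls,
              consistencySites = lapply(sites, function(s)
                list(before = s$clsBefore, after = s$clsAfter)))
  if (keepCache) {
    out$cache <- c(cache, list(
      convs = convs, feat = feat, hF = hF, wF = wF, clsA = clsA,
      xCls0 = xCls0, seg1 = seg1, seg1u = seg1u, cf2col = cf2$col,
      xSeg0 = xSeg0, xSegFinal = xSeg, xClsFinal = xCls, sites = sites,
      hS = hS, wS = wS))
  }
  out
}

# Backward pass.  dCls (3 x N) and dSeg (8 x (H*W*N)) are the loss
# gradients at the heads; dClsSite gives extra gradient pairs injected by
# the consistency penalty (same length as fusion sites, each a list with
# `before` and `after` C1 x N matrices; may be NULL).
#' @noRd
mtcsnBackwardBatch <- function(model, cache, dCls, dSeg, dClsSite = NULL) {
  p <- model@params
  g <- lapply(p, function(w) array(0, dim(w) %||% length(w)))
  names(g) <- names(p)
  N <- cache$N
  hS <- cache$hS; wS <- cache$wS
  # seg head + upsample
  dSegPre <- resize_bilinear_grad(dSeg, hS, wS, N, cache$H, cache$W)
  g$segHead.W <- tcrossprod(dSegPre, cache$xSegFinal)
  g$segHead.b <- rowSums(dSegPre)
  dxSeg <- crossprod(p$segHead.W, dSegPre)
  # cls head
  g$clsHead.W <- tcrossprod(dCls, cache$xClsFinal)
  g$clsHead.b <- rowSums(dCls)
  dxCls <- crossprod(p$clsHead.W, dCls)
  # fusion (reverse site order), with consistency gradient injection
  if (model@fusionEnabled && length(cache$sites)) {
    for (s in rev(seq_along(cache$sites))) {
      st <- cache$sites[[s]]
      if (!is.null(dClsSite)) dxCls <- dxCls + dClsSite[[s]]$after
      fb <- fuseBatchBackward(dxCls, dxSeg, st$clsBefore, st$segBefore,
                              hS * wS, N, p$fusion.M, model@poolMode,
                              model@activation, st$cache)
      g$fusion.M <- g$fusion.M + fb$dM
      dxCls <- fb$dxCls
      dxSeg <- fb$dxSeg
      if (!is.null(dClsSite)) dxCls <- dxCls + dClsSite[[s]]$before
    }
  }
  # segmentation stem
  dxSeg0 <- reluBackward(dxSeg, cache$xSeg0)
  cb2 <- convBackward(dxSeg0, cache$cf2col, cache$seg1u, hS, wS, N,
                      p$segStem2.W, 3L, 3L, 1L, 1L)
  g$segStem2.W <- cb2$dW; g$segStem2.b <- cb2$db
  dSeg1u <- cb2$dx
  dSeg1 <- resize_bilinear_grad(dSeg1u, cache$hF, cache$wF, N,
                                hS, wS)
  dSeg1 <- reluBackward(dSeg1, cache$seg1)
  g$segStem1.W <- tcrossprod(dSeg1, cache$feat)
  g$segStem1.b <- rowSums(dSeg1)
  dFeat <- crossprod(p$segStem1.W, dSeg1)
  # classification stem
  hwF <- cache$hF * cache$wF
  dClsA <- globalPoolBackward(dxCls, cache$clsA, hwF, N, "GAP")
  dClsA <- reluBackward(dClsA, cache$clsA)
  g$clsStem.W <- tcrossprod(dClsA, cache$feat)
  g$clsStem.b <- rowSums(dClsA)
  dFeat <- dFeat + crossprod(p$clsStem.W, dClsA)
  # encoder (reverse)
  enc <- model@encoder
  dcur <- dFeat
  for (i in rev(seq_along(enc@channels))) {
    cv <- cache$convs[[i]]
    dcur <- reluBackward(dcur, cv$out)
    cb <- convBackward(dcur, cv$col, cv$inMat, cv$preH, cv$preW, N,
                       p[[sprintf("enc%d.W", i)]], 3L, 3L,
                       enc@strides[i], 1L)
    g[[sprintf("enc%d.W", i)]] <- cb$dW
    g[[sprintf("enc%d.b", i)]] <- cb$db
    dcur <- cb$dx
  }
  g
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Single-sample convenience wrappers (spec-level operations)
# ---------------------------------------------------------------------------

#' @noRd
imageToTensor <- function(image) {
  d <- dim(image)
  m <- t(matrix(as.vector(image), d[1] * d[2], 3))
  m / 255 - 0.5
}

#' Encode an image with the shared backbone
#'
#' @param model An [MTCSNModel-class].
#' @param image H x W x 3 intensity array (0..255); H and W must be
#'   divisible by the encoder's downsample factor.
#' @return Feature array `[Cs, H/d, W/d]`.
#' @export
encodeFeatures <- function(model, image) {
  stopifnot(is(model, "MTCSNModel"))
  d <- dim(image)
  stopIf(length(d) != 3L || d[3] != 3L, "image must be H x W x 3")
  enc <- model@encoder
  checkDivisible(d[1], d[2], enc@downsampleFactor)
  x <- imageToTensor(image)
  p <- model@params
  cur <- x; curH <- d[1]; curW <- d[2]
  for (i in seq_along(enc@channels)) {
    cf <- convForward(cur, curH, curW, 1L, p[[sprintf("enc%d.W", i)]],
                      p[[sprintf("enc%d.b", i)]], 3L, 3L, enc@strides[i], 1L)
    cur <- reluForward(cf$out)
    curH <- cf$H; curW <- cf$W
  }
  array(aperm(array(cur, c(nrow(cur), curH, curW)), c(1, 2, 3)),
        c(nrow(cur), curH, curW))
}

#' Branch stems and heads applied to single-sample features
#'
#' `clsStem` maps a shared feature grid to the pooled classification
#' vector (1x1 conv, ReLU, global average pooling); `segStem` maps it to
#' the segmentation feature grid (1x1 conv, ReLU, 2x bilinear upsample,
#' 3x3 conv, ReLU); `clsHead` produces the 3 clearness logits and
#' `segHead` the per-pixel class logits upsampled to `outDims`.
#'
#' @param model An [MTCSNModel-class].
#' @param feature `[Cs, H', W']` array from [encodeFeatures()].
#' @param xCls `[C1, 1, 1]` array (or length-C1 vector).
#' @param xSeg `[C2, H', W']` array.
#' @param outDims Integer pair `(H, W)` for the output logit resolution.
#' @return `clsStem`: `[C1, 1, 1]`; `segStem`: `[C2, 2H', 2W']`;
#'   `clsHead`: numeric length-3 logits; `segHead`: `[8, H, W]` logits.
#' @name branch-ops
NULL

#' @rdname branch-ops
#' @export
clsStem <- function(model, feature) {
  d <- dim(feature)
  m <- matrix(feature, d[1], d[2] * d[3])
  a <- reluForward(model@params$clsStem.W %*% m + model@params$clsStem.b)
  array(rowMeans(a), c(nrow(a), 1, 1))
}

#' @rdname branch-ops
#' @export
segStem <- function(model, feature) {
  d <- dim(feature)
  p <- model@params
  m <- matrix(feature, d[1], d[2] * d[3])
  s1 <- reluForward(p$segStem1.W %*% m + p$segStem1.b)
  up <- model@arch$segUpsample
  hS <- d[2] * up; wS <- d[3] * up
  s1u <- resize_bilinear(s1, d[2], d[3], 1L, hS, wS)
  cf <- convForward(s1u, hS, wS, 1L, p$segStem2.W, p$segStem2.b,
                    3L, 3L, 1L, 1L)
  array(reluForward(cf$out), c(nrow(cf$out), hS, wS))
}

#' @rdname branch-ops
#' @export
clsHead <- function(model, xCls) {
  v <- as.vector(xCls)
  as.vector(model@params$clsHead.W %*% v + model@params$clsHead.b)
}

#' @rdname branch-ops
#' @export
segHead <- function(model, xSeg, outDims) {
  d <- dim(xSeg)
  p <- model@params
  pre <- p$segHead.W %*% matrix(xSeg, d[1], d[2] * d[3]) + p$segHead.b
  out <- resize_bilinear(pre, d[2], d[3], 1L, outDims[1], outDims[2])
  array(out, c(nrow(pre), outDims[1], outDims[2]))
}

#' Full forward pass on one or more frames
#'
#' @param model An [MTCSNModel-class].
#' @param samples A single [ImageSample-class], an H x W x 3 array, or a
#'   list of either.
#' @return List with `clsLogits` (3 x N matrix) and `segLogits` (list of
#'   `[8, H, W]` arrays), plus `clsPred` (factor-coded 1..3) and
#'   `segPred` (list of H x W integer masks).
#' @export
forwardMTCSN <- function(model, samples) {
  if (!is.list(samples)) samples <- list(samples)
  imgs <- lapply(samples, function(s)
    if (is(s, "ImageSample")) imageArray(s) else s)
  d <- dim(imgs[[1]])
  N <- length(imgs)
  x <- matrix(0, 3, d[1] * d[2] * N)
  for (n in seq_len(N))
    x[, (n - 1) * d[1] * d[2] + seq_len(d[1] * d[2])] <-
      imageToTensor(imgs[[n]])
  fw <- mtcsnForwardBatch(model, x, d[1], d[2], N)
  hw <- d[1] * d[2]
  segLogits <- lapply(seq_len(N), function(n)
    array(fw$segLogits[, (n - 1) * hw + seq_len(hw)],
          c(model@nSegClasses, d[1], d[2])))
  segPred <- lapply(segLogits, function(sl) {
    m <- matrix(sl, dim(sl)[1], hw)
    matrix(max.col(t(m), ties.method = "first") - 1L, d[1], d[2])
  })
  list(clsLogits = fw$clsLogits,
       clsPred = apply(fw$clsLogits, 2, which.max),
       segLogits = segLogits, segPred = segPred)
}
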