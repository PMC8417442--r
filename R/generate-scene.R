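# Scene composition for synthetic capsule-endoscopy frames.
#
# Frames are painted back to front: mucosa wall (background), lumen hole,
# clear-tissue folds, lesions, excreta, bubbles, specular reflections,
# then optional global motion blur.  The mask records the topmost class
# per pixel; under heavy blur, clear-tissue pixels are relabeled as blur
# tissue (the occluder/lesion classes keep their identity).  Every draw
# goes through a per-sample seeded RNG so (seed, index) determines each
# byte of the output.

# pixel-coordinate grids; rows are y (image height), columns x
sceneGrids <- function(H, W) {
  list(x = matrix(seq_len(W), H, W, byrow = TRUE),
       y = matrix(seq_len(H), H, W))
}

# squared normalized elliptical radius; <= 1 is inside
ellipseR2 <- function(g, cx, cy, rx, ry, angle = 0) {
  dx <- g$x - cx
  dy <- g$y - cy
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  (u / rx)^2 + (v / ry)^2
}

# irregular blob: ellipse whose radius wobbles sinusoidally with angle
blobMask <- function(g, cx, cy, rx, ry, angle = 0, wobble = 0.25,
                     lobes = NULL, phase = NULL) {
  if (is.null(lobes)) lobes <- sample(3:6, 1)
  if (is.null(phase)) phase <- runif(1, 0, 2 * pi)
  dx <- g$x - cx
  dy <- g$y - cy
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  r <- sqrt((u / rx)^2 + (v / ry)^2)
  th <- atan2(v / ry, u / rx)
  r <= 1 + wobble * sin(lobes * th + phase)
}

speckle <- function(H, W, amp) matrix(runif(H * W, -amp, amp), H, W)

# smooth low-frequency field from bilinearly upsampled coarse noise
lowFreqField <- function(H, W, amp, n = 6L) {
  gcoarse <- matrix(runif(n * n, -amp, amp), n, n)
  uh <- bilinearMatrix(n, H)
  uw <- bilinearMatrix(n, W)
  uh %*% gcoarse %*% t(uw)
}

# paint `color` (+ per-pixel texture) over selected pixels of all channels
paintRegion <- function(img, sel, color, texture = NULL, blend = 1) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    val <- color[ch]
    if (!is.null(texture)) val <- val + texture[[ch]][sel]
    plane[sel] <- (1 - blend) * plane[sel] + blend * val
    img[, , ch] <- plane
  }
  img
}

# shift a matrix by (dy, dx) with edge replication
shiftReplicate <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) - dy, 1L), H)
  ci <- pmin(pmax(seq_len(W) - dx, 1L), W)
  m[ri, ci, drop = FALSE]
}

# linear motion blur: average of L copies shifted along a line
applyMotionBlur <- function(img, length, angle) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ts <- seq_len(length) - (length + 1) / 2
  out <- array(0, dim(img))
  for (ch in 1:3) {
    acc <- matrix(0, H, W)
    for (t in ts)
      acc <- acc + shiftReplicate(img[, , ch], round(t * sin(angle)),
                                  round(t * cos(angle)))
    out[, , ch] <- acc / length
  }
  out
}

#' Generate one synthetic capsule-endoscopy frame
#'
#' Composes a warm-toned tubular mucosa scene with a darker lumen hole,
#' clear-tissue folds, reddened lesion patches, excreta blobs, bubble
#' clusters (bright translucent or opaque), optional specular highlights
#' and optional global motion blur, together with the per-pixel class
#' mask and the rule-derived clearness label.  Output is fully
#' deterministic given `(config@seed, index)`.
#'
#' @param config A [SynthConfig-class].
#' @param index 1-based sample index, `<= config@nSamples`.
#' @return An [ImageSample-class] with 8-bit intensities, an integer mask
#'   coded by [tissuePalette()] order and `splitTag = "unassigned"`.
#' @examples
#' s <- generateScene(synthConfig(nSamples = 2, seed = 3), 1)
#' table(maskArray(s))
#' @export
generateScene <- function(config, index) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  stopIf(!isCount(index) || index < 1 || index > config@nSamples,
         "index must be in 1..nSamples")
  H <- config@imageHeight
  W <- config@imageWidth
  stopIf(H * W == 0, "degenerate configuration: zero image area")

  withSeed(deriveSeed(config@seed, index), {
    g <- sceneGrids(H, W)
    img <- array(0, c(H, W, 3))
    mask <- matrix(0L, H, W)

    # -- mucosa wall (background, class 0)
    illum <- lowFreqField(H, W, 18)
    rr <- ellipseR2(g, W / 2, H / 2, W / 1.3, H / 1.3)
    shade <- 1 - 0.35 * pmin(rr, 1)
    spk <- speckle(H, W, 26)
    base <- c(158, 99, 92)
    chScale <- c(1, 0.8, 0.8)
    for (ch in 1:3)
      img[, , ch] <- (base[ch] + illum * chScale[ch]) * shade +
        spk * chScale[ch] + speckle(H, W, 8)

    # -- lumen hole (class 4), darker toward its center
    hr2 <- ellipseR2(g, runif(1, 0.3, 0.7) * W, runif(1, 0.3, 0.7) * H,
                     runif(1, 0.14, 0.26) * W, runif(1, 0.14, 0.26) * H,
                     runif(1, 0, pi))
    sel <- hr2 <= 1
    grad <- 0.55 + 0.45 * sqrt(pmin(hr2, 1))
    tex <- lapply(c(14, 8, 8), function(a) speckle(H, W, a) * grad)
    holeCol <- c(55, 28, 26)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- holeCol[ch] * grad[sel] + tex[[ch]][sel]
      img[, , ch] <- plane
    }
    mask[sel] <- 4L

    # -- clear-tissue folds (class 1), ridged texture
    for (k in seq_len(sample(1:3, 1))) {
      sel <- ellipseR2(g, runif(1, 0.15, 0.85) * W, runif(1, 0.15, 0.85) * H,
                       runif(1, 0.16, 0.34) * W, runif(1, 0.16, 0.34) * H,
                       runif(1, 0, pi)) <= 1
      a <- runif(1, 0, pi)
      ridges <- 14 * sin(2 * pi * runif(1, 4, 9) *
                           (cos(a) * g$x + sin(a) * g$y) / W +
                           runif(1, 0, 2 * pi))
      spk1 <- speckle(H, W, 20)
      tex <- list(ridges + spk1, 0.8 * (ridges + spk1), 0.8 * (ridges + spk1))
      img <- paintRegion(img, sel, c(205, 125, 112), tex)
      mask[sel] <- 1L
    }

    # -- lesions (class 3), reddened with a darker rim
    nLes <- sample(0:3, 1, prob = c(0.2, 0.35, 0.3, 0.15))
    for (k in seq_len(nLes)) {
      r2 <- ellipseR2(g, runif(1, 0.15, 0.85) * W, runif(1, 0.15, 0.85) * H,
                      runif(1, 0.06, 0.12) * W, runif(1, 0.06, 0.12) * H,
                      runif(1, 0, pi))
      sel <- r2 <= 1
      rim <- 1 - 0.3 * pmin(r2, 1)
      tex <- lapply(c(18, 10, 10), function(a) speckle(H, W, a))
      lesCol <- c(172, 38, 46)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[sel] <- lesCol[ch] * rim[sel] + tex[[ch]][sel]
        img[, , ch] <- plane
      }
      mask[sel] <- 3L
    }

    # -- excreta occlusion (class 6): coverage drawn from the configured
    #    range with a long-tailed shape, so heavy occlusion is rare
    covRange <- config@excretaCoverageRange
    target <- covRange[1] + (covRange[2] - covRange[1]) * runif(1)^7
    if (target >= 0.005) {
      covered <- matrix(FALSE, H, W)
      tries <- 0L
      while (mean(covered) < 0.95 * target && tries < 60L) {
        tries <- tries + 1L
        grow <- 1 + 2 * sqrt(max(target - mean(covered), 0))
        covered <- covered | blobMask(
          g, runif(1, 0.1, 0.9) * W, runif(1, 0.1, 0.9) * H,
          runif(1, 0.09, 0.16) * W * grow, runif(1, 0.09, 0.16) * H * grow,
          runif(1, 0, pi))
      }
      tex <- lapply(c(15, 15, 10), function(a) speckle(H, W, a))
      tex[[2]] <- tex[[2]] + lowFreqField(H, W, 12)   # greenish mottling
      img <- paintRegion(img, covered, c(118, 108, 48), tex)
      mask[covered] <- 6L
    }

    # -- bubbles: opaque clusters occlude (class 5), translucent ones are
    #    annotated as clear bubble (class 7)
    bRange <- config@bubbleCountRange
    nBub <- if (bRange[2] > 0) sample(bRange[1]:bRange[2], 1) else 0L
    opaqueProb <- 0.30
    if (bRange[2] > 0 && runif(1) < 0.02) {   # rare foam frame
      nBub <- nBub + 14L
      opaqueProb <- 0.9
    }
    for (k in seq_len(nBub)) {
      cx <- runif(1, 0.08, 0.92) * W
      cy <- runif(1, 0.08, 0.92) * H
      nDisc <- sample(1:3, 1)
      opaque <- runif(1) < opaqueProb
      for (d in seq_len(nDisc)) {
        r <- runif(1, 0.06, 0.12) * W
        dcx <- cx + runif(1, -0.6, 0.6) * r
        dcy <- cy + runif(1, -0.6, 0.6) * r
        r2 <- ellipseR2(g, dcx, dcy, r, r * runif(1, 0.85, 1.15))
        sel <- r2 <= 1
        if (opaque) {
          shadeB <- 1 - 0.18 * pmin(r2, 1)
          tex <- lapply(c(6, 6, 6), function(a) speckle(H, W, a))
          bubCol <- c(208, 206, 212)
          for (ch in 1:3) {
            plane <- img[, , ch]
            plane[sel] <- bubCol[ch] * shadeB[sel] + tex[[ch]][sel]
            img[, , ch] <- plane
          }
          mask[sel] <- 5L
        } else {
          img <- paintRegion(img, sel, c(175, 205, 235), blend = 0.5)
          rimSel <- r2 <= 1 & r2 > 0.7
          for (ch in 1:3) {
            plane <- img[, , ch]
            plane[rimSel] <- plane[rimSel] + 50
            img[, , ch] <- plane
          }
          mask[sel] <- 7L
        }
      }
    }

    # -- specular reflections: bright spots, no mask change
    if (runif(1) < config@reflectionProb) {
      for (k in seq_len(sample(1:4, 1))) {
        r <- runif(1, 1.5, 3.5)
        sel <- ellipseR2(g, runif(1, 0.05, 0.95) * W,
                         runif(1, 0.05, 0.95) * H, r,
                         r * runif(1, 0.7, 1.3), runif(1, 0, pi)) <= 1
        img <- paintRegion(img, sel, c(248, 246, 240))
      }
    }

    # -- global motion blur; heavy kernels relabel clear tissue as blur
    blurApplied <- FALSE
    if (runif(1) < config@blurProb) {
      img <- applyMotionBlur(img, config@blurKernelLength, runif(1, 0, pi))
      if (config@blurKernelLength >= 5L) {
        blurApplied <- TRUE
        mask[mask == 1L] <- 2L
      }
    }

    img <- round(clamp255(img))
    label <- deriveClearness(mask, blurApplied,
                             config@tauInvisible, config@tauBlur)
    new("ImageSample",
        image = img, mask = mask, clearness = label,
        blurApplied = blurApplied,
        sampleId = sprintf("synth-%05d", index),
        splitTag = "unassigned")
  })
}

#' Generate a full synthetic dataset
#'
#' @param config A [SynthConfig-class]; `config@nSamples` frames are
#'   generated.
#' @return List of [ImageSample-class] objects.
#' @seealso [generateScene()], [stratifiedSplit()], [writeDataset()]
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  lapply(seq_len(config@nSamples), function(i) generateScene(config, i))
}
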