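#' Loss configuration
#'
#' The training objective is the weighted multi-task sum
#' \deqn{L = \lambda_{cls}\,(L_{cls} + \alpha L_{consistency}) +
#'       \lambda_{seg} L_{seg}}
#' where \eqn{L_{cls}} is the image-level softmax cross-entropy,
#' \eqn{L_{seg}} the pixel-wise softmax cross-entropy (ignoring the
#' reserved mask code), and \eqn{L_{consistency}} the mean-squared
#' distance between the classification-branch features before and after
#' cross fusion, summed over fusion sites.
#'
#' @param lambdaCls,lambdaSeg Non-negative task weights; at least one
#'   must be positive.  Default 1 and 1.
#' @param alpha Non-negative consistency weight; default 0.1.
#' @param ignoreIndex Mask code excluded from the pixel loss.
#' @return A [LossConfig-class].
#' @export
lossConfig <- function(lambdaCls = 1, lambdaSeg = 1, alpha = 0.1,
                       ignoreIndex = 255L) {
  cfg <- new("LossConfig", lambdaCls = as.numeric(lambdaCls),
             lambdaSeg = as.numeric(lambdaSeg), alpha = as.numeric(alpha),
             ignoreIndex = as.integer(ignoreIndex))
  validObject(cfg)
  cfg
}

#' Image-level classification cross-entropy
#'
#' `-log softmax(logits)[label]` for one frame.
#'
#' @param logits Numeric vector of class logits (length 3 for the
#'   clearness task).
#' @param label Class as 1-based index or a [clearnessLevels()] name.
#' @return Non-negative scalar loss.
#' @examples
#' crossEntropyClass(c(0, 0, 0), "blur")   # log(3)
#' @export
crossEntropyClass <- function(logits, label) {
  stopIf(!all(is.finite(logits)), "logits must be finite")
  if (is.character(label)) {
    label <- match(label, clearnessLevels())
    stopIf(is.na(label), "unknown clearness label")
  }
  stopIf(label < 1 || label > length(logits), "label index out of range")
  m <- max(logits)
  (m + log(sum(exp(logits - m)))) - logits[label]
}

#' Consistency loss between pre- and post-fusion features
#'
#' Sum over fusion sites of the mean squared elementwise difference
#' between the paired features.  Zero exactly when fusion leaves the
#' features untouched (e.g. fusion disabled or `M = 0`).
#'
#' @param before,after Array, or list of arrays (one per fusion site)
#'   with matching shapes.
#' @return Non-negative scalar.
#' @examples
#' consistencyLoss(c(1, 2), c(2, 4))   # mean(1, 4) = 2.5
#' @export
consistencyLoss <- function(before, after) {
  if (!is.list(before)) before <- list(before)
  if (!is.list(after)) after <- list(after)
  stopIf(length(before) != length(after),
         "before/after site lists must be paired")
  total <- 0
  for (i in seq_along(before)) {
    b <- before[[i]]; a <- after[[i]]
    stopIf(length(a) != length(b),
           sprintf("site %d: feature shapes differ", i))
    total <- total + mean((a - b)^2)
  }
  total
}

#' Pixel-wise segmentation cross-entropy
#'
#' Mean over non-ignored pixels of the per-pixel softmax cross-entropy.
#'
#' @param logits `[K, H, W]` array (or `K x (H*W)` matrix) of class
#'   logits.
#' @param mask H x W integer matrix (or vector) of true class codes
#'   0-based, with `ignoreIndex` marking unlabeled pixels.
#' @param ignoreIndex Reserved code excluded from the mean.
#' @return Non-negative scalar; errors if every pixel is ignored.
#' @examples
#' lg <- array(0, c(8, 2, 2))
#' crossEntropyPixelwise(lg, matrix(0L, 2, 2))   # log(8)
#' @export
crossEntropyPixelwise <- function(logits, mask, ignoreIndex = 255L) {
  d <- dim(logits)
  m <- if (length(d) == 3L) matrix(logits, d[1], d[2] * d[3]) else logits
  v <- as.vector(mask)
  stopIf(ncol(m) != length(v), "logits and mask disagree on pixel count")
  valid <- v != ignoreIndex
  stopIf(!any(valid), "all pixels are ignored")
  stopIf(any(v[valid] < 0 | v[valid] >= nrow(m)),
         "mask contains class codes outside the logit range")
  m <- m[, valid, drop = FALSE]
  lab <- v[valid] + 1L
  mx <- apply(m, 2, max)
  lse <- mx + log(colSums(exp(sweep(m, 2, mx))))
  mean(lse - m[cbind(lab, seq_along(lab))])
}

#' Combine task losses into the multi-task objective
#'
#' @param clsCe Image-level cross-entropy.
#' @param consistency Consistency loss (see [consistencyLoss()]).
#' @param segCe Pixel-wise cross-entropy.
#' @param config A [LossConfig-class].
#' @return A [LossBreakdown-class]; its `total` satisfies
#'   `lambdaCls * (clsCe + alpha * consistency) + lambdaSeg * segCe`.
#' @examples
#' totalLoss(0.3, 2.5, 0.7, lossConfig(alpha = 0.1))
#' @export
totalLoss <- function(clsCe, consistency, segCe, config = lossConfig()) {
  stopifnot(is(config, "LossConfig"))
  validObject(config)
  vals <- c(clsCe, consistency, segCe)
  stopIf(any(!is.finite(vals)) || any(vals < 0),
         "loss components must be finite and non-negative")
  total <- config@lambdaCls * (clsCe + config@alpha * consistency) +
    config@lambdaSeg * segCe
  b <- new("LossBreakdown", clsCe = clsCe, consistency = consistency,
           segCe = segCe, total = total)
  validObject(b)
  b
}

# ---------------------------------------------------------------------------
# Batched losses with gradients (training path)
# ---------------------------------------------------------------------------

# logits: K x N, labels: 1-based integer vector.  Mean loss over batch
# plus gradient wrt logits (stable log-sum-exp in C++).
#' @noRd
clsLossGrad <- function(logits, labels) {
  softmax_ce_grad(logits, as.integer(labels) - 1L, -1L)
}

# logits: K x P, maskVec: 0-based labels with ignore code.  Mean over
# valid pixels plus gradient.
#' @noRd
pixelLossGrad <- function(logits, maskVec, ignore = 255L) {
  softmax_ce_grad(logits, as.integer(maskVec), as.integer(ignore))
}

# MSE consistency over fusion sites with gradients for both sides.
#' @noRd
consistencyGrad <- function(sites) {
  loss <- 0
  grads <- lapply(sites, function(s) {
    diff <- s$after - s$before
    n <- length(diff)
    loss <<- loss + mean(diff^2)
    list(before = -2 * diff / n, after = 2 * diff / n)
  })
  list(loss = loss, grads = grads)
}
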