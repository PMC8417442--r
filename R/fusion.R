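#' Cross fusion parameters
#'
#' The cross fusion module exchanges information between the pooled
#' classification feature (shape `[C1, 1, 1]`) and the segmentation
#' feature grid (shape `[C2, H, W]`) through a single shared
#' transformation matrix `M` (realized as a 1x1 convolution kernel):
#'
#' \deqn{\tilde X_{cls} = X_{cls} + \mathrm{Pool}(\sigma(M X_{seg})),\qquad
#'       \tilde X_{seg} = X_{seg} + \sigma(M^T \mathrm{Pad}(X_{cls}))}
#'
#' Both directions use the same parameter tensor (transpose-tied), so the
#' module adds exactly `C1 * C2` parameters.  `Pad` replicates the
#' classification vector over the spatial grid; `Pool` is global average
#' (GAP) or global max (GMP) pooling; the optional elementwise
#' nonlinearity \eqn{\sigma} defaults to the identity, in which case the
#' module is exactly the linear residual exchange above.
#'
#' @param M Numeric `C1 x C2` matrix (finite).
#' @param poolMode `"GAP"` (default; GMP tends to propagate outliers) or
#'   `"GMP"`.
#' @param activation `"identity"` (default), `"relu"` or `"tanh"`,
#'   applied to the transformed term before the residual addition.
#' @return A [FusionParams-class] object.
#' @examples
#' p <- fusionParams(matrix(0.5, 1, 1))
#' fuseFeatures(array(2, c(1, 1, 1)),
#'              array(c(1, 3, 2, 4), c(1, 2, 2)), p)
#' @export
fusionParams <- function(M, poolMode = "GAP", activation = "identity") {
  p <- new("FusionParams", M = as.matrix(M), poolMode = poolMode,
           activation = activation)
  validObject(p)
  p
}

#' @noRd
fusionActivation <- function(name) {
  switch(name,
         identity = list(f = function(z) z, df = function(z) 1),
         relu = list(f = function(z) pmax(z, 0),
                     df = function(z) (z > 0) * 1),
         tanh = list(f = tanh, df = function(z) 1 - tanh(z)^2))
}

#' Broadcast a classification vector over a spatial grid
#'
#' Spatial replication of the `[C1, 1, 1]` classification feature to
#' `[C1, H, W]`: every location carries the same channel vector.
#'
#' @param xCls Numeric vector of length `C1`, or an array `[C1, 1, 1]`.
#' @param H,W Target spatial dimensions.
#' @return Array of dimension `c(C1, H, W)`.
#' @export
padBroadcast <- function(xCls, H, W) {
  v <- as.vector(xCls)
  stopIf(H < 1 || W < 1, "target grid must be at least 1x1")
  array(rep(v, times = H * W), c(length(v), H, W))
}

#' Global pooling of a feature grid
#'
#' @param grid Array `[C, H, W]`.
#' @param mode `"GAP"` (per-channel spatial mean) or `"GMP"`
#'   (per-channel spatial max).
#' @return Array `[C, 1, 1]`.
#' @export
poolGrid <- function(grid, mode = c("GAP", "GMP")) {
  mode <- match.arg(mode)
  d <- dim(grid)
  stopIf(length(d) != 3L, "grid must be a [C, H, W] array")
  m <- matrix(grid, d[1], d[2] * d[3])
  v <- if (mode == "GAP") rowMeans(m) else apply(m, 1, max)
  array(v, c(d[1], 1, 1))
}

#' Apply the cross fusion module to one feature pair
#'
#' See [fusionParams()] for the exchange rule.  With `M = 0` the module
#' is an exact passthrough (residual identity); with the identity
#' activation it is linear in both inputs.
#'
#' @param xCls Classification feature: vector of length `C1` or array
#'   `[C1, 1, 1]`.
#' @param xSeg Segmentation feature: array `[C2, H, W]`.
#' @param params A [FusionParams-class] with `M` of shape `C1 x C2`.
#' @return List with fused `xCls` (`[C1, 1, 1]`) and `xSeg`
#'   (`[C2, H, W]`), shapes equal to the inputs.
#' @export
fuseFeatures <- function(xCls, xSeg, params) {
  stopifnot(is(params, "FusionParams"))
  d <- dim(xSeg)
  stopIf(length(d) != 3L, "xSeg must be a [C2, H, W] array")
  v <- as.vector(xCls)
  stopIf(!all(is.finite(v)) || !all(is.finite(xSeg)),
         "fusion inputs must be finite")
  M <- params@M
  stopIf(nrow(M) != length(v),
         sprintf("M has %d rows but xCls has %d channels", nrow(M),
                 length(v)))
  stopIf(ncol(M) != d[1],
         sprintf("M has %d columns but xSeg has %d channels", ncol(M),
                 d[1]))
  res <- fuseBatch(matrix(v), matrix(xSeg, d[1], d[2] * d[3]),
                   d[2] * d[3], 1L, M, params@poolMode,
                   params@activation)
  list(xCls = array(res$xCls, c(length(v), 1, 1)),
       xSeg = array(res$xSeg, d))
}

# Batched fusion on column-matrix tensors: xCls is C1 x N, xSeg is
# C2 x (HW*N).  Returns fused features plus caches for the backward pass.
#' @noRd
fuseBatch <- function(xCls, xSeg, HW, N, M, poolMode, activation) {
  act <- fusionActivation(activation)
  zSeg2cls <- M %*% xSeg                 # C1 x (HW*N)
  aSeg2cls <- act$f(zSeg2cls)
  pooled <- globalPool(aSeg2cls, HW, N, poolMode)
  zCls2seg <- crossprod(M, xCls)         # C2 x N
  aCls2seg <- act$f(zCls2seg)
  rep_idx <- rep(seq_len(N), each = HW)
  xSegOut <- xSeg + aCls2seg[, rep_idx, drop = FALSE]
  list(xCls = xCls + pooled, xSeg = xSegOut,
       cache = list(zSeg2cls = zSeg2cls, aSeg2cls = aSeg2cls,
                    zCls2seg = zCls2seg, repIdx = rep_idx))
}

# Backward of fuseBatch.  dCls: C1 x N, dSeg: C2 x (HW*N).
#' @noRd
fuseBatchBackward <- function(dCls, dSeg, xCls, xSeg, HW, N, M,
                              poolMode, activation, cache) {
  act <- fusionActivation(activation)
  # path: xSeg -> M xSeg -> act -> pool -> +xCls
  dPooled <- globalPoolBackward(dCls, cache$aSeg2cls, HW, N, poolMode)
  dZ1 <- dPooled * act$df(cache$zSeg2cls)
  dxSeg <- dSeg + crossprod(M, dZ1)
  dM <- tcrossprod(dZ1, xSeg)
  # path: xCls -> M^T xCls -> act -> broadcast -> +xSeg
  dA2 <- rowsumByBlock(dSeg, HW, N)      # C2 x N, sum over spatial
  dZ2 <- dA2 * act$df(cache$zCls2seg)
  dxCls <- dCls + M %*% dZ2
  dM <- dM + tcrossprod(xCls, dZ2)
  list(dxCls = dxCls, dxSeg = dxSeg, dM = dM)
}

# sum a C x (HW*N) tensor over spatial positions -> C x N
#' @noRd
rowsumByBlock <- function(x, HW, N) {
  C <- nrow(x)
  a <- array(x, c(C, HW, N))
  out <- matrix(0, C, N)
  for (n in seq_len(N)) out[, n] <- rowSums(matrix(a[, , n], C, HW))
  out
}

#' Summary of the learned sharing extent
#'
#' Reports the mean and maximum absolute entry of the fusion matrix `M`,
#' a quick gauge of how strongly the network couples the two branches
#' (near-zero entries make layers effectively task-specific).
#'
#' @param params A [FusionParams-class], or a numeric matrix `M`.
#' @return List with `meanAbs` and `maxAbs`.
#' @export
fusionGateReport <- function(params) {
  M <- if (is(params, "FusionParams")) params@M else as.matrix(params)
  if (length(M) == 0) return(list(meanAbs = 0, maxAbs = 0))
  list(meanAbs = mean(abs(M)), maxAbs = max(abs(M)))
}
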