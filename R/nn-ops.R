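# Low-level network primitives.
#
# Feature tensors are C x (H*W*N) matrices throughout (column index
# h + H*(w + W*n)); convolutions run as weight %*% im2col(column matrix)
# so BLAS does the heavy lifting, with the im2col/col2im gather/scatter
# in C++.  All layers have matching manual backward passes; correctness
# is pinned by finite-difference tests.

#' @noRd
convForward <- function(x, H, W, N, weight, bias, kh, kw, stride, pad) {
  if (kh == 1L && kw == 1L && stride == 1L && pad == 0L) {
    col <- x
  } else {
    col <- conv_im2col(x, H, W, N, kh, kw, stride, pad)
  }
  out <- weight %*% col + bias
  Ho <- (H + 2 * pad - kh) %/% stride + 1L
  Wo <- (W + 2 * pad - kw) %/% stride + 1L
  list(out = out, col = col, H = Ho, W = Wo)
}

#' @noRd
convBackward <- function(dout, col, x, H, W, N, weight, kh, kw, stride, pad) {
  dW <- tcrossprod(dout, col)
  db <- rowSums(dout)
  dcol <- crossprod(weight, dout)
  dx <- if (kh == 1L && kw == 1L && stride == 1L && pad == 0L) dcol else
    conv_col2im(dcol, nrow(x), H, W, N, kh, kw, stride, pad)
  list(dW = dW, db = db, dx = dx)
}

#' @noRd
reluForward <- function(x) relu_fwd(x)

#' @noRd
reluBackward <- function(dout, out) relu_bwd(dout, out)

# Interpolation matrix U (nOut x nIn) for 1-D bilinear resize with
# half-pixel centre alignment; 2-D resize is U_h %*% X %*% t(U_w).
#' @noRd
bilinearMatrix <- function(nIn, nOut) {
  U <- matrix(0, nOut, nIn)
  src <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5
  lo <- floor(src)
  frac <- src - lo
  lo0 <- pmin(pmax(lo, 0), nIn - 1)
  hi0 <- pmin(lo + 1, nIn - 1)
  for (i in seq_len(nOut)) {
    U[i, lo0[i] + 1] <- U[i, lo0[i] + 1] + (1 - frac[i])
    U[i, hi0[i] + 1] <- U[i, hi0[i] + 1] + frac[i]
  }
  U
}

# resize a C x (H*W*N) tensor spatially with precomputed row/col matrices.
# Reference implementation; the training path uses the equivalent C++
# resize_bilinear / resize_bilinear_grad (4-tap direct loop).
#' @noRd
resizeForward <- function(x, H, W, N, uh, uw) {
  C <- nrow(x)
  Ho <- nrow(uh); Wo <- nrow(uw)
  a <- aperm(array(x, c(C, H, W, N)), c(2, 1, 3, 4))      # H,C,W,N
  m1 <- uh %*% matrix(a, H, C * W * N)                    # Ho x (C*W*N)
  a2 <- aperm(array(m1, c(Ho, C, W, N)), c(3, 2, 1, 4))   # W,C,Ho,N
  m2 <- uw %*% matrix(a2, W, C * Ho * N)                  # Wo x (C*Ho*N)
  a3 <- aperm(array(m2, c(Wo, C, Ho, N)), c(2, 3, 1, 4))  # C,Ho,Wo,N
  matrix(a3, C, Ho * Wo * N)
}

#' @noRd
resizeBackward <- function(dout, H, W, N, uh, uw) {
  resizeForward(dout, nrow(uh), nrow(uw), N, t(uh), t(uw))
}

# global spatial pooling of a C x (H*W*N) tensor to C x N
#' @noRd
globalPool <- function(x, HW, N, mode = c("GAP", "GMP")) {
  mode <- match.arg(mode)
  C <- nrow(x)
  a <- array(x, c(C, HW, N))
  out <- matrix(0, C, N)
  for (n in seq_len(N)) {
    sl <- matrix(a[, , n], C, HW)
    out[, n] <- if (mode == "GAP") rowMeans(sl) else apply(sl, 1, max)
  }
  out
}

# backward of global pooling; `x` is the pooled input (needed for GMP)
#' @noRd
globalPoolBackward <- function(dout, x, HW, N, mode = c("GAP", "GMP")) {
  mode <- match.arg(mode)
  C <- nrow(x)
  if (mode == "GAP") {
    dx <- matrix(0, C, HW * N)
    for (n in seq_len(N)) {
      cols <- (n - 1L) * HW + seq_len(HW)
      dx[, cols] <- dout[, n] / HW
    }
    dx
  } else {
    dx <- matrix(0, C, HW * N)
    a <- array(x, c(C, HW, N))
    for (n in seq_len(N)) {
      sl <- matrix(a[, , n], C, HW)
      # route gradient to the first maximal location per channel
      first <- max.col(sl, ties.method = "first")
      cols <- (n - 1L) * HW
      for (c in seq_len(C)) dx[c, cols + first[c]] <- dout[c, n]
    }
    dx
  }
}

# column-wise softmax with log-sum-exp stabilisation
#' @noRd
softmaxCols <- function(logits) {
  C <- nrow(logits)
  m <- logits[1, ]
  if (C > 1) for (r in 2:C) m <- pmax(m, logits[r, ])
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

#' @noRd
heInit <- function(nOut, nIn) {
  matrix(rnorm(nOut * nIn, sd = sqrt(2 / nIn)), nOut, nIn)
}
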