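# Shared fixtures and independent oracles.

# Independent nested-loop implementation of the cross fusion exchange:
#   out_cls[c1] = x_cls[c1] + Pool_{h,w}( act( sum_c2 M[c1,c2] x_seg[c2,h,w] ) )
#   out_seg[c2,h,w] = x_seg[c2,h,w] + act( sum_c1 M[c1,c2] x_cls[c1] )
# Written with scalar loops only, sharing no code with fuseFeatures().
fuseOracle <- function(xCls, xSeg, M, pool = "GAP", act = identity) {
  C1 <- length(xCls)
  d <- dim(xSeg)
  C2 <- d[1]; H <- d[2]; W <- d[3]
  outCls <- numeric(C1)
  for (c1 in seq_len(C1)) {
    vals <- matrix(0, H, W)
    for (h in seq_len(H)) for (w in seq_len(W)) {
      s <- 0
      for (c2 in seq_len(C2)) s <- s + M[c1, c2] * xSeg[c2, h, w]
      vals[h, w] <- act(s)
    }
    pooled <- if (pool == "GAP") mean(vals) else max(vals)
    outCls[c1] <- xCls[c1] + pooled
  }
  outSeg <- array(0, d)
  for (c2 in seq_len(C2)) {
    s <- 0
    for (c1 in seq_len(C1)) s <- s + M[c1, c2] * xCls[c1]
    for (h in seq_len(H)) for (w in seq_len(W))
      outSeg[c2, h, w] <- xSeg[c2, h, w] + act(s)
  }
  list(xCls = outCls, xSeg = outSeg)
}

# minimal sample with a given clearness label (for split tests)
mkLabeledSample <- function(label, id) {
  code <- switch(label, clearness = 1L, blur = 2L, invisible = 6L)
  new("ImageSample", image = array(0, c(2, 2, 3)),
      mask = matrix(code, 2, 2), clearness = label, blurApplied = FALSE,
      sampleId = id, splitTag = "unassigned")
}

# small real dataset for pipeline tests (48x48 keeps them quick)
smallDataset <- function(n, seed) {
  generateDataset(synthConfig(imageHeight = 48L, imageWidth = 48L,
                              nSamples = n, seed = seed))
}

# The end-to-end study conditions: 400 synthetic frames at 96x96 under
# seed 7 with a stratified 80/10/10 split.  Generated once per test run.
.accEnv <- new.env(parent = emptyenv())
accDataset <- function() {
  if (is.null(.accEnv$split)) {
    ds <- generateDataset(synthConfig(nSamples = 400L, seed = 7L))
    .accEnv$split <- stratifiedSplit(ds, c(0.8, 0.1, 0.1), seed = 7)
  }
  .accEnv$split
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
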