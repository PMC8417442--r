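#' Stratified train/val/test split by clearness category
#'
#' Samples are partitioned per clearness category with largest-remainder
#' rounding, so within each category the realized counts differ from
#' `fraction * category size` by less than one sample.  Shuffling within
#' categories is seeded; the same seed reproduces the identical
#' partition.
#'
#' @param samples List of [ImageSample-class] objects (every clearness
#'   category present must have at least one sample).
#' @param fractions Numeric triple `(train, val, test)` summing to 1.
#' @param seed Integer seed for the within-category shuffles.
#' @return List with elements `train`, `val`, `test`: disjoint lists of
#'   samples with `splitTag` set accordingly; their union is the input.
#' @examples
#' ds <- generateDataset(synthConfig(nSamples = 10, seed = 2))
#' sp <- stratifiedSplit(ds, c(0.8, 0.1, 0.1), seed = 1)
#' lengths(sp)
#' @export
stratifiedSplit <- function(samples, fractions = c(0.8, 0.1, 0.1),
                            seed = 1L) {
  stopIf(length(fractions) != 3L || any(fractions < 0),
         "fractions must be three non-negative numbers")
  stopIf(abs(sum(fractions) - 1) > 1e-9, "fractions must sum to 1")
  labels <- vapply(samples, clearness, character(1))
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  withSeed(seed, {
    for (lev in clearnessLevels()) {
      idx <- which(labels == lev)
      m <- length(idx)
      if (m == 0L) next
      counts <- largestRemainder(fractions * m)
      idx <- idx[sample.int(m)]
      ends <- cumsum(counts)
      parts$train <- c(parts$train, idx[seq_len(counts[1])])
      parts$val <- c(parts$val, idx[seq_len(counts[2]) + ends[1]])
      parts$test <- c(parts$test, idx[seq_len(counts[3]) + ends[2]])
    }
  })
  tagged <- function(ids, tag) lapply(samples[sort(ids)], function(s) {
    s@splitTag <- tag
    s
  })
  list(train = tagged(parts$train, "train"),
       val = tagged(parts$val, "val"),
       test = tagged(parts$test, "test"))
}

# integer apportionment: floors plus the largest fractional remainders
#' @noRd
largestRemainder <- function(quota) {
  base <- floor(quota + 1e-9)
  left <- as.integer(round(sum(quota))) - sum(base)
  if (left > 0) {
    rem <- quota - base
    give <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}
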