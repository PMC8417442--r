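#' @noRd
clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' @noRd
clamp255 <- function(x) pmin(pmax(x, 0), 255)

# Run `expr` under a deterministic RNG state without disturbing the
# caller's stream.  All generator and training randomness goes through
# this so that (seed, index) fully determines the output.
#' @noRd
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derived per-sample seed, kept inside 32-bit integer range.
#' @noRd
deriveSeed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) * 1000003 + as.double(index) * 7919 +
          as.double(salt) * 104729) %% 2147483629
  as.integer(s)
}

#' @noRd
stopIf <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' @noRd
isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0
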