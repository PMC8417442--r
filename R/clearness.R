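#' Derive the image-level clearness label from a mask
#'
#' Operationalises the adequacy assessment behind the 3-level clearness
#' degree: a frame is "invisible" when occluding classes (invisible by
#' bubble, invisible by excreta) cover at least `tauInvisible` of its
#' labeled pixels; otherwise it is "blur" when global motion blur was
#' applied or blur-tissue pixels reach `tauBlur`; otherwise "clearness".
#' The rule is deterministic, so stored labels can always be re-audited
#' from the mask.
#'
#' @param mask H x W integer matrix of class codes 0..7 (255 = ignore).
#' @param blurApplied Logical flag: was global motion blur applied to the
#'   frame?
#' @param tauInvisible,tauBlur Decision thresholds in `[0, 1]`.
#' @return One of `"invisible"`, `"blur"`, `"clearness"`.
#' @examples
#' m <- matrix(1L, 4, 4)          # all clear tissue
#' deriveClearness(m, FALSE)      # "clearness"
#' deriveClearness(m, TRUE)       # "blur"
#' @export
deriveClearness <- function(mask, blurApplied,
                            tauInvisible = 0.4, tauBlur = 0.25) {
  v <- as.vector(mask)
  valid <- v != ignoreIndex()
  stopIf(!any(valid), "mask has no labeled pixels (all ignore)")
  stopIf(!all(v[valid] %in% 0:7), "mask contains invalid class codes")
  v <- v[valid]
  n <- length(v)
  fInv <- sum(v == 5L | v == 6L) / n
  fBlur <- sum(v == 2L) / n
  if (fInv >= tauInvisible) return("invisible")
  if (isTRUE(blurApplied) || fBlur >= tauBlur) return("blur")
  "clearness"
}
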