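#' Accessors for ImageSample
#'
#' @param object,x An [ImageSample-class] object.
#' @param value Replacement value.
#' @return `clearness()` the clearness label; `sampleId()` the identifier;
#'   `splitTag()` the split assignment; `imageArray()` the H x W x 3
#'   intensity array; `maskArray()` the H x W integer class mask.
#' @name imageSample-accessors
#' @aliases clearness sampleId splitTag imageArray maskArray
NULL

#' @rdname imageSample-accessors
#' @export
setGeneric("clearness", function(object) standardGeneric("clearness"))
#' @rdname imageSample-accessors
#' @export
setMethod("clearness", "ImageSample", function(object) object@clearness)

#' @rdname imageSample-accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname imageSample-accessors
#' @export
setMethod("sampleId", "ImageSample", function(object) object@sampleId)

#' @rdname imageSample-accessors
#' @export
setGeneric("splitTag", function(object) standardGeneric("splitTag"))
#' @rdname imageSample-accessors
#' @export
setMethod("splitTag", "ImageSample", function(object) object@splitTag)

#' @rdname imageSample-accessors
#' @export
setGeneric("splitTag<-", function(object, value) standardGeneric("splitTag<-"))
#' @rdname imageSample-accessors
#' @export
setMethod("splitTag<-", "ImageSample", function(object, value) {
  object@splitTag <- value
  validObject(object)
  object
})

#' @rdname imageSample-accessors
#' @export
setGeneric("imageArray", function(object) standardGeneric("imageArray"))
#' @rdname imageSample-accessors
#' @export
setMethod("imageArray", "ImageSample", function(object) object@image)

#' @rdname imageSample-accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname imageSample-accessors
#' @export
setMethod("maskArray", "ImageSample", function(object) object@mask)

#' Number of trainable parameters
#'
#' @param object An [MTCSNModel-class].
#' @return Integer count of scalar parameters, including the fusion
#'   matrix when fusion is enabled.
#' @export
setGeneric("parameterCount", function(object) standardGeneric("parameterCount"))

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf("SynthConfig: %d samples, %dx%d px, seed %d\n",
              object@nSamples, object@imageHeight, object@imageWidth,
              object@seed))
  cat(sprintf("  blur: p=%.2f, kernel %d px | bubbles: %d-%d | excreta: %.2f-%.2f | reflections: p=%.2f\n",
              object@blurProb, object@blurKernelLength,
              object@bubbleCountRange[1], object@bubbleCountRange[2],
              object@excretaCoverageRange[1], object@excretaCoverageRange[2],
              object@reflectionProb))
  cat(sprintf("  clearness thresholds: tau_invisible=%.2f, tau_blur=%.2f\n",
              object@tauInvisible, object@tauBlur))
})

setMethod("show", "ImageSample", function(object) {
  d <- dim(object@image)
  cat(sprintf("ImageSample '%s': %dx%d, clearness=%s, split=%s\n",
              object@sampleId, d[1], d[2], object@clearness,
              object@splitTag))
  tab <- table(factor(as.vector(object@mask), levels = c(0:7, ignoreIndex())))
  present <- names(tab)[tab > 0]
  cat("  mask classes present:", paste(present, collapse = ", "), "\n")
})

setMethod("show", "FusionParams", function(object) {
  cat(sprintf("FusionParams: M is %dx%d, pool=%s, activation=%s\n",
              nrow(object@M), ncol(object@M), object@poolMode,
              object@activation))
  r <- fusionGateReport(object)
  cat(sprintf("  |M|: mean %.4g, max %.4g\n", r$meanAbs, r$maxAbs))
})

setMethod("show", "LossBreakdown", function(object) {
  cat(sprintf(
    "LossBreakdown: total %.4f (cls %.4f, consistency %.4f, seg %.4f)\n",
    object@total, object@clsCe, object@consistency, object@segCe))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  cat(sprintf("  classification: accuracy %.4f, precision %.4f, recall %.4f, F1 %.4f\n",
              object@accuracy, object@precision, object@recall, object@f1))
  cat(sprintf("  segmentation:   mIoU %.4f, mACC %.4f, pixel accuracy %.4f\n",
              object@mIoU, object@mACC, object@pixelAccuracy))
})

setMethod("show", "MTCSNModel", function(object) {
  cat(sprintf("MTCSNModel (%s encoder, d=%d)\n",
              object@encoder@variant, object@encoder@downsampleFactor))
  cat(sprintf("  C1=%d, C2=%d, fusion=%s (pool %s, activation %s)\n",
              object@c1, object@c2,
              if (object@fusionEnabled) "on" else "off",
              object@poolMode, object@activation))
  cat(sprintf("  %d trainable parameters\n", parameterCount(object)))
})
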