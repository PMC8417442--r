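#' Tissue class palette
#'
#' Ordered names of the eight segmentation classes.  Index-coded masks use
#' 0-based codes in palette order (0 = background ... 7 = clear bubble);
#' the reserved code 255 marks unlabeled pixels and is excluded from
#' losses and metrics.
#'
#' @return Character vector of length 8.
#' @examples
#' tissuePalette()
#' @export
tissuePalette <- function() c(
  "background", "clear_tissue", "blur_tissue", "lesion", "hole",
  "invisible_by_bubble", "invisible_by_excreta", "clear_bubble"
)

#' Clearness degree levels
#'
#' The three image-level usability labels, in fixed order.
#'
#' @return Character vector of length 3.
#' @export
clearnessLevels <- function() c("clearness", "blur", "invisible")

#' Reserved ignore code for unlabeled pixels
#' @return The integer 255.
#' @export
ignoreIndex <- function() 255L

# ---------------------------------------------------------------------------
# Synthetic generator configuration
# ---------------------------------------------------------------------------

#' @rdname synthConfig
#' @export
setClass("SynthConfig", representation(
  imageHeight = "integer",
  imageWidth = "integer",
  nSamples = "integer",
  classPalette = "character",
  blurKernelLength = "integer",
  blurProb = "numeric",
  bubbleCountRange = "integer",
  excretaCoverageRange = "numeric",
  reflectionProb = "numeric",
  tauInvisible = "numeric",
  tauBlur = "numeric",
  seed = "integer"
))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@imageHeight < 32L || object@imageWidth < 32L)
    msg <- c(msg, "image dimensions must be at least 32 pixels")
  if (object@nSamples < 0L)
    msg <- c(msg, "nSamples must be non-negative")
  if (length(object@classPalette) != 8L || anyDuplicated(object@classPalette))
    msg <- c(msg, "classPalette must have exactly 8 distinct entries")
  probs <- c(object@blurProb, object@reflectionProb,
             object@tauInvisible, object@tauBlur)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    msg <- c(msg, "probabilities and thresholds must lie in [0, 1]")
  if (object@blurKernelLength < 1L)
    msg <- c(msg, "blurKernelLength must be a positive pixel count")
  if (length(object@bubbleCountRange) != 2L ||
      any(object@bubbleCountRange < 0L) ||
      object@bubbleCountRange[1] > object@bubbleCountRange[2])
    msg <- c(msg, "bubbleCountRange must be a non-decreasing pair of counts")
  if (length(object@excretaCoverageRange) != 2L ||
      any(object@excretaCoverageRange < 0) ||
      any(object@excretaCoverageRange > 1) ||
      object@excretaCoverageRange[1] > object@excretaCoverageRange[2])
    msg <- c(msg, "excretaCoverageRange must be a non-decreasing pair in [0, 1]")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# One annotated frame
# ---------------------------------------------------------------------------

#' @rdname imageSample
#' @export
setClass("ImageSample", representation(
  image = "array",       # H x W x 3, 8-bit intensities stored as numeric
  mask = "matrix",       # H x W integer codes 0..7 or 255
  clearness = "character",
  blurApplied = "logical",
  sampleId = "character",
  splitTag = "character"
))

setValidity("ImageSample", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "image must be an H x W x 3 array")
  if (!identical(dim(object@mask), d[1:2]))
    msg <- c(msg, "mask and image must share spatial dimensions")
  vals <- unique(as.vector(object@mask))
  if (!all(vals %in% c(0:7, ignoreIndex())))
    msg <- c(msg, "mask values must be class codes 0..7 or the ignore code")
  if (!object@clearness %in% clearnessLevels())
    msg <- c(msg, sprintf("unknown clearness label '%s'", object@clearness))
  if (!object@splitTag %in% c("train", "val", "test", "unassigned"))
    msg <- c(msg, sprintf("unknown split tag '%s'", object@splitTag))
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Cross fusion parameters
# ---------------------------------------------------------------------------

#' @rdname fusionParams
#' @export
setClass("FusionParams", representation(
  M = "matrix",          # C1 x C2, shared by both directions
  poolMode = "character",
  activation = "character"
))

setValidity("FusionParams", function(object) {
  msg <- character()
  if (!all(is.finite(object@M)))
    msg <- c(msg, "M must be finite")
  if (!object@poolMode %in% c("GAP", "GMP"))
    msg <- c(msg, "poolMode must be 'GAP' or 'GMP'")
  if (!object@activation %in% c("identity", "relu", "tanh"))
    msg <- c(msg, "activation must be 'identity', 'relu' or 'tanh'")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Loss configuration and breakdown
# ---------------------------------------------------------------------------

#' @rdname lossConfig
#' @export
setClass("LossConfig", representation(
  lambdaCls = "numeric",
  lambdaSeg = "numeric",
  alpha = "numeric",
  ignoreIndex = "integer"
))

setValidity("LossConfig", function(object) {
  msg <- character()
  if (object@lambdaCls < 0 || object@lambdaSeg < 0)
    msg <- c(msg, "task weights must be non-negative")
  if (object@lambdaCls + object@lambdaSeg <= 0)
    msg <- c(msg, "at least one task weight must be positive")
  if (object@alpha < 0)
    msg <- c(msg, "consistency weight alpha must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname totalLoss
#' @export
setClass("LossBreakdown", representation(
  clsCe = "numeric",
  consistency = "numeric",
  segCe = "numeric",
  total = "numeric"
))

setValidity("LossBreakdown", function(object) {
  vals <- c(object@clsCe, object@consistency, object@segCe, object@total)
  if (any(!is.finite(vals)) || any(vals < -1e-12))
    "loss components must be finite and non-negative" else TRUE
})

# ---------------------------------------------------------------------------
# Metrics report
# ---------------------------------------------------------------------------

#' @rdname classificationMetrics
#' @export
setClass("MetricsReport", representation(
  clsConfusion = "matrix",
  accuracy = "numeric",
  precision = "numeric",
  recall = "numeric",
  f1 = "numeric",
  segConfusion = "matrix",
  perClassIoU = "numeric",
  mIoU = "numeric",
  mACC = "numeric",
  pixelAccuracy = "numeric"
))

# ---------------------------------------------------------------------------
# Encoder description and model container
# ---------------------------------------------------------------------------

#' @rdname encoderSpec
#' @export
setClass("EncoderSpec", representation(
  variant = "character",
  channels = "integer",     # output channels per conv block
  strides = "integer",      # spatial stride per conv block
  outputChannels = "integer",
  downsampleFactor = "integer"
))

setValidity("EncoderSpec", function(object) {
  msg <- character()
  if (length(object@channels) != length(object@strides))
    msg <- c(msg, "channels and strides must have equal length")
  if (any(object@channels < 1L)) msg <- c(msg, "channels must be positive")
  if (!all(object@strides %in% c(1L, 2L)))
    msg <- c(msg, "strides must be 1 or 2")
  d <- prod(object@strides)
  if (bitwAnd(d, d - 1L) != 0L)
    msg <- c(msg, "downsample factor must be a power of 2")
  if (length(msg)) msg else TRUE
})

#' @rdname buildMTCSN
#' @export
setClass("MTCSNModel", representation(
  encoder = "EncoderSpec",
  c1 = "integer",
  c2 = "integer",
  nClearness = "integer",
  nSegClasses = "integer",
  fusionEnabled = "logical",
  fusionSites = "integer",
  poolMode = "character",
  activation = "character",
  params = "list",          # named list of weight matrices / vectors
  arch = "list"             # layer plan built by buildMTCSN
))
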