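#' Encoder (backbone) specification
#'
#' Describes the shared convolutional backbone as a stack of 3x3 conv +
#' ReLU blocks.  The `"tiny"` variant (three strided blocks, downsample
#' factor 8) trains on a CPU in minutes and is the test default; the
#' named-depth variants are deeper/wider stacks in the spirit of
#' residual- and densely-connected backbones of those depths, not exact
#' replicas.
#'
#' @param variant One of `"tiny"`, `"resnet-style-50"`,
#'   `"resnet-style-101"`, `"densenet-style-121"`.
#' @return An [EncoderSpec-class].
#' @examples
#' encoderSpec("tiny")
#' @export
encoderSpec <- function(variant = c("tiny", "resnet-style-50",
                                    "resnet-style-101",
                                    "densenet-style-121")) {
  variant <- match.arg(variant)
  plan <- switch(variant,
    "tiny" = list(channels = c(16L, 32L, 64L), strides = c(2L, 2L, 2L)),
    "resnet-style-50" = list(
      channels = c(32L, 32L, 64L, 64L, 128L, 128L, 256L, 256L),
      strides = c(2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L)),
    "resnet-style-101" = list(
      channels = c(32L, 32L, 64L, 64L, 64L, 128L, 128L, 128L, 256L, 256L),
      strides = c(2L, 1L, 2L, 1L, 1L, 2L, 1L, 1L, 2L, 1L)),
    "densenet-style-121" = list(
      channels = c(24L, 48L, 96L, 96L, 192L, 192L),
      strides = c(2L, 2L, 2L, 1L, 2L, 1L)))
  spec <- new("EncoderSpec", variant = variant,
              channels = plan$channels, strides = plan$strides,
              outputChannels = plan$channels[length(plan$channels)],
              downsampleFactor = as.integer(prod(plan$strides)))
  validObject(spec)
  spec
}
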