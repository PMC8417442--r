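#' Configuration of the synthetic capsule-endoscopy generator
#'
#' Builds a [SynthConfig-class] describing how synthetic frames are
#' composed and degraded.  The defaults emulate the statistical structure
#' of a real clearness-annotated capsule-endoscopy corpus: roughly 69 %
#' clear frames, 22 % blurred frames and 9 % frames rendered unusable by
#' occlusion, over a palette of 7 annotated tissue categories plus
#' background.
#'
#' @param imageHeight,imageWidth Frame size in pixels (>= 32).  96 is the
#'   desk-scale default; use 240 to mimic full-scale training input.
#' @param nSamples Number of frames the configuration describes.
#' @param classPalette Ordered names of the 8 mask classes; codes 0..7
#'   follow this order.
#' @param blurKernelLength Length in pixels of the linear motion-blur
#'   kernel applied to degraded frames.
#' @param blurProb Probability that a frame receives global motion blur
#'   (such frames are labeled "blur" unless occlusion dominates).
#' @param bubbleCountRange Integer pair: min/max number of bubble clusters
#'   per frame.
#' @param excretaCoverageRange Pair of fractions bounding the excreta
#'   coverage drawn for occluded frames.
#' @param reflectionProb Probability of specular highlight spots.
#' @param tauInvisible Fraction of occluded (invisible-class) pixels at or
#'   above which a frame is labeled "invisible".
#' @param tauBlur Fraction of blur-tissue pixels at or above which an
#'   unblurred frame is still labeled "blur".
#' @param seed Integer seed; together with the sample index it fully
#'   determines every generated byte.
#' @return A validated [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(nSamples = 4, seed = 1)
#' s <- generateScene(cfg, 1)
#' clearness(s)
#' @seealso [generateScene()], [generateDataset()], [deriveClearness()]
#' @export
synthConfig <- function(imageHeight = 96L,
                        imageWidth = 96L,
                        nSamples = 100L,
                        classPalette = tissuePalette(),
                        blurKernelLength = 9L,
                        blurProb = 0.24,
                        bubbleCountRange = c(0L, 5L),
                        excretaCoverageRange = c(0, 0.7),
                        reflectionProb = 0.5,
                        tauInvisible = 0.4,
                        tauBlur = 0.25,
                        seed = 1L) {
  cfg <- new("SynthConfig",
             imageHeight = as.integer(imageHeight),
             imageWidth = as.integer(imageWidth),
             nSamples = as.integer(nSamples),
             classPalette = as.character(classPalette),
             blurKernelLength = as.integer(blurKernelLength),
             blurProb = as.numeric(blurProb),
             bubbleCountRange = as.integer(bubbleCountRange),
             excretaCoverageRange = as.numeric(excretaCoverageRange),
             reflectionProb = as.numeric(reflectionProb),
             tauInvisible = as.numeric(tauInvisible),
             tauBlur = as.numeric(tauBlur),
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Read or write a SynthConfig as YAML
#'
#' @param path File path.
#' @param config A [SynthConfig-class].
#' @return `readSynthConfig` returns a [SynthConfig-class];
#'   `writeSynthConfig` returns `path` invisibly.
#' @export
readSynthConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("imageHeight", "imageWidth", "nSamples", "classPalette",
             "blurKernelLength", "blurProb", "bubbleCountRange",
             "excretaCoverageRange", "reflectionProb", "tauInvisible",
             "tauBlur", "seed")
  bad <- setdiff(names(y), known)
  stopIf(length(bad) > 0, "unknown SynthConfig fields: ",
         paste(bad, collapse = ", "))
  do.call(synthConfig, y)
}

#' @rdname readSynthConfig
#' @export
writeSynthConfig <- function(config, path) {
  stopifnot(is(config, "SynthConfig"))
  fields <- c("imageHeight", "imageWidth", "nSamples", "classPalette",
              "blurKernelLength", "blurProb", "bubbleCountRange",
              "excretaCoverageRange", "reflectionProb", "tauInvisible",
              "tauBlur", "seed")
  y <- lapply(fields, function(f) slot(config, f))
  names(y) <- fields
  yaml::write_yaml(y, path)
  invisible(path)
}
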