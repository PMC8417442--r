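# YAML run configuration: one file describes a whole training run
# (data manifest, model block, loss block, optimiser, schedule).

#' Build or read a run configuration
#'
#' A run configuration is a validated named list with the blocks
#' `manifest` (dataset manifest path), `model` (`encoder`, `c1`, `c2`,
#' `fusion = list(enabled, poolMode, activation, sites)`), `loss`
#' (`lambdaCls`, `lambdaSeg`, `alpha`, `ignoreIndex`), `optimizer`
#' (`name`, `lr`), `batchSize`, `resize` (`c(H, W)`), `maxIterations`,
#' `seed`, `valEvery`, `checkpointPath`, `logPath`.  Defaults follow the
#' full-scale protocol (batch 8, 240x240 input, 30000 iterations); the
#' desk-scale test profile passes 96x96 and a few hundred iterations.
#'
#' @param ... Overrides of the defaults above (nested lists are merged).
#' @return Named list of class `mtcsnRunConfig`.
#' @examples
#' cfg <- runConfig(maxIterations = 50, resize = c(96, 96))
#' cfg$batchSize
#' @export
runConfig <- function(...) {
  defaults <- list(
    manifest = NULL,
    model = list(encoder = "tiny", c1 = 32L, c2 = 16L,
                 fusion = list(enabled = TRUE, poolMode = "GAP",
                               activation = "identity", sites = 1L)),
    loss = list(lambdaCls = 1, lambdaSeg = 1, alpha = 0.1,
                ignoreIndex = 255L),
    optimizer = list(name = "adam", lr = 1e-3),
    batchSize = 8L,
    resize = c(240L, 240L),
    maxIterations = 30000L,
    seed = 1L,
    valEvery = 100L,
    checkpointPath = NULL,
    logPath = NULL)
  cfg <- modifyList(defaults, list(...))
  stopIf(cfg$batchSize < 1, "batchSize must be >= 1")
  stopIf(cfg$maxIterations < 1, "maxIterations must be >= 1")
  d <- encoderSpec(cfg$model$encoder)@downsampleFactor
  stopIf(any(cfg$resize %% d != 0),
         sprintf("resize dims must be divisible by the encoder downsample factor %d", d))
  class(cfg) <- "mtcsnRunConfig"
  cfg
}

#' @rdname runConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

#' Resize a sample to the configured input dimensions
#'
#' Bilinear for the image, nearest-neighbour for the mask (class codes
#' must not be interpolated).
#'
#' @param sample An [ImageSample-class].
#' @param dims Integer pair `(H, W)`.
#' @return Resized [ImageSample-class].
#' @export
resizeSample <- function(sample, dims) {
  d <- dim(imageArray(sample))
  if (identical(d[1:2], as.integer(dims))) return(sample)
  H <- d[1]; W <- d[2]
  uh <- bilinearMatrix(H, dims[1]); uw <- bilinearMatrix(W, dims[2])
  img <- array(0, c(dims[1], dims[2], 3))
  for (ch in 1:3)
    img[, , ch] <- round(clamp255(uh %*% imageArray(sample)[, , ch] %*% t(uw)))
  ri <- pmin(pmax(round((seq_len(dims[1]) - 0.5) * H / dims[1] + 0.5), 1), H)
  ci <- pmin(pmax(round((seq_len(dims[2]) - 0.5) * W / dims[2] + 0.5), 1), W)
  msk <- maskArray(sample)[ri, ci, drop = FALSE]
  new("ImageSample", image = img, mask = msk,
      clearness = clearness(sample), blurApplied = sample@blurApplied,
      sampleId = sampleId(sample), splitTag = splitTag(sample))
}

#' Run a full training from a run configuration
#'
#' Reads the dataset manifest, groups samples by their split tags,
#' resizes to the configured input dimensions and calls [trainMTCSN()].
#'
#' @param cfg A list from [runConfig()] / [readRunConfig()].
#' @return The [trainMTCSN()] result list.
#' @export
runTraining <- function(cfg) {
  stopIf(!inherits(cfg, "mtcsnRunConfig"), "cfg must come from runConfig()")
  stopIf(is.null(cfg$manifest), "run configuration has no dataset manifest")
  samples <- readDataset(cfg$manifest)
  tags <- vapply(samples, splitTag, character(1))
  stopIf(!any(tags == "train"), "manifest has no training split")
  prep <- function(ss) lapply(ss, resizeSample, dims = cfg$resize)
  trainS <- prep(samples[tags == "train"])
  valS <- if (any(tags == "val")) prep(samples[tags == "val"]) else NULL
  model <- buildMTCSN(
    encoder = encoderSpec(cfg$model$encoder),
    c1 = cfg$model$c1, c2 = cfg$model$c2,
    fusionEnabled = isTRUE(cfg$model$fusion$enabled),
    fusionSites = cfg$model$fusion$sites %||% 1L,
    poolMode = cfg$model$fusion$poolMode,
    activation = cfg$model$fusion$activation,
    seed = cfg$seed)
  trainMTCSN(
    trainS, valS, model = model,
    lossCfg = lossConfig(cfg$loss$lambdaCls, cfg$loss$lambdaSeg,
                         cfg$loss$alpha, cfg$loss$ignoreIndex),
    batchSize = cfg$batchSize, maxIterations = cfg$maxIterations,
    lr = cfg$optimizer$lr, seed = cfg$seed, valEvery = cfg$valEvery,
    checkpointPath = cfg$checkpointPath, logPath = cfg$logPath)
}
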