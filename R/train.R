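# Training driver: seeded minibatch Adam on the multi-task objective,
# periodic validation, JSON-lines logging, resumable RDS checkpoints.

#' @noRd
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' @noRd
adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + eps)
  }
  list(params = params, state = state)
}

# stack a list of samples into the batched training tensors
#' @noRd
stackSamples <- function(samples) {
  d <- dim(imageArray(samples[[1]]))
  H <- d[1]; W <- d[2]; N <- length(samples)
  hw <- H * W
  x <- matrix(0, 3, hw * N)
  masks <- integer(hw * N)
  labels <- integer(N)
  for (n in seq_len(N)) {
    s <- samples[[n]]
    stopIf(!identical(dim(imageArray(s))[1:2], c(H, W)),
           "all samples must share dimensions")
    x[, (n - 1) * hw + seq_len(hw)] <- imageToTensor(imageArray(s))
    masks[(n - 1) * hw + seq_len(hw)] <- as.vector(maskArray(s))
    labels[n] <- match(clearness(s), clearnessLevels())
  }
  list(x = x, masks = masks, labels = labels, H = H, W = W, N = N)
}

#' Train the multi-task network
#'
#' Seeded end-to-end minibatch optimisation of the multi-task objective
#' (see [lossConfig()]) with Adam.  Given the same data, configuration
#' and seed, the run is reproducible.
#'
#' @param trainSamples List of [ImageSample-class] for training.
#' @param valSamples Optional validation list; metrics are computed every
#'   `valEvery` iterations and at the end.
#' @param model An [MTCSNModel-class] to continue training, or `NULL` to
#'   build one from `...`-style arguments below.
#' @param lossCfg A [LossConfig-class].
#' @param batchSize Minibatch size (default 8).
#' @param maxIterations Number of minibatch steps.
#' @param lr Adam learning rate.
#' @param seed Seed for weight init (when `model` is `NULL`) and batch
#'   sampling.
#' @param valEvery Validation cadence in iterations.
#' @param logEvery Cadence of loss records in the returned log.
#' @param checkpointPath If non-`NULL`, the final model (with optimiser
#'   state, resumable) is written here as RDS.
#' @param logPath If non-`NULL`, log records are appended as JSON lines.
#' @param resumeFrom Optional checkpoint path to resume from (overrides
#'   `model`).
#' @param fusionEnabled,poolMode,activation,c1,c2,encoder Model options
#'   used when `model` is `NULL`; see [buildMTCSN()].
#' @return List with `model` (trained [MTCSNModel-class]), `log` (list of
#'   per-interval records), `lossHistory` (total loss per iteration), and
#'   `valReport` (final [MetricsReport-class], or `NULL`).
#' @export
trainMTCSN <- function(trainSamples, valSamples = NULL, model = NULL,
                       lossCfg = lossConfig(), batchSize = 8L,
                       maxIterations = 500L, lr = 1e-3, seed = 1L,
                       valEvery = 100L, logEvery = 25L,
                       checkpointPath = NULL, logPath = NULL,
                       resumeFrom = NULL,
                       fusionEnabled = TRUE, poolMode = "GAP",
                       activation = "identity", c1 = 32L, c2 = 16L,
                       encoder = encoderSpec("tiny")) {
  stopIf(length(trainSamples) == 0, "empty training split")
  stopIf(batchSize < 1 || maxIterations < 1,
         "batchSize and maxIterations must be positive")
  validObject(lossCfg)
  optState <- NULL
  startIter <- 0L
  if (!is.null(resumeFrom)) {
    ck <- loadCheckpoint(resumeFrom)
    model <- ck$model
    optState <- ck$optState
    startIter <- ck$iteration
  }
  if (is.null(model))
    model <- buildMTCSN(encoder = encoder, c1 = c1, c2 = c2,
                        fusionEnabled = fusionEnabled, poolMode = poolMode,
                        activation = activation, seed = seed)
  data <- stackSamples(trainSamples)
  hw <- data$H * data$W
  params <- model@params
  if (is.null(optState)) optState <- adamInit(params)
  lossHistory <- numeric(maxIterations)
  log <- list()
  logCon <- if (!is.null(logPath)) file(logPath, open = "a") else NULL
  on.exit(if (!is.null(logCon)) close(logCon), add = TRUE)

  withSeed(deriveSeed(seed, startIter, salt = 17L), {
    for (it in seq_len(maxIterations)) {
      idx <- sample.int(data$N, batchSize, replace = batchSize > data$N)
      cols <- as.vector(vapply(idx, function(n)
        (n - 1L) * hw + seq_len(hw), integer(hw)))
      xb <- data$x[, cols, drop = FALSE]
      mb <- data$masks[cols]
      lb <- data$labels[idx]

      model@params <- params
      fw <- mtcsnForwardBatch(model, xb, data$H, data$W, batchSize,
                              keepCache = TRUE)
      cl <- clsLossGrad(fw$clsLogits, lb)
      sl <- pixelLossGrad(fw$segLogits, mb, lossCfg@ignoreIndex)
      consLoss <- 0
      dSite <- NULL
      if (model@fusionEnabled && length(fw$consistencySites)) {
        cg <- consistencyGrad(fw$consistencySites)
        consLoss <- cg$loss
        if (lossCfg@alpha > 0) {
          w <- lossCfg@lambdaCls * lossCfg@alpha
          dSite <- lapply(cg$grads, function(gr)
            list(before = w * gr$before, after = w * gr$after))
        }
      }
      total <- lossCfg@lambdaCls * (cl$loss + lossCfg@alpha * consLoss) +
        lossCfg@lambdaSeg * sl$loss
      stopIf(!is.finite(total),
             sprintf("training diverged at iteration %d (loss not finite)",
                     startIter + it))
      lossHistory[it] <- total

      grads <- mtcsnBackwardBatch(model, fw$cache,
                                  lossCfg@lambdaCls * cl$grad,
                                  lossCfg@lambdaSeg * sl$grad, dSite)
      upd <- adamStep(params, grads, optState, lr)
      params <- upd$params
      optState <- upd$state

      if (it %% logEvery == 0L || it == 1L || it == maxIterations) {
        rec <- list(iteration = startIter + it,
                    clsCe = cl$loss, consistency = consLoss,
                    segCe = sl$loss, total = total)
        if (model@fusionEnabled)
          rec$fusionGate <- fusionGateReport(params$fusion.M)
        if (!is.null(valSamples) &&
            (it %% valEvery == 0L || it == maxIterations)) {
          model@params <- params
          vr <- evaluateMTCSN(model, valSamples)
          rec$valAccuracy <- vr@accuracy
          rec$valMIoU <- vr@mIoU
        }
        log[[length(log) + 1L]] <- rec
        if (!is.null(logCon))
          writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA),
                     logCon)
      }
    }
  })
  model@params <- params
  valReport <- if (!is.null(valSamples)) evaluateMTCSN(model, valSamples)
  else NULL
  if (!is.null(checkpointPath))
    saveCheckpoint(model, checkpointPath, optState = optState,
                   iteration = startIter + maxIterations)
  list(model = model, log = log, lossHistory = lossHistory,
       valReport = valReport)
}

#' Evaluate a model on a set of samples
#'
#' Forward-only and deterministic: the same model and samples always
#' yield the identical report.
#'
#' @param model An [MTCSNModel-class], or a checkpoint path.
#' @param samples Non-empty list of [ImageSample-class].
#' @param batchSize Frames per forward chunk.
#' @return A [MetricsReport-class] covering both tasks.
#' @export
evaluateMTCSN <- function(model, samples, batchSize = 8L) {
  if (is.character(model)) model <- loadCheckpoint(model)$model
  stopifnot(is(model, "MTCSNModel"))
  stopIf(length(samples) == 0, "empty evaluation split")
  predCls <- integer(length(samples))
  predMasks <- vector("list", length(samples))
  chunks <- split(seq_along(samples),
                  ceiling(seq_along(samples) / batchSize))
  for (ch in chunks) {
    fw <- forwardMTCSN(model, samples[ch])
    predCls[ch] <- fw$clsPred
    predMasks[ch] <- fw$segPred
  }
  trueCls <- vapply(samples, clearness, character(1))
  cm <- classConfusion(predCls, trueCls)
  seg <- segmentationMetrics(predMasks, lapply(samples, maskArray),
                             nClasses = model@nSegClasses)
  metricsReport(cm, seg)
}

#' Save / load a training checkpoint
#'
#' Checkpoints hold every model parameter (including the fusion matrix)
#' plus the optimiser state, so training can resume exactly and a
#' reloaded model evaluates bit-identically.
#'
#' @param model An [MTCSNModel-class].
#' @param path RDS file path.
#' @param optState,iteration Optimiser state and iteration counter.
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint`
#'   a list with `model`, `optState`, `iteration`.
#' @export
saveCheckpoint <- function(model, path, optState = NULL, iteration = 0L) {
  stopifnot(is(model, "MTCSNModel"))
  saveRDS(list(model = model, optState = optState, iteration = iteration,
               package = "mtcsn", version = "1"), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  stopIf(!file.exists(path), "checkpoint not found: ", path)
  ck <- readRDS(path)
  stopIf(!is.list(ck) || !is(ck$model, "MTCSNModel"),
         "not an mtcsn checkpoint: ", path)
  ck
}
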