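#' Confusion matrix for image-level predictions
#'
#' @param pred,true 1-based class indices (or [clearnessLevels()] names).
#' @param nClasses Number of classes (default 3).
#' @return `nClasses x nClasses` integer matrix; rows are true classes,
#'   columns predictions.
#' @export
classConfusion <- function(pred, true, nClasses = 3L) {
  toIdx <- function(x) if (is.character(x))
    match(x, clearnessLevels()) else as.integer(x)
  pred <- toIdx(pred); true <- toIdx(true)
  stopIf(length(pred) != length(true), "pred and true must be paired")
  stopIf(any(is.na(pred)) || any(is.na(true)), "unknown class labels")
  m <- matrix(0L, nClasses, nClasses)
  for (i in seq_along(pred)) m[true[i], pred[i]] <- m[true[i], pred[i]] + 1L
  dimnames(m) <- list(true = clearnessLevels()[seq_len(nClasses)],
                      pred = clearnessLevels()[seq_len(nClasses)])
  m
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is `trace / total`.  For two classes the precision/recall of
#' the positive class (row/column 1) are reported, the conventional
#' binary reading; for three or more classes, per-class one-vs-rest
#' precision and recall are macro-averaged (classes whose denominator is
#' empty are skipped; `average = "weighted"` weights classes by support
#' instead).  `F1 = 2 P R / (P + R)`, 0 when `P + R = 0`.
#'
#' @param confusion Square matrix of non-negative counts, rows = true
#'   classes, columns = predictions.
#' @param average `"macro"` (default for >= 3 classes), `"weighted"`, or
#'   `"binary"` (default, and only meaningful, for 2 classes).
#' @return List with `accuracy`, `precision`, `recall`, `f1`.
#' @examples
#' cm <- matrix(c(2, 1, 0, 0, 1, 0, 0, 0, 1), 3, 3)
#' classificationMetrics(cm)
#' @export
classificationMetrics <- function(confusion, average = NULL) {
  confusion <- as.matrix(confusion)
  stopIf(nrow(confusion) != ncol(confusion),
         "confusion matrix must be square")
  stopIf(any(confusion < 0) || any(confusion != round(confusion)),
         "confusion entries must be non-negative counts")
  total <- sum(confusion)
  stopIf(total == 0, "empty confusion matrix")
  if (is.null(average))
    average <- if (nrow(confusion) == 2L) "binary" else "macro"
  accuracy <- sum(diag(confusion)) / total
  tp <- diag(confusion)
  colTot <- colSums(confusion)   # predicted counts (TP + FP)
  rowTot <- rowSums(confusion)   # true counts (TP + FN)
  if (average == "binary") {
    stopIf(nrow(confusion) != 2L, "binary averaging needs a 2x2 matrix")
    precision <- if (colTot[1] > 0) tp[1] / colTot[1] else NA_real_
    recall <- if (rowTot[1] > 0) tp[1] / rowTot[1] else NA_real_
  } else {
    pc <- ifelse(colTot > 0, tp / colTot, NA_real_)
    rc <- ifelse(rowTot > 0, tp / rowTot, NA_real_)
    if (average == "weighted") {
      w <- rowTot / total
      precision <- sum(w * pc, na.rm = TRUE) / sum(w[!is.na(pc)])
      recall <- sum(w * rc, na.rm = TRUE) / sum(w[!is.na(rc)])
    } else {
      precision <- mean(pc, na.rm = TRUE)
      recall <- mean(rc, na.rm = TRUE)
    }
  }
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) 0
  else 2 * precision * recall / (precision + recall)
  list(accuracy = unname(accuracy), precision = unname(precision),
       recall = unname(recall), f1 = unname(f1))
}

#' Segmentation metrics: per-class IoU, mIoU, mACC
#'
#' For each class present in the union of prediction and truth,
#' `IoU_c = |pred = c AND true = c| / |pred = c OR true = c|`; `mIoU`
#' averages over classes with nonempty union.  Per-class pixel accuracy
#' `acc_c = |pred = c AND true = c| / |true = c|` is averaged over
#' classes with true pixels to give `mACC`.  Pixels equal to
#' `ignoreIndex` in the truth are excluded everywhere.
#'
#' @param predMasks,trueMasks Integer matrices (0-based class codes), or
#'   lists of them with matching shapes.
#' @param nClasses Number of classes (default 8).
#' @param ignoreIndex Reserved truth code to exclude.
#' @return List with `perClassIoU` (length `nClasses`, `NA` for classes
#'   with empty union), `mIoU`, `mACC`, `pixelAccuracy`, and the
#'   `nClasses x nClasses` confusion matrix (rows = true).
#' @examples
#' tr <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
#' pr <- matrix(c(0, 1, 1, 1), 2, 2, byrow = TRUE)
#' segmentationMetrics(pr, tr, nClasses = 2)
#' @export
segmentationMetrics <- function(predMasks, trueMasks, nClasses = 8L,
                                ignoreIndex = 255L) {
  if (!is.list(predMasks)) predMasks <- list(predMasks)
  if (!is.list(trueMasks)) trueMasks <- list(trueMasks)
  stopIf(length(predMasks) != length(trueMasks),
         "prediction and truth lists must be paired")
  conf <- matrix(0, nClasses, nClasses)
  for (i in seq_along(predMasks)) {
    p <- as.vector(predMasks[[i]])
    t <- as.vector(trueMasks[[i]])
    stopIf(length(p) != length(t),
           sprintf("mask pair %d: shapes differ", i))
    keep <- t != ignoreIndex
    p <- p[keep]; t <- t[keep]
    stopIf(any(p < 0 | p >= nClasses | t < 0 | t >= nClasses),
           sprintf("mask pair %d: class codes out of range", i))
    conf <- conf + matrix(tabulate(t * nClasses + p + 1L,
                                   nbins = nClasses * nClasses),
                          nClasses, nClasses, byrow = TRUE)
  }
  tp <- diag(conf)
  trueTot <- rowSums(conf)
  predTot <- colSums(conf)
  union <- trueTot + predTot - tp
  iou <- ifelse(union > 0, tp / union, NA_real_)
  acc <- ifelse(trueTot > 0, tp / trueTot, NA_real_)
  dimnames(conf) <- list(true = tissuePalette()[seq_len(nClasses)],
                         pred = tissuePalette()[seq_len(nClasses)])
  list(perClassIoU = iou,
       mIoU = mean(iou, na.rm = TRUE),
       mACC = mean(acc, na.rm = TRUE),
       pixelAccuracy = sum(tp) / sum(conf),
       segConfusion = conf)
}

#' Assemble a full metrics report
#'
#' @param clsConfusion 3x3 confusion matrix of clearness predictions.
#' @param segResult Output of [segmentationMetrics()].
#' @return A [MetricsReport-class].
#' @export
metricsReport <- function(clsConfusion, segResult) {
  cm <- classificationMetrics(clsConfusion)
  new("MetricsReport",
      clsConfusion = clsConfusion,
      accuracy = cm$accuracy, precision = cm$precision,
      recall = cm$recall, f1 = cm$f1,
      segConfusion = segResult$segConfusion,
      perClassIoU = segResult$perClassIoU,
      mIoU = segResult$mIoU, mACC = segResult$mACC,
      pixelAccuracy = segResult$pixelAccuracy)
}

#' Write a metrics report as JSON (+ confusion matrices as CSV)
#'
#' @param report A [MetricsReport-class].
#' @param path Output JSON path; confusion matrices are written next to
#'   it as `<stem>_cls_confusion.csv` and `<stem>_seg_confusion.csv`.
#' @return `path`, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  stopifnot(is(report, "MetricsReport"))
  out <- list(accuracy = report@accuracy, precision = report@precision,
              recall = report@recall, f1 = report@f1,
              mIoU = report@mIoU, mACC = report@mACC,
              pixelAccuracy = report@pixelAccuracy,
              perClassIoU = report@perClassIoU)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  stem <- sub("\\.json$", "", path)
  write.csv(report@clsConfusion, paste0(stem, "_cls_confusion.csv"))
  write.csv(report@segConfusion, paste0(stem, "_seg_confusion.csv"))
  invisible(path)
}
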