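#' Write a dataset to disk (PNG images, index-PNG masks, CSV manifest)
#'
#' Images are written as 8-bit RGB PNG, masks as single-channel 8-bit
#' index PNG (class codes 0..7, ignore 255), and a CSV manifest records
#' `sample_id, image_path, mask_path, clearness, split` with paths
#' relative to the manifest.  The round trip through
#' [readDataset()] restores every field exactly.
#'
#' @param samples List of [ImageSample-class] objects (may be empty).
#' @param outDir Output directory, created if missing.
#' @return Path of the written manifest, invisibly.
#' @examples
#' ds <- generateDataset(synthConfig(nSamples = 2, seed = 5))
#' man <- writeDataset(ds, file.path(tempdir(), "demo-ds"))
#' length(readDataset(man))
#' @export
writeDataset <- function(samples, outDir) {
  dir.create(file.path(outDir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outDir, "masks"), showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    id <- sampleId(s)
    imgRel <- file.path("images", paste0(id, ".png"))
    mskRel <- file.path("masks", paste0(id, "_mask.png"))
    png::writePNG(imageArray(s) / 255, file.path(outDir, imgRel))
    png::writePNG(maskArray(s) / 255, file.path(outDir, mskRel))
    data.frame(sample_id = id, image_path = imgRel, mask_path = mskRel,
               clearness = clearness(s), split = splitTag(s),
               stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), image_path = character(0),
               mask_path = character(0), clearness = character(0),
               split = character(0))
  manifestPath <- file.path(outDir, "manifest.csv")
  write.csv(manifest, manifestPath, row.names = FALSE)
  invisible(manifestPath)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param manifestPath Path to a `manifest.csv`.
#' @return List of [ImageSample-class] objects in manifest order.
#' @export
readDataset <- function(manifestPath) {
  stopIf(!file.exists(manifestPath), "manifest not found: ", manifestPath)
  manifest <- read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("sample_id", "image_path", "mask_path", "clearness", "split")
  stopIf(!all(need %in% names(manifest)),
         "manifest must have columns ", paste(need, collapse = ", "))
  root <- dirname(manifestPath)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    stopIf(!row$clearness %in% clearnessLevels(),
           sprintf("sample '%s': unknown clearness label '%s'",
                   row$sample_id, row$clearness))
    stopIf(!row$split %in% c("train", "val", "test", "unassigned"),
           sprintf("sample '%s': unknown split tag '%s'",
                   row$sample_id, row$split))
    imgPath <- file.path(root, row$image_path)
    mskPath <- file.path(root, row$mask_path)
    stopIf(!file.exists(imgPath),
           sprintf("sample '%s': missing image file %s", row$sample_id,
                   row$image_path))
    stopIf(!file.exists(mskPath),
           sprintf("sample '%s': missing mask file %s", row$sample_id,
                   row$mask_path))
    img <- round(png::readPNG(imgPath) * 255)
    stopIf(length(dim(img)) != 3L || dim(img)[3] < 3L,
           sprintf("sample '%s': image is not RGB", row$sample_id))
    img <- img[, , 1:3, drop = FALSE]
    msk <- png::readPNG(mskPath)
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    msk <- matrix(as.integer(round(msk * 255)), nrow(msk), ncol(msk))
    s <- new("ImageSample", image = img, mask = msk,
             clearness = row$clearness,
             blurApplied = NA,
             sampleId = row$sample_id, splitTag = row$split)
    validObject(s)
    s
  })
}
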