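test_that("generateScene is byte-deterministic in (seed, index)", {
  cfg <- synthConfig(imageHeight = 48L, imageWidth = 48L, nSamples = 3L,
                     seed = 11L)
  a <- generateScene(cfg, 2)
  b <- generateScene(cfg, 2)
  expect_identical(imageArray(a), imageArray(b))
  expect_identical(maskArray(a), maskArray(b))
  expect_identical(clearness(a), clearness(b))
  c <- generateScene(cfg, 3)
  expect_false(identical(imageArray(a), imageArray(c)))
})

test_that("degradation-free config always yields 'clearness' frames", {
  cfg <- synthConfig(imageHeight = 48L, imageWidth = 48L, nSamples = 10L,
                     blurProb = 0, bubbleCountRange = c(0L, 0L),
                     excretaCoverageRange = c(0, 0), seed = 5L)
  for (i in 1:10)
    expect_identical(clearness(generateScene(cfg, i)), "clearness")
})

test_that("saturating excreta coverage forces the invisible label", {
  cfg <- synthConfig(imageHeight = 48L, imageWidth = 48L, nSamples = 5L,
                     excretaCoverageRange = c(0.9, 0.9),
                     tauInvisible = 0.5, seed = 9L)
  for (i in 1:5) {
    s <- generateScene(cfg, i)
    # re-derive the label from the emitted mask by direct counting
    v <- as.vector(maskArray(s))
    fInv <- mean(v %in% c(5L, 6L))
    expect_gte(fInv, 0.5)
    expect_identical(clearness(s), "invisible")
    expect_identical(deriveClearness(maskArray(s), s@blurApplied,
                                     0.5, cfg@tauBlur), "invisible")
  }
})

test_that("deriveClearness applies the threshold rule", {
  expect_identical(deriveClearness(matrix(1L, 4, 4), FALSE), "clearness")
  expect_identical(deriveClearness(matrix(1L, 4, 4), TRUE), "blur")
  # half the labeled pixels occluded at tau = 0.5
  m <- matrix(c(6L, 6L, 1L, 1L), 2, 2, byrow = TRUE)
  expect_identical(deriveClearness(m, FALSE, tauInvisible = 0.5),
                   "invisible")
  # blur-tissue fraction alone can trigger the blur label
  m2 <- matrix(c(2L, 2L, 1L, 1L), 2, 2)
  expect_identical(deriveClearness(m2, FALSE, tauBlur = 0.25), "blur")
  # ignored pixels are excluded from the denominators
  m3 <- matrix(c(6L, 255L, 255L, 255L), 2, 2)
  expect_identical(deriveClearness(m3, FALSE, tauInvisible = 0.9),
                   "invisible")
  expect_error(deriveClearness(matrix(255L, 2, 2), FALSE), "ignore")
  expect_error(deriveClearness(matrix(9L, 2, 2), FALSE), "invalid")
})

test_that("stored labels are consistent with the clearness rule and all
           classes and labels occur across 200 default frames", {
  ds <- generateDataset(synthConfig(nSamples = 200L, seed = 3L))
  seen <- integer(0)
  labels <- character(0)
  for (s in ds) {
    expect_identical(clearness(s),
                     deriveClearness(maskArray(s), s@blurApplied))
    seen <- union(seen, unique(as.vector(maskArray(s))))
    labels <- union(labels, clearness(s))
  }
  expect_setequal(seen, 0:7)
  expect_setequal(labels, clearnessLevels())
})

test_that("stratified split follows largest-remainder counts per category", {
  samples <- c(lapply(1:60, function(i) mkLabeledSample("clearness", paste0("c", i))),
               lapply(1:30, function(i) mkLabeledSample("blur", paste0("b", i))),
               lapply(1:10, function(i) mkLabeledSample("invisible", paste0("i", i))))
  sp <- stratifiedSplit(samples, c(0.8, 0.1, 0.1), seed = 4)
  expect_identical(lengths(sp), c(train = 80L, val = 10L, test = 10L))
  countBy <- function(part) table(factor(vapply(part, clearness, character(1)),
                                         levels = clearnessLevels()))
  expect_equal(as.vector(countBy(sp$train)), c(48, 24, 8))
  expect_equal(as.vector(countBy(sp$val)), c(6, 3, 1))
  expect_equal(as.vector(countBy(sp$test)), c(6, 3, 1))
  # partition: union equals input, no id twice
  ids <- unname(unlist(lapply(unlist(sp, recursive = FALSE), sampleId)))
  expect_identical(sort(ids), sort(vapply(samples, sampleId, character(1))))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("stratified split is seed-deterministic and honours edge fractions", {
  samples <- lapply(1:20, function(i)
    mkLabeledSample(clearnessLevels()[(i %% 3) + 1], paste0("s", i)))
  a <- stratifiedSplit(samples, c(0.8, 0.1, 0.1), seed = 2)
  b <- stratifiedSplit(samples, c(0.8, 0.1, 0.1), seed = 2)
  expect_identical(lapply(a$train, sampleId), lapply(b$train, sampleId))
  expect_identical(lapply(a$val, sampleId), lapply(b$val, sampleId))
  all.train <- stratifiedSplit(samples, c(1, 0, 0), seed = 2)
  expect_length(all.train$train, 20)
  expect_length(all.train$val, 0)
  expect_error(stratifiedSplit(samples, c(0.5, 0.2, 0.2), seed = 1), "sum")
})

test_that("dataset write/read round-trips every field", {
  ds <- smallDataset(5, seed = 21)
  ds <- lapply(seq_along(ds), function(i) {
    s <- ds[[i]]
    s@splitTag <- c("train", "train", "val", "test", "unassigned")[i]
    s
  })
  dir <- file.path(tempdir(), "rt-ds")
  man <- writeDataset(ds, dir)
  back <- readDataset(man)
  expect_length(back, 5)
  for (i in seq_along(ds)) {
    expect_identical(imageArray(back[[i]]), imageArray(ds[[i]]) + 0)
    expect_identical(maskArray(back[[i]]), maskArray(ds[[i]]) + 0L)
    expect_identical(clearness(back[[i]]), clearness(ds[[i]]))
    expect_identical(splitTag(back[[i]]), splitTag(ds[[i]]))
    expect_identical(sampleId(back[[i]]), sampleId(ds[[i]]))
  }
})

test_that("dataset IO validates manifests and empty datasets", {
  dir <- file.path(tempdir(), "empty-ds")
  man <- writeDataset(list(), dir)
  expect_true(file.exists(man))
  expect_length(readDataset(man), 0)

  ds <- smallDataset(1, seed = 8)
  dir2 <- file.path(tempdir(), "bad-ds")
  man2 <- writeDataset(ds, dir2)
  m <- read.csv(man2, stringsAsFactors = FALSE)
  m$clearness <- "foggy"
  write.csv(m, man2, row.names = FALSE)
  expect_error(readDataset(man2), "foggy")

  man3 <- writeDataset(ds, file.path(tempdir(), "miss-ds"))
  unlink(file.path(tempdir(), "miss-ds", "masks",
                   paste0(sampleId(ds[[1]]), "_mask.png")))
  expect_error(readDataset(man3), sampleId(ds[[1]]))
})

test_that("synth config round-trips through YAML and rejects bad values", {
  cfg <- synthConfig(imageHeight = 64L, nSamples = 7L, blurProb = 0.5,
                     seed = 123L)
  p <- file.path(tempdir(), "cfg.yaml")
  writeSynthConfig(cfg, p)
  back <- readSynthConfig(p)
  expect_equal(back@imageHeight, 64L)
  expect_equal(back@nSamples, 7L)
  expect_equal(back@blurProb, 0.5)
  expect_equal(back@seed, 123L)
  expect_error(synthConfig(imageHeight = 16L), "32")
  expect_error(synthConfig(blurProb = 1.5), "\\[0, 1\\]")
  expect_error(synthConfig(classPalette = letters[1:5]), "8")
})
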