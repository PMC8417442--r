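Package: mtcsn
Title: Multi-Task Clearness Classification and Tissue Segmentation for
    Capsule Endoscopy Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint image-quality (clearness degree) classification and
    tissue semantic segmentation for wireless capsule endoscopy frames.
    Implements a compact multi-task convolutional network in which the two
    task branches exchange information through a cross fusion module: a
    single shared transformation matrix maps the pooled classification
    feature into the segmentation grid and back, with a consistency
    penalty regularising how far fusion may move the classification
    representation. Ships a seeded synthetic capsule-endoscopy scene
    generator (tissue folds, lumen, lesions, bubbles, excreta occlusion,
    specular reflections, motion blur) with rule-derived clearness labels,
    stratified dataset splitting, PNG/CSV dataset I/O, training and
    evaluation drivers, and the standard classification and segmentation
    metrics (accuracy, precision, recall, F1, mACC, mIoU).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
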