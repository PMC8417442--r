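# mtcsn

Joint image-quality classification and tissue segmentation for wireless
capsule endoscopy frames, in R.

Capsule endoscopy produces hours of small-bowel video in which motion
blur, excreta occlusion, bubbles and reflections leave many frames
unusable, so clinicians reading for Crohn's lesions spend much of their
time searching for clear frames.  This package implements a multi-task
convolutional network that triages frames by learning two readings at
once:

* **Clearness degree (CD)** — a 3-level usability label per frame:
  *clearness* / *blur* / *invisible*;
* **Tissue semantic segmentation (TSS)** — an 8-class per-pixel map
  (background, clear tissue, blur tissue, lesion, hole,
  invisible-by-bubble, invisible-by-excreta, clear bubble) that makes
  the image-level call explicable.

The two branches share an encoder and exchange information through a
**cross fusion module**: one shared matrix `M` (a 1×1 conv kernel, used
transpose-tied in both directions) performs a bidirectional residual
exchange between the pooled classification vector `X_cls ∈ R^{C1×1×1}`
and the segmentation grid `X_seg ∈ R^{C2×H×W}`:

    X̃_cls = X_cls + Pool(σ(M · X_seg))
    X̃_seg = X_seg + σ(Mᵀ · Pad(X_cls))

with `Pad` = spatial replication, `Pool` ∈ {GAP, GMP} and σ an optional
elementwise activation (identity by default).  The objective is the
weighted multi-task sum

    L = λ_cls (Φ_CE(X'_cls, y) + α Σ_i Φ_MSE(X_i, X'_i)) + λ_seg Φ_CE_pix(X'_seg, Y)

whose middle term — the **consistency loss**, MSE between the
classification features before and after fusion (α = 0.1) — regularises
how far fusion may move the classification representation.  Evaluation
follows the field's conventions: accuracy / macro precision / macro
recall / F1 for classification, mIoU and mACC for segmentation.

Annotated clinical corpora of this kind are private, so the package
ships a seeded **synthetic scene generator** emulating their structure
(mucosa wall, lumen hole, tissue folds, lesions, excreta, bubbles,
reflections, linear motion blur) with clearness labels derived from the
mask by a fixed threshold rule — the whole pipeline is testable end to
end without clinical data.  The network, manual backpropagation and Adam
live in the package itself (conv/resize/softmax primitives in C++ via
Rcpp); no deep-learning framework is required.

## Worked example

```r
library(mtcsn)

# 400 synthetic frames at 96x96, stratified 80/10/10 by clearness
cfg <- synthConfig(nSamples = 400L, seed = 7L)
ds  <- generateDataset(cfg)
sp  <- stratifiedSplit(ds, c(0.8, 0.1, 0.1), seed = 7)

# tiny encoder, cross fusion with GAP, 1500 Adam steps at batch 8
fit <- trainMTCSN(sp$train, sp$val, maxIterations = 1500L, seed = 7)
show(fit$valReport)
#> MetricsReport
#>   classification: accuracy 0.9756, precision 0.9881, recall 0.9333, F1 0.9599
#>   segmentation:   mIoU 0.8593, mACC 0.9269, pixel accuracy 0.9522
```

Validation accuracy 0.98 means 40/41 stratified validation frames get
the correct clearness degree; mIoU 0.86 is the mean per-class
intersection-over-union of the 8-class masks at full resolution.  The
training loss falls from 3.13 to about 0.17 (smoothed) over the run.
`fusionGateReport(fit$model@params$fusion.M)` summarises how strongly
the trained network couples the two branches.

The standard cross-fusion ablation — hard parameter sharing vs
fusion-GAP vs fusion-GMP under identical data and seeds — is one call:

```r
ablateMTCSN(sp$train, sp$val, seeds = 1:3, maxIterations = 1500L)
```

A thin command-line front end over the same functions lives at
`inst/cli/mtcsn.R` (`generate`, `train`, `evaluate`, `ablate`
subcommands, YAML configs).

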