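---
title: "Weakly supervised WSI classification with hard tile mining"
author: "wsimine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised WSI classification with hard tile mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsimine)
```

## The problem and the model

A whole-slide image (WSI) is a gigapixel raster pyramid of a stained tissue
section. The clinically interesting signal — here, diffuse-type gastric
adenocarcinoma — occupies a small, irregular fraction of the slide, while
the supervision is usually weak: a single label per slide, sometimes
augmented by free-hand lesion outlines on positive training slides.

`wsimine` implements a tile-based classifier for this setting:

1. **Tissue detection.** The slide thumbnail is converted to grayscale
   (luminance) and thresholded by Otsu's method; pixels darker than the
   threshold are tissue. Tiles are enumerated on a sliding grid over the
   tissue mask.
2. **Tile sampling for training.** Slides with lesion annotations
   contribute only annotation tiles: an annotation smaller than the tile is
   represented by one tile centred on its bounding box; larger annotations
   are covered by an overlapping grid (stride = half the tile) keeping
   tiles that intersect the polygon. Unannotated slides contribute their
   whole tissue grid. Tile labels equal the slide label.
3. **Partial fine-tuning.** Only the affine parameters (scale and offset)
   of every batch-normalisation layer plus the final 1-unit classification
   layer are trainable; everything else is frozen. On the EfficientNetB1
   architecture this mask contains exactly 63,329 parameters
   (2 x 31,024 batch-norm channels + 1,280 head weights + 1 bias), which
   `efficientnet_b1_spec()` + `count_trainable()` reproduce from the
   published compound-scaling recipe.
4. **Two-phase training.**
   *Phase 1 — random balanced sampling:* slides sit in per-label shuffled
   queues; labels alternate; each drawn WSI contributes
   `batch_size / num_labels` tiles, so every batch is exactly balanced, and
   smaller label groups recycle (over-sampling) until every WSI has been
   seen in the epoch. When the validation loss has not improved for 2
   consecutive epochs, training switches — once, irreversibly — to
   *Phase 2 — hard mining:* the current model scans every training slide's
   tissue in a sliding window; on a negative slide the k most-positive
   tiles, on a positive slide the k least-positive tiles, join a subset;
   whenever the subset reaches N tiles it is trained on (batches of 32 in
   arrival order) and cleared. With the defaults k = 16, N = 256 a flush
   happens every 16 slides. Training stops after 10 non-improving
   validation epochs and the snapshot with the lowest validation loss is
   the final model.
5. **Inference.** The model scores every tissue tile; the slide probability
   is the maximum over valid heatmap cells. In the two-stage configuration
   the slide probability is the product `P1(ADC) * P2(diffuse | ADC)`,
   where P1 comes from a pluggable first-stage scorer supplied as a CSV.
6. **Evaluation.** Slide-level ROC AUC (Mann–Whitney form), log loss
   (probabilities clipped at 1e-15), and accuracy/sensitivity/specificity
   at threshold 0.5 (boundary counted positive), each with a percentile
   bootstrap CI over 1000 slide resamples.

Optimisation uses Adam (beta1 = 0.9, beta2 = 0.999), batch size 32, initial
learning rate 0.001 decayed by 0.95 every 2 epochs
(`lr(e) = lr0 * 0.95^(e %/% 2)`), binary cross-entropy loss.

## Physical calibration

Nominal magnification maps to resolution as `mpp = 10 / magnification`:
x20 = 0.5 µm/px, x10 = 1.0 µm/px. A 224 px tile at x20 therefore covers
112 µm per side (`tile_physical_extent(224, 20)`), which fixes the heatmap
cell geometry. Coordinates are 0-based with a top-left origin and half-open
extents; conversions between magnifications truncate toward zero, so a
round trip x20 → x10 → x20 moves a coordinate by less than 2 px.

## The tile scorer

No GPU-scale network is needed (or useful) for the synthetic studies, so
the default scorer is a small convolutional network instantiated from a
structural descriptor (`toy_backbone()`):

* preprocessing: grayscale, area-average resampling to 32 x 32, scaled to
  [0, 1];
* three frozen valid-convolution blocks (3x3 kernels, 16/16/32 channels,
  ReLU, 2x2 average pooling), filters drawn once from a seeded He-normal
  distribution;
* global average pooling to a 32-vector;
* one batch-normalisation layer (trainable affine) and a 1-unit sigmoid
  head — 97 trainable parameters in total.

Two design choices deserve comment.

**The trainable layers sit after global pooling.** With a frozen
convolutional stack, gradients for the BN affine pair and head are exact
and closed-form, and frozen features can be computed once per tile and
cached, which is what makes the end-to-end study fast on one CPU. The
structural machinery (`trainable_mask()`, `count_trainable()`) still
handles batch norm anywhere in a network, as the EfficientNetB1 descriptor
exercises.

**Batch-norm statistics are calibrated once.** The normalisation mean and
standard deviation are fixed from the training tile pool before training
(inference-mode batch norm); only the affine pair trains. This mirrors
partial fine-tuning of a frozen pretrained backbone, keeps every training
step deterministic, and avoids batch-composition artefacts at batch size 32.

**The head has one sigmoid unit trained with binary cross-entropy.** The
printed trainable-parameter count is odd; batch-norm affines come in equal
scale/offset pairs, so the head must contribute an odd count — 1,280
weights + 1 bias. A 2-unit softmax head would contribute 2,562. The
binary task makes the two formulations equivalent up to parametrisation.

## Inference stride

Annotation sampling centres training tiles on lesions, so the scorer is
calibrated on tiles whose lesion content is high. A non-overlapping
inference grid can place every cell boundary across a lesion of comparable
size to the tile, halving or quartering the lesion fraction of the best
cell and diluting its score. The pipeline therefore defaults to an
inference and mining stride of half the tile size, which guarantees some
window re-centres each lesion to within a quarter tile; the training grid
remains non-overlapping. Stride is a configuration field, so fully
disjoint heatmaps (`stride = tile_size`) remain available; heatmap cells
then tile the slide without overlap and each cell covers
`tile_size * mpp` µm.

## The synthetic slide generator

`generate_slide()` emulates the imaging situation of an endoscopic biopsy
scan, not its histology: a near-white background (gray 240 ± 5), darker
tissue blobs (180 ± 15; perturbed circles with low-frequency radial
harmonics), and — on positive slides only — lesion regions carrying a
high-frequency dark speckle (per-pixel density 6%, dot gray 60 ± 20) whose
star-shaped boundary polygons are the ground-truth annotations. Negative
slides can optionally carry sparser "distractor" speckle (density 1.5%)
that mimics borderline mimics of the lesion texture; these are used to
probe hard mining, which exists precisely to suppress such rare
false-positive textures. The pyramid is synthesised by repeated 2x
area-average downsampling, so magnification handling is exercised
everywhere. All randomness flows from a single seed through a fixed integer
hash (`derive_seed()`), making cohorts reproducible and stable under
reordering.

What the generator deliberately does **not** model: stain colour and its
variability, scanner artefacts (blur, pen marks, bubbles), nuclear-scale
morphology, tissue folds. Consequently, a high AUC on synthetic cohorts
demonstrates that the sampling, training, mining, aggregation and
evaluation machinery is correct and that the pipeline can exploit a
texture signal weaker than single-pixel contrast — it does not certify
clinical performance.

## Study conditions and problem sizes

The package's end-to-end benchmark (`run_synthetic_benchmark()`) uses
2048 x 2048 px slides at 0.5 µm/px with 3 tissue blobs; positives carry 2
lesion regions of 200 px diameter. The cohort is 100 training slides
(stratified 80 fit / 20 validation) plus 40 held-out slides, half positive
throughout; the scorer is the toy backbone trained at the reference
hyperparameters (k = 16, N = 256, batch 32, lr 0.001 with the 0.95/2
decay, patience 2/10) at x20 with 224 px tiles and a 112 px inference
stride. Held-out slides are scored by max-tile aggregation and summarised
by ROC AUC. Unit tests use smaller slides (512–1024 px) with
proportionally smaller tiles so the full suite stays fast.

## Numerical conventions and degenerate inputs

* Pixels are 8-bit; every fractional intermediate is quantised by round
  half up (a 2x2 checkerboard of 0/255 averages to 128).
* Downscaling is exact area averaging; upscaling is bilinear with the
  pixel-centre convention.
* Otsu's threshold maximises between-class variance over all 255 split
  points; ties resolve to the lowest level; the returned threshold T means
  "tissue iff gray < T". Single-valued thumbnails cannot be split: they
  produce an all-background (bright) or all-tissue (dark) mask with a
  warning.
* Hard-tile selection breaks probability ties by row-major tile order; if
  a slide has fewer than k tiles, all are taken.
* Patience counters are anchored at a pre-training (epoch-0) validation
  evaluation, so "no improvement for p epochs" means exactly p epochs for
  a flat validation curve. Improvement is strict (<).
* Phase-2 Adam state and the learning-rate schedule restart at the phase
  boundary; the mined subset carries over epoch boundaries and is only
  flushed at N tiles.
* Bootstrap resamples that lose one label category are redrawn, keeping
  exactly `n_bootstrap` replicates; the interval is the percentile
  interval (not BCa), recorded in the report metadata.
* Edge tiles that would cross the slide boundary are discarded, not
  padded; annotation-centred tiles near an edge are clamped in-bounds.

## Known limitations

* The default scorer is deliberately tiny; it cannot represent
  morphology-level distinctions and is not intended for real H&E data.
  Pretrained backbones are represented structurally (for the trainable
  parameter accounting) but no weight loading is provided.
* The first-stage model of the two-stage configuration is a pluggable
  probability source; its training is out of scope.
* Hard mining assumes the slide label applies to at least one tile per
  slide; on positive slides whose lesions are all annotated and small, the
  mined "hardest positive" tiles are genuinely ambiguous, and the
  best-validation-snapshot rule is what keeps this label noise from
  degrading the final model.
* Non-integer resampling factors fall back to bilinear interpolation
  rather than exact fractional area averaging; all shipped configurations
  use integer factors.
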