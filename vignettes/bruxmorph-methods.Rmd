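---
title: "bruxmorph: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bruxmorph: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scientific background

*Brettanomyces bruxellensis*, the principal spoilage yeast of red wine,
is structured into genetic groups defined by microsatellite genotyping.
Group membership correlates with ploidy and with oenologically critical
phenotypes, above all sulfite (SO~2~) tolerance, so a fast way to place an
isolate into its group has practical value in the cellar. Two cheap proxies
for genotyping motivate this package:

* **Cell morphology.** The four groups differ, on average, in cell shape
  and size: GG1 — round, mid-sized cells (mean length/width ratio 1.50,
  mean single-cell area 13.9 µm²); GG2 — elongated small cells (1.72,
  11.5 µm²); GG3 — elongated large cells (1.84, 16.9 µm²); GG4 — round
  large cells (1.50, 18.5 µm²) that, uniquely among the groups, frequently
  form multicellular aggregates (clumps of independent cells or
  non-separated daughters). A convolutional network trained on tiled
  brightfield micrographs can exploit these population-level differences to
  assign a genetic group to a whole image by majority vote over its tiles.
* **RAPD-PCR fingerprints.** Arbitrary-primer PCR profiles are categorical
  strain markers. A primer identifies the genetic groups exactly when its
  profile partition *refines* the group partition: every profile is carried
  by one group only (a group split over several profiles is harmless).

The raw micrographs behind the published analysis are not public, so the
package pairs every analysis step with a ground-truthed synthetic micrograph
generator. All quantitative claims the test suite makes are claims about the
pipeline run on that generator, not about the original images.

## The synthetic micrograph generator

The generator is hierarchical, mirroring the isolate structure of the study
panel (74 isolates in groups of 12/7/50/5):

1. **Group → isolate.** An isolate's mean l/w ratio and mean area are drawn
   from truncated normal hyperdistributions centred on the group means
   (truncation at l/w ≥ 1.05 and area ≥ 2 µm²), with between-isolate SDs of
   0.10 (l/w) and 2.0 µm² (area). This reproduces the isolate-level
   clustering seen when per-isolate averages are plotted, including the
   documented overlap between groups (some GG3 isolates sit among GG1/GG4).
2. **Isolate → cell.** Cell-level l/w and area are lognormal with the
   isolate means and coefficients of variation 0.12 (l/w) and 0.20 (area).
   The lognormal is parametrised by its arithmetic mean, so zero CVs
   reproduce the means exactly — the basis of the exact parameter-recovery
   tests.
3. **Budding and aggregation.** Each cell carries a bud with probability
   0.2 (all groups); buds are tangent to their mother, below 40 % of her
   area, and flagged so measurement can exclude them. Cells join
   multicellular aggregates with probability 0.5 in GG4 and 0.02 elsewhere
   (the other groups "only rarely" form such structures); aggregate sizes
   are uniform on 3–8 cells, members are placed tangent to an earlier
   member. Buds inherit their mother's aggregate membership.
4. **Placement and rendering.** Single cells are placed by rejection
   sampling with no overlap (cap 1000 attempts, then a capacity error), so
   single-cell ground truth is unambiguous; touching occurs only inside
   aggregates. Fields are 1280 × 960 px, 8-bit grayscale: light background
   (gray 200), each cell a dark elliptical rim (−90 gray) with a moderately
   darker interior (−54 gray), then Gaussian blur (σ = 1 px) and additive
   Gaussian noise (SD 3 gray levels).

Two constants are package conventions because the source imaging system's
values are not public:

* **Calibration**: 0.25 µm/px. Absolute pixel sizes in the ground truth
  follow this convention; both pixel and micrometre values are recorded.
* **Cell density**: 280 mother cells per 1280 × 960 field (`simulateCohort`
  default), i.e. roughly 13 single cells per 224 × 224 tile. This emulates
  a well-grown 72-h culture observed at ×40, dense enough that a single
  tile carries a usable sample of the population's morphology. Sparse
  fields (a few cells per tile) make the tile-classification task
  statistically ill-posed regardless of the classifier, because the
  between-group differences are differences of distribution means with
  large within-isolate spread.

The generator does **not** emulate: phase-contrast halos or uneven
illumination, debris, filamentous/pseudohyphal forms, motion or focus blur,
or intensity texture inside cells. A green test therefore establishes that
the pipeline's logic and statistics are correct on geometrically faithful
images; it cannot certify performance on real micrographs.

## Morphometry

Segmentation is deliberately standard: global Otsu threshold (cells are
dark), 8-connected component labeling, rejection of components under
30 px or touching the border (border clipping biases shape). Measurement
follows the "fit ellipse" convention: `l` and `w` are the major/minor axis
lengths of the ellipse with the same second moments as the pixel set (with
the 1/12 pixel-area correction), so `l/w ≥ 1` by construction; area is the
pixel count times the squared calibration. Collinear pixel sets are a
measurement error, judged on the raw moments.

The selection protocol mirrors the study: per isolate, three images and
`n = 100` pseudo-randomly selected single cells, excluding buds and (by
default) aggregate members, stratified as evenly as possible across the
images (33/33/34) under a caller-supplied seed. Because both
segmentation-based and ground-truth-based records exist (`source` column),
parameter-recovery tests can separate generator correctness from segmenter
quality.

## Thumbnails, balancing, split, augmentation

Tiling is a non-overlapping 224 × 224 grid anchored top-left with partial
edge tiles discarded; a 1280 × 960 image yields exactly 20 tiles, so the
150-image GG4 design yields exactly 3000 — the corroboration for this
choice of tiling scheme. Balancing downsamples every class, without
replacement, to the smallest class count. The 75/25 split is stratified per
class so a balanced input yields a balanced validation set. Augmentation
(training tiles only, redrawn every epoch) composes a continuous-uniform
rotation in [−45°, +45°], optional horizontal/vertical mirrors (probability
1/2 each), and x/y translations uniform in [−30, +30] px; exposed pixels
take the tile's median gray value, a robust background estimate. The
rotation range is read as a continuous interval, not just its endpoints, as
is standard augmentation practice.

## The classifier

No deep-learning backend (and no pretrained GoogleNet weights) exists in an
offline R environment, so the default backbone is a compact convolutional
network implemented in RcppArmadillo and trained from scratch:

* 2× average pooling of the 224 × 224 grayscale tile to 112 × 112 with a
  fixed affine gray-level normalisation ((x − 180)/64). The fixed map —
  rather than per-image standardisation — preserves absolute contrast and
  cell-density information, which are class signals here. The 2× (not 4×)
  pooling keeps the ~8 px cell radius resolvable.
* Four 3 × 3 convolution blocks (16, 32, 64, 64 channels), each conv
  followed by batch normalisation and ReLU, with 2 × 2 max pooling after
  the first three blocks; global average pooling; 4-way softmax head.
  Batch normalisation is what lets the network fit within a 10-epoch desk
  profile; without it the same architecture underfits badly.
* Training: Adam (β₁ = 0.9, β₂ = 0.999), base learning rate 2 × 10⁻³ with
  half-cosine decay over the configured epochs, batch 32, cross-entropy.
  Plain SGD with momentum is available (`optimizer = "sgd"`) but does not
  reach criterion within 10 epochs — the package's one deliberate departure
  from a conventional-SGD default, made because the desk-scale profile is
  part of the package's test contract.
* The transfer-learning scheme of the original study — freeze the first 10
  layers, multiply the replaced head's learning rate by 5 — is expressed as
  per-layer learning-rate multipliers (`layerLRMultipliers`), which the
  training loop always honours. Selecting `backbone = "pretrained_backbone"`
  raises a configuration error with a remediation note, since pretrained
  weights can neither ship with the package nor be downloaded offline.
* Image-level assignment: tiles are classified, the modal label wins; ties
  are broken by the highest summed tile probability and flagged. The tie
  rule is a package decision (the source procedure does not state one); the
  flag keeps it auditable.

Determinism: all R-side randomness (isolate draws, placement, noise,
balancing, splits, shuffling, augmentation) flows through caller-supplied
seeds with save/restore of the global RNG state; training is bit-
reproducible given the config seed on a fixed BLAS.

## Evaluation panel

Accuracy = trace/total on the confusion matrix (rows = truth). Per class,
one-vs-rest TP/FP/FN/TN give sensitivity, specificity, precision, FPR and
F1; macro averages are unweighted class means. Macro averaging was chosen
because the validation set is class-balanced by construction, where macro
and weighted averages coincide. Undefined ratios (zero denominators, e.g.
an absent class) are reported as `NA` with a warning and excluded from the
macro means rather than silently zeroed. Two identities hold by
construction and are asserted in the tests: error = 1 − accuracy, and per
class specificity + FPR = 1.

## RAPD concordance fixture

The packaged profile table (`inst/extdata/rapd_profiles_synthetic.csv`,
labelled synthetic) realises the reported profile structure over the real
74-isolate panel: OPA-09 has five profiles, each carried by one group (A9
→ GG1, B9 → GG2, D9 → GG4, GG3 split between C9 and E9), so it refines the
group partition; OPA-02 (C2 shared by GG3+GG4) and OPA-03 (B3 shared by
GG2+GG3) do not. Three conventions were required where the source is
silent: which isolates of GG3 carry each of its two OPA-09 profiles (30/20
in panel order), and which group carries the fourth observed profile of
OPA-02 and OPA-03 (a GG3 subset, the only group large enough to split
without contradicting the reported sharing). Band sizes are not modelled;
profiles are categorical labels.

## Numerical and degenerate-input choices

* Otsu's threshold is computed on the 256-bin histogram; uniform images
  segment to zero components (not an error).
* `sampleCells(n = 0)` returns an empty, correctly-typed table; empty
  renders return a pure background field.
* Truncated-normal draws use rejection sampling (the truncation points are
  far tails at all defaults); a guard aborts after 10⁴ rounds.
* Placement failures (field too crowded) name the cell count and field
  size.
* Vote ties are flagged, never silent.
* The 1/12 moment correction makes the measured l/w of thin rasterized
  ellipses finite and stabilises small components.

## Known limitations

* Synthetic realism is geometric, not photometric; real-image performance
  claims are out of scope by design.
* The desk-scale criterion (2 isolates/group) makes the learning task
  partly one of isolate recognition; with the spec'd between-isolate SDs,
  adverse isolate draws can make two groups nearly coincide in morphology.
  The shipped seeds are fixed, not searched.
* Batch-norm running statistics make validation accuracy during early
  epochs a lagging estimate; the final epoch's model is the one evaluated.
* The segmentation path measures merged mother+bud or touching aggregate
  outlines as single components; measurement-grade statistics should use
  the ground-truth path or the single-cell exclusion rules, as the study
  itself did by excluding buds.
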