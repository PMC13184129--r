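---
title: "Methods: semi-automatic inferior alveolar nerve segmentation on MRN slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automatic inferior alveolar nerve segmentation on MRN slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scientific problem

Magnetic resonance neurography (MRN) visualizes the inferior alveolar nerve
(IAN) as a small bright structure inside the mandibular canal on coronal
slices. Tracing the nerve slice-by-slice by hand is slow and
observer-dependent, yet a per-slice delineation is exactly what presurgical
planning (third-molar extraction, implantology) needs. `ianseg` implements a
semi-automatic pipeline: the human supplies a cropped, landmark-centred
coronal stack per nerve; the package handles everything after that —
normalization, geometric canonicalization, supervised training of a
segmentation network, and statistically careful evaluation.

The task is extreme in two ways that drive every design choice below:

* **Class imbalance.** The nerve cross-section occupies well under 1% of the
  pixels of a slice. An unweighted pixel loss lets a network win by
  predicting "all background".
* **Tiny, low-contrast target.** The nerve is a few pixels across; the
  decisive information is multi-scale context (where is the canal? where was
  the nerve on the neighbouring slice?) rather than local texture.

## The phantom model

Real MRN data cannot ship with a package, so `generate_cohort()` synthesizes
a cohort with the *statistical structure the method assumes*, and every
downstream stage is tested against it.

Each patient gets a left and a right nerve series. A series is an ordered
stack of grayscale slices and binary masks in which:

* the nerve is a small filled ellipse (radius range 1–3 px by default) whose
  centre follows a smooth path through the stack (per-slice displacement
  bounded by `path_smoothness`), standing in for the curved canal course;
* the background is smooth low-frequency tissue texture plus a dark
  "cortical" ring around the nerve path, mimicking the canal wall;
* the nerve intensity is `nerve_contrast` (default 2.5) times the local
  background, clipped below 1 — chosen so that, before noise, the brightest
  pixel of a slice always lies inside the mask. This gives the tests a
  ground-truth anchor that holds by construction;
* the foreground fraction is forced ≤ 1% of pixels per slice (radii are
  shrunk if a draw violates it), reproducing the imbalance regime;
* with probability `artifact_prob` a slice receives a low-intensity void
  patch and/or a streak that may overlap the nerve, standing in for flow and
  susceptibility artifacts;
* left-side series are stored mirrored, so the orientation rule in
  preprocessing is actually exercised;
* everything is deterministic given `seed`.

What the phantom deliberately does **not** emulate: partial-volume fading of
the nerve, bifurcations and anatomical variants, coil-dependent intensity
bias fields, motion ghosting, or any pathology. Conclusions about *clinical*
accuracy cannot be drawn from phantom scores; the phantom exists so that the
machinery (shapes, gradients, splits, statistics) is verifiable end to end.

## Preprocessing

`preprocess_slice()` applies, in order:

1. **Side canonicalization.** Left-side slices and masks are flipped
   horizontally so the network always sees one anatomical orientation and
   the effective training set doubles.
2. **Min–max scaling to 8 bit.** Each slice is mapped to 0–255 with
   round-half-up; a constant slice maps to zeros with a warning rather than
   dividing by zero.
3. **Aspect-preserving fit-resize.** The slice is scaled by
   `target/max(H, W)` using separable Lanczos-3 resampling; output dims are
   round-half-up. Masks are resampled **nearest-neighbour** and re-binarized
   at 0.5: interpolating a binary mask would manufacture gray "half-nerve"
   pixels that are neither foreground nor background, whereas
   nearest-neighbour keeps the label set exact at the cost of ±1-pixel
   boundary jitter — the right trade for ground truth.
4. **Centered zero-padding** to `target × target`, with the smaller margin
   on the top/left when the remainder is odd.

Lanczos-3 is implemented in-package as a separable linear operator with
kernel widening by the inverse scale on downscaling (anti-aliasing) and
per-row renormalization; no installed imaging package provides a Lanczos
filter.

## Network

`build_model()` assembles a U-shaped encoder–decoder operating on
`(H, W, C, N)` arrays:

* **Encoder.** A 3×3 conv-BN-ReLU stem, then four stages. Each stage is a
  *split-attention residual block*: `radix` parallel 3×3 conv-BN-ReLU
  branches are summed, globally average-pooled, pushed through a two-layer
  bottleneck MLP, and turned into per-channel softmax weights across the
  branches; the weighted sum plus an identity shortcut (1×1 conv-BN when
  channels change) feeds a ReLU. After each stage a 2×2 max-pool runs with
  **retained argmax indices**.
* **Bottleneck (MSPA).** Two context modules side by side: MSA applies
  parallel convolutions with kernel sizes {1, 3, 5, 7}; MPA applies adaptive
  average pooling to {1, 2, 3} grids followed by 1×1 convs and bilinear
  upsampling back to the bottleneck geometry. Their outputs are concatenated
  and fused by a 1×1 conv-BN-ReLU. Concatenation-plus-1×1 fusion was chosen
  over summation because the two context types (receptive-field vs global
  pooling) are not commensurate feature spaces; the 1×1 conv learns the mix.
* **Decoder.** Per stage, deepest first: **max-unpooling** with the encoder's
  stored indices (placing activations back where the maxima came from, which
  preserves thin-structure localization better than learned upsampling),
  concatenation with the pre-pool skip tensor, and a 3×3 conv-BN-ReLU.
* **Head.** A 1×1 convolution and a sigmoid produce a per-pixel nerve
  probability. The head bias is initialized to `qlogis(0.01)` so the initial
  output matches the ≤1% foreground prior; without this, early training
  spends its budget learning "mostly background".

There is no deep-learning framework in this stack, so the package carries
its own reverse-mode automatic differentiation over dense arrays, with the
convolutions as compiled im2col+GEMM kernels. Every operator's gradient is
checked against central finite differences in the test suite.

## Loss

`focal_tversky_loss()` implements, per slice,

$$\mathrm{TI} = \frac{\sum p g + \epsilon}{\sum p g + \alpha \sum p(1-g) + \beta \sum (1-p) g + \epsilon}, \qquad L = \operatorname{mean}\big((1-\mathrm{TI})^\gamma\big)$$

with defaults α = 0.7, β = 0.3, γ = 2. α > β penalizes false positives
more than false negatives in the TI denominator, which for a rare
foreground counteracts the optimizer's temptation to under-segment; γ = 2
focuses gradient on hard slices (low TI). Whether 0.7/0.3 is optimal for a
given dataset is an open empirical question; the defaults are exposed in
`loss_config()` and α + β = 1 is enforced only as a default convention, not
a mathematical necessity. The backward pass uses the analytic derivative of
TI rather than graph decomposition, for speed and numerical robustness.

## Training and splitting

`make_split()` partitions **patients** (never single nerves or slices) into
train/val/test at 70/15/15 with round-half-up on val/test and the remainder
to train — 29 patients give 21/4/4, 20 give 14/3/3. Both sides of a patient
always travel together, so no near-duplicate anatomy leaks across
partitions. `monte_carlo_splits()` draws `n_repeats` independent such plans
with derived seeds `base_seed + repeat_index`, and the pipeline trains one
model per plan; reporting pools per-slice test metrics across repeats so the
summary reflects split variability, not one lucky draw.

`train_model()` uses AdamW (decoupled weight decay 1e-4), base learning
rate 1e-3 under cosine annealing to zero over the epoch budget (default 50,
batch 32), early stopping on validation mean DSC with patience 25, and
**restores the best-validation weights** (including batch-norm running
statistics) at the end — the returned model is the one that generalized
best, not the one that happened to exist when the budget ran out.

## Evaluation

`seg_metrics()` computes DSC, IoU, precision, and recall from integer
confusion counts; undefined ratios (empty union) are `NA`, and slices with
empty ground truth are excluded from averages with a reported count rather
than silently scored. The identity DSC = 2·IoU/(1+IoU) is used as an
internal consistency oracle.

`classify_failure()` reports the cumulative failure taxonomy: complete
failure (DSC = 0), tracking failure (DSC < 0.2), boundary failure
(DSC < 0.3), as percentages — monotone by construction.

`compare_models()` runs a two-sided Wilcoxon signed-rank test on paired
per-slice metrics: zero differences dropped, mid-rank ties, the **exact**
distribution (generating-function dynamic program over doubled ranks) for
n ≤ 25, otherwise a normal approximation with tie correction and 0.5
continuity correction, and Bonferroni adjustment `min(1, m·p)` over the
comparison family. The exact path is implemented in-package because
`stats::wilcox.test` refuses exact p-values in the presence of ties.

## Numerical and protocol choices worth knowing

* Prediction masks are thresholded at 0.5. This is the probability-calibrated
  default, not a tuned operating point; `predict()` exposes the threshold.
* Aggregates report mean ± sample SD (n−1) and midpoint medians.
* All randomness flows through explicit seeds surfaced in the configs; a
  rerun of `run_pipeline()` with the same config reproduces the phantom
  data and split JSONs bit-exactly.
* Desk-scale problem sizes (4 patients × 8 slices × 64×64, the "small"
  network preset `[8, 16, 32, 64]`) are used in examples and tests so that
  everything runs in seconds-to-minutes on a CPU; the full-scale defaults
  (256×256, channels `[32, 64, 128, 256]`, 50 epochs) remain the
  constructors' documented full-scale settings.

## Worked example

```{r example}
library(ianseg)

cfg <- run_config(
  phantom = phantom_config(n_patients = 4, slices_per_nerve = 8,
                           image_height = 64, image_width = 64, seed = 5),
  preprocess = preprocess_config(target_size = 64),
  net = net_config(preset = "small"),
  train = train_config(epochs = 5, batch_size = 8, patience = 5,
                       n_repeats = 2, seed = 9))
res <- run_pipeline(cfg, tempfile("run"))
res$pooled_summary
res$pooled_failures
```
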