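---
title: "Dimension-information-embedding attention for histology grading: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimension-information-embedding attention for histology grading: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dieagrade)
```

## The problem

Grading invasive lung adenocarcinoma from HE-stained histopathology patches
is a three-class task (low / intermediate / high grade) with small
between-class and large within-class differences: the discriminative signal
lives both in the local growth morphology of individual tumor cells and in
the arrangement of cell clusters across the patch. Channel-attention
operators that summarise each spatial axis with a single average-pooled
strip — coordinate attention (CA) being the canonical example — compress
this signal aggressively and never let descriptors from the *same* spatial
dimension interact.

The dimension-information-embedding attention (DIEA) operator implemented
here addresses both points. This vignette describes the operator, the
surrounding pipeline (stain normalization, patch QC, case-level
cross-validation, metrics, Grad-CAM), the synthetic fixture generator that
makes everything testable without clinical data, and the design decisions
taken where the published description is silent.

## The DIEA operator

Given a feature map $x \in \mathbb{R}^{C \times H \times W}$, four strip
descriptors are pooled per channel $c$:

$$
a^h_c(h) = \tfrac1W \sum_i x_c(h, i), \quad
a^w_c(w) = \tfrac1H \sum_j x_c(j, w), \quad
m^h_c(h) = \max_i x_c(h, i), \quad
m^w_c(w) = \max_j x_c(j, w).
$$

The average strips carry long-range context; the max strips highlight the
strongest local responses along each row and column (elementwise
$m \ge a$, with equality only on constant strips). Each pooling family is
spliced into a length-$(H{+}W)$ descriptor,
$\mathbf a = [\,a^h, (a^w)^T\,]$ and $\mathbf m = [\,m^h, (m^w)^T\,]$, and
both are concatenated into one length-$2(H{+}W)$ sequence that passes
through a squeeze-style bottleneck:

$$
\mathbf h = \delta\!\left(\mathrm{BN}\!\left(F_1([\mathbf a, \mathbf m])\right)\right)
\in \mathbb{R}^{C/r \times 2(H+W)},
$$

where $F_1$ is a 1×1 convolution reducing $C$ to $C/r$ channels and
$\delta$ is hard-swish. The two halves are re-expanded by 1×1 convolutions
$F_2, F_3$ (each followed by BN) into two *directional embeddings*
$h^a \in \mathbb{R}^{C \times (H+W) \times 1}$ and
$h^m \in \mathbb{R}^{C \times 1 \times (H+W)}$, whose per-channel outer
product

$$
h^{am}_c = h^a_c \, h^m_c \in \mathbb{R}^{(H+W) \times (H+W)}
$$

is the embedding map: each channel slice has rank one, and its four
quadrants realise the four average/max interactions
$a^h (m^h)^T$, $a^h m^w$, $(a^w)^T (m^h)^T$, $(a^w)^T m^w$ — i.e. both the
cross-dimension interactions CA provides *and* the same-dimension
(row-row, column-column) interactions it lacks. A 3×3, stride-2,
padding-1 convolution $F_\downarrow$ maps the $(H{+}W)^2$ map back to
$H \times W$ (exact when $H = W$), and the sigmoid of the result gates the
input:

$$
g = \sigma(F_\downarrow(h^{am})), \qquad y = x \odot g .
$$

Because $g \in (0,1)^{C\times H\times W}$, the operator preserves shape and
sign and can only attenuate, never amplify. `diea_forward()` implements the
full composition; `strip_avg_pool()`, `strip_max_pool()`,
`concat_strips()`, `fuse_descriptors()`, `split_and_expand()`,
`outer_embed()` and `gate_and_apply()` expose the stages individually, and
`ca_forward()` provides the CA baseline (whose gate factorises exactly as
$g_c(i,j) = g^h_c(i)\, g^w_c(j)$).

### Tunable parameters and defaults

* **Reduction ratio `r = 32`, `min_mid_channels = 8`.** The bottleneck
  width is $\max(8, \lfloor C/r \rfloor)$. The published description
  borrows the squeeze operation of the SE block and builds on CA, whose
  reference implementation uses exactly this convention; the value is
  configurable in `diea_config()`.
* **Pool mode.** `AP_MP` is the operator proper; `AP_AP` and `MP_MP`
  replace both branches with average resp. max pooling and exist to
  reproduce the pooling ablations. On constant inputs all three coincide
  (average and max of a constant strip agree), a useful sanity check.
* **$F_\downarrow$ grouping: depthwise by default.** Only kernel, stride
  and padding of $F_\downarrow$ are published. A full $C \to C$ 3×3
  convolution at $C = 512$ alone costs ~2.4 M parameters, an order of
  magnitude more than the published whole-operator overhead (~0.08 M), and
  would break the "equal computational expense" framing; depthwise grouping
  is the only natural choice consistent with it. `full` and integer
  groupings remain selectable.
* **Placement: one block after the final feature stage.** Insertion sites
  are likewise unpublished. A single placement at the last stage (C = 512
  for ResNet-34, C = 320 for MobileNetV2/EfficientNet-B0) keeps the
  parameter overhead at 0.1–0.6% and the MACs overhead below 0.1% for all
  three backbones, consistent with a published CA overhead of +0.02 M.
  `every_stage` and `per_block` are available for budget exploration.
* **Non-square inputs.** The stride-2 recovery convolution returns an
  $H \times W$ gate only when $H = W$. Default behaviour is an explicit
  error (`gate_resize = "require_square"`); `"bilinear"` resizes the gate
  instead. The published pipeline only ever uses 256×256 inputs.
* **BN semantics.** Batch statistics in training, running statistics
  (momentum 0.1, eps 1e-5) at inference; 1×1 convolutions carry no bias
  (BN follows), $F_\downarrow$ does. Kaiming-uniform initialisation.

All gradients (through pooling argmaxes, BN batch statistics, the outer
product and the strided depthwise convolution) are derived by hand and
verified against central finite differences in the test suite.

## Budget accounting

`count_params()` counts trainable weights (BN affine terms included).
`count_macs()` defaults to a convention calibrated against the published
backbone figures at 256×256: convolution and linear multiply-accumulates
(one MAC = one FLOP), plus four ops per element for affine batch
normalisation and the summation/division ops of average pooling, with max
pooling, activations and biases free. Under this convention the three
backbones reproduce the printed 4.8042 / 0.4261 / 0.5404 G within 0.02%.
A stricter `conv_only` convention is available; it matches ResNet-34
within 0.5% but undercounts the two lightweight backbones by 7–8%,
because elementwise ops are a non-trivial fraction of their budgets.
The ResNet-34 parameter count is asserted only as a band (the canonical
3-class count is 21.286 M; the printed 21.32 M is not derivable from the
text and likely reflects the authors' tool or head configuration).

## Stain normalization

Work happens in optical density, $OD = -\log_{10}(I/255)$, where
Beer–Lambert makes pixel OD vectors nonnegative combinations of the
hematoxylin and eosin color vectors. `estimate_stain_basis()` runs a
2-atom sparse NMF on tissue pixels (OD norm > 0.15; at least 1000
required; 2000 subsampled): multiplicative updates with an L1 penalty
(λ = 0.1) on concentrations, initialised from the Ruifrok–Johnston H&E
reference, followed by a short unpenalised polish — the L1 term biases
concentrations downward and tilts the dictionary to compensate, and the
polish removes that tilt (recovery of a known basis improves from cosine
~0.989 to >0.999 on synthetic tissue). Columns are unit-normalised and
ordered hematoxylin-first (larger red-OD component). Nearly collinear or
unused second atoms are flagged `degenerate` with a warning rather than
returned silently.

`normalize_stain()` refits per-pixel concentrations under the source basis
(exact two-variable NNLS, vectorised over pixels), rescales each stain so
its 99th-percentile concentration matches the target image's, and
recomposes under the target basis. The 99th-percentile anchors therefore
travel with the basis object. Background pixels have near-zero
concentration and survive unchanged; normalising an image to its own basis
is identity up to ±2 intensity levels.

## Patch extraction, QC and folds

Three 256×256 crops are taken per normalized image at uniformly random
offsets (seeded, reproducible). A pixel is *blank* iff all three channels
are ≥ 220; a patch is removed iff its blank fraction strictly exceeds 75%
("more than 75%" ⇒ strict inequality at the boundary, so exactly 75%
passes). Folds are assigned at the *case* level — shuffled within grade,
dealt round-robin into k = 5 folds — so per-grade fold sizes differ by at
most one and every patch inherits its case's fold; the trainer verifies
the resulting split is leakage-free and aborts otherwise. The target basis
for normalization defaults to the first image whose basis estimation
succeeds, configurable by path.

## Synthetic fixtures

`synth_image()` emulates an HE patch: Gaussian-profile nuclei (the
hematoxylin concentration map) at a grade-dependent density — 40 / 90 /
180 nuclei per 256² of tissue for low / intermediate / high, radii 4 /
3.5 / 3 px — over a smooth random eosin background, with eosin suppressed
under dense nuclei (basophilic nuclei displace eosinophilic cytoplasm,
which also gives the stain-separation problem near-pure pixels of each
stain), an optional white strip of configurable area fraction, and
Beer–Lambert composition through a configurable stain matrix. Densities
were chosen once so that adjacent grades separate at p < 0.01 (Welch) with
30 patches per grade while still overlapping at the single-patch level;
default images are 384×384 so random 256-crops have genuine offset
freedom.

What passing tests on these fixtures shows: the pipeline's plumbing,
determinism, leakage freedom, stain-recovery loop and the trainability of
the models. What it does not show: performance on real tissue — the
generator has no growth-pattern morphology, no scanner or compression
artifacts, no stain variation within an image, and its grade signal
(nuclear density) is far simpler than histological grade.

## Training and evaluation

The published recipe is the default `train_config()`: AdamW (decoupled
weight decay 1e-2, weights only — biases and BN affine terms undecayed),
lr 1e-4, batch 16, 256×256 inputs, 200 epochs, cross-entropy, a linear
warmup across the first epoch and cosine annealing
$\eta_e = \tfrac{\eta}{2}(1 + \cos \pi \tfrac{e-1}{E-1})$ that reaches
exactly zero at the final epoch. Model selection is final-epoch weights
(no early stopping).

The desk-scale experiment (`smoke_config()`) trains `tiny_cnn()` — two
conv/ReLU/max-pool stages, a DIEA block on the 16×8×8 feature map, global
average pooling, linear head — on patches block-averaged to 32×32,
standardised per channel with training-fold statistics, for 10 epochs at
lr 1e-2. Problem sizes (5 cases per grade, 2 images per case, 3 crops,
5 folds ⇒ 90 patches) keep the full pipeline run under a minute; the run
reaches mean validation accuracy ≈ 0.69–0.84 across seeds against a 1/3
chance level.

`compute_metrics()` derives the nine-metric report from the confusion
matrix: accuracy; per-class precision/recall/F1 with macro (unweighted)
and weighted (support-weighted) averages; Cohen's kappa
$(p_o - p_e)/(1 - p_e)$; the K-category Matthews correlation computed from
the confusion matrix; and AUC as macro one-vs-rest on softmax scores (the
most common convention for a single printed AUC in a multiclass setting —
the weighted variant is also emitted since the published averaging is not
stated). Zero-support classes score 0 with a warning. Cross-validated
results report the mean and sample standard deviation over folds.

## Grad-CAM

`grad_cam()` backpropagates a one-hot class score to a chosen feature
layer (default: the last convolutional or attention layer), weights the
layer's channels by their spatially averaged gradients, rectifies the
weighted sum, upsamples bilinearly to the input resolution and min-max
normalises. An all-zero map (e.g. a zero classification head) stays
all-zero rather than dividing by zero, and normalisation is idempotent.
Which layer and class the published qualitative maps used is not stated;
both are configurable.

## Numerical choices and degenerate inputs

* Max-pooling ties route gradients to the first maximising index.
* BN uses biased variance for normalisation and unbiased variance for the
  running estimate, momentum 0.1.
* The 2-variable NNLS enumerates its three active sets exactly; no
  iterative solver is involved.
* Empty tensors, non-square inputs under `require_square`, mismatched
  channel counts, sub-crop-size images, grades with fewer cases than
  folds, and case ids with conflicting grades all fail fast with specific
  errors.

## Known limitations

* The full 200-epoch, 256×256 recipe on the three real backbones is
  expressed by the configuration objects but is far beyond desk-scale
  compute; backbones are exercised for budgets, shapes and inference only.
* `zoo_forward()` runs single images in inference mode; training the zoo
  backbones end-to-end is out of scope (the trainer covers `tiny_cnn()`).
* Stain estimation assumes two stains; it flags but does not specially
  handle three-stain or unstained inputs.
* The ResNet-34 printed parameter figure cannot be reproduced exactly from
  the published information; see the budget section.
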