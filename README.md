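# dieagrade

Dimension-information-embedding attention (DIEA) and a desk-scale
histopathology-grading pipeline, in pure R.

## What this is for

Grading invasive lung adenocarcinoma from HE-stained patches is a
three-class problem (low / intermediate / high) with small between-class
and large within-class differences. Strip-pooling channel attention such
as coordinate attention (CA) summarises each spatial axis with one
average-pooled descriptor, which over-compresses local evidence and never
lets descriptors of the same spatial dimension interact. DIEA fixes both:
it pools **average and max** strips along both axes,

    a_c^h(h) = mean_i x_c(h, i)        m_c^h(h) = max_i x_c(h, i)
    a_c^w(w) = mean_j x_c(j, w)        m_c^w(w) = max_j x_c(j, w),

fuses the spliced descriptors `[a, m]` through a squeeze bottleneck
(1×1 conv → BN → hard-swish, width `max(8, C/r)`), re-expands them into two
directional embeddings `h^a ∈ R^{C×(H+W)×1}`, `h^m ∈ R^{C×1×(H+W)}`, forms
the rank-one per-channel outer product `h^am = h^a · h^m` — whose four
quadrants carry all four same- and cross-dimension interactions of the
average and max descriptors — and recovers a full-resolution multiplicative
gate with a 3×3 / stride-2 / padding-1 convolution:

    g = sigmoid(F↓(h^am)) ∈ (0,1)^{C×H×W},     y = x ⊙ g.

Around the operator the package implements the complete pipeline a grading
study needs: Vahadane-style sparse-NMF stain normalization in optical
density, seeded random 256×256 cropping, blank-patch QC (> 75% white
removed), case-level stratified 5-fold splitting (leakage-free by
construction and checked at training time), a ResNet-34 / MobileNetV2 /
EfficientNet-B0 budget accountant, an AdamW + warmup + cosine trainer with
hand-derived backpropagation, the nine-metric evaluation suite (ACC, AUC,
MCC, Kappa, macro/weighted F1/precision/recall), Grad-CAM heatmaps, and a
synthetic HE-like fixture generator with grade-dependent nuclear density so
everything runs without clinical data.

Everything is plain R (arrays + BLAS); there is no deep-learning framework
dependency. The attention operator, its gradients, the convolution kernels
and the NMF are implemented in this package.

## Worked example

Budget of ResNet-34 with a DIEA block after the final stage, at the
256×256 convention:

```r
library(dieagrade)
budget_report("resnet34", attention = "diea")
#> $params_millions  21.317987      # bare backbone: 21.286211
#> $macs_giga        4.805036       # bare backbone: 4.804217
#> $input_size       256 256
```

The attention block costs +0.032 M parameters (+0.15%) and +0.0008 G MACs
(+0.017%): attention at essentially equal computational expense. The bare
backbone numbers reproduce the published 4.8042 G (ResNet-34), 0.4261 G /
2.23 M (MobileNetV2) and 0.5404 G / 4.01 M (EfficientNet-B0) figures.

Applying the operator directly to a feature map:

```r
set.seed(1)
x   <- array(rnorm(64 * 16 * 16), c(64, 16, 16))
cfg <- diea_config(channels = 64)        # r = 32, mid width max(8, C/r) = 8
w   <- diea_init(cfg, seed = 1)
out <- diea_forward(x, cfg, w, with_gate = TRUE)
range(out$g)                             # 0.0012 0.9997  -- gate in (0,1)
mean(abs(out$y)) / mean(abs(x))          # 0.5058         -- multiplicative attenuation
```

End-to-end on synthetic fixtures (15 cases, 30 images, 90 patches, 5-fold
case-level CV, tiny CNN + DIEA, 10 epochs — about a minute on one CPU):

```r
mf  <- synth_dataset(synth_spec(n_cases_per_grade = 5, images_per_case = 2,
                                seed = 1), "raw/")
pm  <- preprocess_cases(mf, "patches/", crops = 3, size = 256, seed = 17)
res <- train_one_config(pm, smoke_config())
subset(res$summary, metric %in% c("acc", "auc", "kappa"))
#>   metric  mean     sd
#>      acc 0.689 0.1948
#>      auc 0.860 0.0952
#>    kappa 0.533 0.2923
```

Mean validation accuracy 0.689 against a 1/3 chance level: the pipeline
learns the grade-ordered nuclear density of the fixtures. The same flow is
scriptable from a shell via the bundled CLI
(`inst/exec/dieagrade synth|preprocess|budget|train|eval|explain`).

## Package layout

- `R/attention.R`, `R/attention-grad.R` — the DIEA operator and CA
  baseline, forward and hand-derived backward
- `R/zoo.R` — backbone graphs, parameter/MACs accounting, inference
- `R/stain.R`, `R/patches.R` — stain separation/normalization, crops, QC,
  fold assignment
- `R/synth.R` — synthetic HE-like fixtures
- `R/nn.R`, `R/train.R` — training framework, recipe, metrics
- `R/gradcam.R`, `R/cli.R` — heatmaps and the command-line entry point
- `vignettes/dieagrade-methods.Rmd` — model, assumptions, design decisions
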