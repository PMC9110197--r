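---
title: "Attention-gated parallel U-Nets for multimodal lung-tumor segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-gated parallel U-Nets for multimodal lung-tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Early lung cancer presents as small pulmonary nodules: compact, roughly
round lesions that occupy a tiny fraction of a chest image and show poor
contrast against surrounding tissue on CT. PET imaging of FDG uptake shows
the same lesions as bright metabolic hot spots, but with low spatial
resolution and blur; the fused PET/CT view blends the two. The three
modalities are complementary — CT carries anatomical boundary detail, PET
carries lesion conspicuity — and this package segments the lesion from
co-registered 50×50 triplets (CT, PET, fused) of a region of interest.

## The model

The segmenter is a pair of parallel encoder–decoder networks:

* **UNet_A** has *two* encoders, one for the fused PET/CT image and one for
  PET, with channel schedule 16, 32, 64, 128, 256. At the bottleneck the
  two encoders' features are summed and decoded by a single decoder
  (128, 64, 32, 16) using 2×2 transpose convolutions.
* **UNet_B** is a standard U-Net on CT with channels 32, 64, 128, 256, 512
  and decoder 256, 128, 64, 32.

Every stage is two rounds of (3×3 convolution, batch normalization, ReLU);
downsampling is 2×2 max pooling with floor division, so the spatial sizes
run 50 → 25 → 12 → 6 → 3 and mirror back up (the 12 → 25 upsampling uses an
output-padded transpose convolution).

Three learned gating mechanisms, each producing weights in [0, 1] through a
sigmoid, connect the branches:

* **Two-modal feature-extraction gate.** At each encoder level the fused
  and PET features (C channels each) are concatenated; a gate
  `sigmoid(Conv3x3(ReLU(Conv1x1(cat))))` with 2C channels multiplies the
  concatenation elementwise. (Two gate wirings are plausible
  here; the composite 1×1 + 3×3 form is the default and
  `two_modal_text_variant = TRUE` selects the all-1×1 alternative.)
* **Hybrid attention on the skip connections.** The fused-branch feature
  `F_hybrid` and the CT feature `F_CT` are concatenated and pass through
  channel attention — global average- and max-pooled channel vectors
  through a shared bias-free MLP with hidden width `floor(C/3)`, summed,
  sigmoid → per-channel α, output `x·α + x` — followed by spatial attention
  — channel-wise mean and max maps, 3×3 convolution, sigmoid → spatial gate
  s, output `x + x·s`. Both stages are residual: a zero gate reproduces the
  input exactly, a unit gate doubles it. The attended skip is reduced by
  1×1 convolutions to each decoder's tabulated width.
* **Multiscale feature aggregation (MFA) head.** Each of the four decoder
  scales of the two branches is concatenated, resampled bilinearly to
  50×50, and compressed to 16 channels by a 1×1 convolution; the four maps
  concatenate into F (64 channels). A channel weight
  `α = sigmoid(MLP(avgpool(F)))` and a map weight
  `β = sigmoid(Conv1x1(ReLU(Conv3x3(F·α))))` combine residually as
  `F_MFA = F·α·β + F·α + F`, and a 1×1 convolution maps F_MFA to the class
  logits.

Ablation variants expose each ingredient separately: `unet` (single-encoder
U-Net on CT, channels 64…1024), `meu_net` (three encoders with summed
skips), `pu_net` (parallel U-Nets only; the two subnetwork logit maps are
summed), `sapu_net` / `capu_net` (spatial / channel attention only),
`mfpu_net` (aggregation head only), and the full `apu_net`.

## Design choices where the architecture was underdetermined

Several wiring details of this architecture family are genuinely open and
were fixed once, as package conventions:

* **Skip wiring.** All dual variants use one uniform skip path:
  `concat(F_hybrid, F_CT)` → optional attention → 1×1 reduction to each
  decoder's width. Without the two-modal gate, `F_hybrid` is the
  elementwise sum of the two UNet_A encoders (mirroring the stated
  bottleneck sum). This keeps the reference decoder channel schedules true
  for every variant.
* **Head supervision.** Cross-entropy is applied to every head the variant
  exposes — the aggregation head plus both subnetwork 1×1 heads for
  `apu_net` — with equal weights by default (`loss_weights` configurable).
* **Gate widths.** The two-modal gate is a full per-channel-per-pixel gate
  (2C channels); the MFA α-MLP hidden width is `floor(64/3) = 21`;
  channel-attention MLPs share weights between the average and max
  branches and carry no biases.
* **Attention order.** Channel before spatial, configurable via
  `attention_order`.
* **Dropout** (p = 0.5) at both bottlenecks during training only.
* **Numerics.** Batch normalization uses eps 1e-5 and momentum 0.1 with
  per-channel statistics over (H, W, N); weights are Kaiming-normal
  initialized from R's RNG (seed the session before `build_model()` for
  bit reproducibility); bilinear resampling uses the half-pixel-center
  convention clamped at borders; max pooling and channel-max maps break
  ties toward the first index, keeping backpropagation deterministic.

## The training recipe

`train_config()` defaults follow the reference training schedule: Adam (β = 0.9,
0.999, eps 1e-8) with initial learning rate 0.005, batch size 8, weight
decay 1e-7, 150 epochs, constant learning rate, no validation split; the
state with the best training DSC is restored at the end, after which the
batch-norm running statistics are recalibrated by two dropout-free passes
over the training set (a precise-BN refresh). Without this, bottleneck
dropout biases the statistics that evaluation-mode normalization uses — a
train/eval variance shift that at small scale can collapse predictions to
background even when training overlap is perfect. The engine
underneath is a self-contained reverse-mode automatic-differentiation tape
with compiled im2col/BLAS convolution kernels; every operation is verified
against central finite differences in the test suite.

## Segmentation metrics

For predicted mask P and ground truth G:
DSC = 2|P∩G|/(|P|+|G|); Recall = TP/(TP+FN); VOE = |1 − |P∩G|/|P∪G||;
RVD = ||P|/|G| − 1|. Conventions for degenerate masks are explicit and
warned: both masks empty gives DSC 1 and VOE 0; an empty ground truth
leaves Recall and RVD undefined (NA). Aggregation is the unweighted mean
over samples (not pooled pixels). The metrics are 2-D; "volumetric" names
are kept because they are the field's standard labels for these overlap
errors. Note the definitions are followed literally: RVD is a volume-only
quantity (disjoint masks of equal area score 0), and both VOE and RVD are
reported as absolute values.

## The synthetic phantom generator

Clinical PET/CT data cannot ship with a package, so all executable checks
run on synthetic 50×50 tri-modal phantoms that emulate the *structure* of
lesion ROI crops:

* **Masks**: a single 8-connected lesion with area fraction drawn from
  [0.02, 0.15] (nodules are small relative to even a tight ROI), in three
  shape families — `ellipse` (easy), `blob` (thresholded Gaussian
  metaballs), `lobulated` (chained union of disks) — plus `mixed`.
* **PET**: flat 0.3 background with the lesion at `pet_contrast` (default
  2.5) times background, Gaussian blur σ = 1 px, additive noise σ = 0.03.
  In the noiseless, blur-free limit the lesion/background mean ratio is
  exactly the configured contrast.
* **CT**: a smooth random field (heavily blurred uniform noise rescaled to
  [0.25, 0.55]) plus texture noise, with a weak `ct_contrast` (default 1.3)
  lesion — high anatomical variability, low lesion conspicuity.
* **Fused**: exactly `alpha·PET + (1−alpha)·CT` with α = 0.5. How clinical
  fusion images were produced is not documented anywhere we could follow,
  so the blend is a stand-in, not a claim about scanner software.

Every pixel is a deterministic function of (seed, config). What the
phantoms do **not** emulate: FDG uptake physics (SUV scales, attenuation),
anatomy-correlated lesion placement, scanner-specific noise spectra, and
inter-patient variability. Tests passing on phantoms therefore validate
the implementation — shapes, gradients, convergence, metric arithmetic —
not clinical segmentation accuracy.

## Problem sizes used by the tests and the acceptance script

Architecture contracts are checked at the reference scale (base channels
16/32, which is ~12.3 M parameters). Training-based checks use the same
architecture with the channel budget scaled down (base 4/8, aggregation
width 4 per scale) so they run in minutes on one CPU: memorization of a
single phantom (200 epochs, batch 1), and an ablation over
`pu/sapu/capu/mfpu/apu` on a 64-train/16-test phantom split (8 epochs,
3 seeds each). At this scale all variants converge to high DSC on the
easy phantom task, so the ablation is read as a direction check — the
attention variants should not fall behind the parallel baseline, and the
full network should stay within tolerance of it — not as a reproduction of
clinical-scale margins, which would require hundreds of real training
images at full width.

## Known limitations

* CPU only, double precision, no multi-threading beyond BLAS.
* The ROI Hough transform is a plain accumulator vote over integer radii;
  it expects one dominant circular structure.
* `enhance_contrast(method = "clahe_like")` is a clipped percentile
  stretch, a deliberately simple stand-in for exposure-fusion enhancement
  (out of scope); `gamma` and `none` are provided alongside.
* Checkpoints store plain R serializations with a YAML sidecar; they are
  not interchangeable with other frameworks.
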