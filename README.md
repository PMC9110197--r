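# apunet

Segmentation of lung lesions in co-registered PET / CT / fused PET-CT
image pairs ("triplets") with **attention-gated parallel U-Nets**, for
researchers in medical image analysis who want a fully inspectable,
dependency-light R implementation of this family of multimodal
segmentation networks.

## The model

Two encoder–decoder networks run in parallel over a 50×50 region of
interest:

* **UNet_A** — two encoders (fused PET/CT and PET, channels
  16–32–64–128–256) fused by summation at the bottleneck, one decoder
  (128–64–32–16);
* **UNet_B** — a CT U-Net (32–64–128–256–512 / 256–128–64–32).

Three sigmoid gating mechanisms connect them: a *two-modal
feature-extraction gate* `cat(x1,x2) ⊙ σ(Conv3×3(ReLU(Conv1×1(cat))))` on
the UNet_A encoder pairs; *hybrid attention* (channel attention
`x·α + x` with `α = σ(MLP(avg) + MLP(max))`, then spatial attention
`x + x·s` with `s = σ(Conv3×3[mean‖max]))` on the concatenated skip
features of both branches; and a *multiscale feature-aggregation head*
that resamples all four decoder scales of both branches to full
resolution, compresses each to 16 channels (F, 64 channels), and combines
`F_MFA = F·α·β + F·α + F`. Ablation variants (`unet`, `meu_net`, `pu_net`,
`sapu_net`, `capu_net`, `mfpu_net`, `apu_net`) isolate each ingredient.

Segmentation quality is scored by DSC = 2|P∩G|/(|P|+|G|),
Recall = TP/(TP+FN), VOE = |1−|P∩G|/|P∪G|| and RVD = ||P|/|G|−1|.

Because clinical PET/CT cannot be redistributed, the package ships a
synthetic tri-modal phantom generator (bright compact lesions; high-contrast
blurred noisy PET; textured low-contrast CT; exact convex-blend fusion)
that makes every component executable and testable end to end. The neural
network itself runs on a self-contained reverse-mode autodiff engine with
compiled (RcppArmadillo) convolution kernels — no Python or GPU runtime is
required.

## Worked example

Generate phantoms, train a reduced-width full network, and evaluate:

```r
library(apunet)

cfg <- phantom_config(seed = 11)          # 50x50 tri-modal phantoms
set.seed(11)
train <- lapply(1:64, function(i) generate_phantom(cfg, sample_id = sprintf("tr%02d", i)))
test  <- lapply(1:16, function(i) generate_phantom(cfg, sample_id = sprintf("te%02d", i)))

set.seed(101)
model <- build_model(model_spec("apu_net", base_channels_a = 4,
                                base_channels_b = 8, mfa_per_scale_ch = 4))
fit <- train_model(model, train, train_config(epochs = 12, seed = 101),
                   verbose = TRUE)
#> epoch   1  loss 1.2512  train DSC 0.6695
#> ...
#> epoch  12  loss 0.0428  train DSC 0.9790

evaluate_model(fit$model, test)
#> Segmentation metrics over 16 samples
#>   mean DSC 0.9832 | recall 0.9841 | VOE 0.0329 | RVD 0.0116
```

The final lines say the scaled-down network segments held-out phantoms
with 98.3% Dice overlap, missing 1.6% of lesion pixels (recall), with a
3.3% Jaccard-type overlap error and a 1.2% volume error. `plot_triplet(test[[1]],
predict_mask(fit$model, test[[1]]))` displays the four channels and the
prediction; `tidy(fit)` / `glance(fit)` and `autoplot()` expose the
training log and metric reports as tibbles/ggplots.

At the reference scale, `build_model(model_spec("apu_net"))` builds the
full 12.3 M-parameter network; `forward_trace()` prints every block's
channel/size schedule.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/apunet.R generate --n-train 64 --n-test 16 --seed 11 --out data/
Rscript inst/cli/apunet.R train    --data data/ --model apu_net --out run/
Rscript inst/cli/apunet.R evaluate --pred preds/ --gt masks/ --out report.csv
```

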