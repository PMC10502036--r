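# sranet

Dual-attention colon-polyp segmentation in R, exercisable entirely on
synthetic data.

## The problem and the model

Colorectal polyps in endoscopy images are hard to segment automatically: the
boundary between a polyp and the surrounding mucosa is often low-contrast and
ambiguous, backgrounds are textured and noisy, and specular glare corrupts
intensities. `sranet` implements an SRaNet-style segmentation network that
attacks this with two complementary attention operators applied over a
feature pyramid (backbone taps **F₃, F₄, F₅** at strides 8/16/32):

- **Shallow attention (SAM)** multiplies a shallow feature map by the ReLU of
  the upsampled deeper map(s),
  `Mᵏˢᴬ = r(up(Fₖ₊₁))`, `Fₖˢᴬ = Mᵏˢᴬ ⊗ Fₖ`
  (and `Fₖˢᴬ = Mᵏˢᴬ ⊗ Mᵏ⁺¹ˢᴬ ⊗ Fₖ` when a second, deeper context map is
  available), suppressing background while keeping shallow spatial detail.
- **Reverse attention (RAM)** builds a normalized foreground map
  `Mᵏᴿᴬ = σ(up(Fₖ₊₁))`, reverses it to `1 − Mᵏᴿᴬ`, and multiplies it into the
  features, steering capacity toward background and boundary pixels.
- A **softmax gate (SG)** fuses the two branches per channel: squeeze-style
  descriptors `c = Z·r(W·GAP(F))` for each branch are stacked and passed
  through a two-way softmax, giving convex weights `v_SA + v_RA = 1` that mix
  `Fˢᴬ` and `Fᴿᴬ` channel by channel.

Training minimizes `L_total = L_DICE + L_BCE` (smooth Dice plus binary
cross-entropy). Evaluation reports mDice, mIoU, weighted Fβ, S-measure,
E-measure (max over 255 thresholds) and MAE.

Because no deep-learning framework is assumed, the package ships its own
compact reverse-mode differentiation engine (conv/BN/pooling/bilinear
upsampling/FC on BLAS matmuls). A `tiny_test` backbone (~0.1 M parameters)
trains on a CPU in minutes; the full `res2net50`/`resnet50` architectures are
buildable and are used for exact static complexity accounting
(MACs/parameters).

## Worked example

```r
library(sranet)

# synthetic endoscopy-like data: blobs with soft boundaries on textured mucosa
ds <- generate_dataset(synth_spec(seed = 7), 200)

model <- sranet(sranet_config(backbone = "tiny_test", channels = 32,
                              input_size = c(64, 64), seed = 3))
res <- train(model, ds$samples[1:180], train_config(preset = "tiny", seed = 3))
tail(res$log[, c("epoch", "loss_total", "val_mdice")], 3)
#>    epoch loss_total val_mdice
#> 8      7  0.2109403 0.8386737
#> 9      8  0.1813597 0.8355452
#> 10     9  0.1753915 0.8834716

evaluate(res$model, ds$samples[181:200])
#> mDice 0.8841  mIoU 0.7985  wFb 0.8263  S 0.9079  E 0.9806  MAE 0.0441
```

The epoch-mean training loss falls from 0.88 to 0.18 over ten epochs and the
held-out mean Dice reaches ~0.88 — far above an untrained model (~0.26) or
the best constant predictor (~0.25) on the same masks. Per-level attention
maps and gate vectors are available through
`predict_mask(model, img, diagnostics = TRUE)`.

Static complexity of the full-scale configuration:

```r
count_complexity(sranet_config(backbone = "res2net50", channels = 64,
                               input_size = c(352, 352)))
#> $gmacs     10.85507   # billions of multiply-accumulates per forward pass
#> $params_m  24.03585   # trainable parameters, millions
```

## Command line

```sh
Rscript inst/cli/sranet.R synth --out data/demo --n 16 --seed 1
Rscript inst/cli/sranet.R train --synthetic --preset tiny --out runs/demo --seed 1
Rscript inst/cli/sranet.R eval --checkpoint runs/demo/checkpoint.rds --data data/demo --out runs/demo
Rscript inst/cli/sranet.R predict --checkpoint runs/demo/checkpoint.rds \
    --image data/demo/images/sample_0000.png --dump-attention --out runs/demo
Rscript inst/cli/sranet.R complexity --backbone res2net50 --input-size 352
```

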