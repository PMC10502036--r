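---
title: "Dual-attention polyp segmentation: model, objectives, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-attention polyp segmentation: model, objectives, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sranet)
```

## The model

Polyp segmentation needs two things at once: a clean separation of the polyp
from a noisy mucosal background, and a sharp delineation of a boundary that
is often low-contrast. The network here addresses each with its own
attention operator and lets the data decide, channel by channel, how much of
each to use.

Given backbone pyramid taps $F_3, F_4, F_5$ (strides 8/16/32), each reduced
to $C$ channels by a $1\times1$ convolution + batch norm + ReLU:

**Shallow attention.** $M_k^{SA} = \mathrm{ReLU}(\mathrm{up}(F_{k+1}))$ and
$F_k^{SA} = M_k^{SA} \otimes F_k$; with a second deeper map,
$F_k^{SA} = M_k^{SA} \otimes M_{k+1}^{SA} \otimes F_k$. Deep activations are
high on likely foreground, so the product suppresses background in the
shallow map while retaining its resolution.

**Reverse attention.** $M_k^{RA} = \sigma(\mathrm{up}(F_{k+1}))$,
$\tilde M_k^{RA} = 1 - M_k^{RA}$, $F_k^{RA} = \tilde M_k^{RA} \otimes F_k$.
The reversed map is large exactly where the deep features are uncertain or
background — which concentrates learning signal on the ambiguous boundary
band.

**Softmax gate.** Each branch is squeezed to a channel descriptor
$c = Z\,\mathrm{ReLU}(W\,\mathrm{GAP}(F))$ (no biases); the two descriptors
are stacked and a two-way softmax per channel yields convex gate weights
$v^{SA} + v^{RA} = 1$. The fused block output is
$v^{SA}\odot F^{SA} + v^{RA}\odot F^{RA}$. The two-way softmax is computed
as $\sigma(c^{SA} - c^{RA})$, which is algebraically identical and
numerically equivalent to max-subtracted softmax. Ablation modes replace the
gate by an unnormalized sigmoid pair or a plain sum.

The dual-attention block is applied twice: between $F_4$ and $F_5$
(two-input form), and between $F_3$, $F_4$ and $F_5$ (three-input shallow
form; the reverse map is driven by $F_4$, the nearest deeper level, which is
the natural reading of the block's $F_{k+1}$ input). The decoder is not
specified by the architecture this package follows, so a deliberately plain
head is used: upsample ×2, concatenate with the next pyramid output,
$3\times3$ conv + BN + ReLU (twice), $1\times1$ conv to one channel,
bilinear upsample to input resolution, sigmoid.

## Objectives and metrics

Training minimizes $L_{total} = L_{DICE} + L_{BCE}$ with
$L_{DICE} = 1 - 2\sum y\hat y / (\sum y^2 + \sum \hat y^2 + \varepsilon)$
(per image, $\varepsilon = 1$ by default) and pixel-mean binary
cross-entropy with predictions clamped to $[10^{-7}, 1-10^{-7}]$. Two
deliberate interpretations:

- The name "weighted Dice" sometimes attached to this objective does not
  match its printed formula, which carries no pixel weights; the formula is
  implemented as printed, and a boundary-weighted variant
  ($1 + 5\,|\mathrm{avgpool}(y)-y|$ weights) is available behind
  `dice_loss(..., boundary_weighted = TRUE)` for experimentation.
- A BCE variant with $\log(1-\hat y^2)$ in the background term circulates in
  print; it is not the cross-entropy of any distribution and breaks the
  usual $y=0$ limit, so the standard form is the default and the variant is
  available via `bce_loss(..., printed_form = TRUE)` for comparison only.

Evaluation: Dice and IoU on predictions thresholded at 0.5 (empty-vs-empty
defined as 1), MAE on the soft prediction, and three saliency-style scores —
weighted $F_\beta$ ($\beta^2 = 1$ by default, configurable to 0.3), the
structure measure ($\alpha = 0.5$), and the enhanced-alignment measure
reported as the maximum over 255 evenly spaced thresholds. Two numerical
notes: the enhanced-alignment normalization divides by $n-1$, which can
nudge a perfect score marginally above 1 on small images, so scores are
capped at 1 to honor the $[0,1]$ contract; and the weighted $F_\beta$
assigns each background pixel the error of its *nearest* foreground pixel,
with distance ties broken by pixel order — the measure is therefore
invariant to image flips only up to tie effects. The nearest-foreground
search is an exact vectorized scan, quadratic in image size, which is
immediate at the evaluation sizes used here.

## Synthetic data

The generator emulates the features that make this task hard: polyps are
Fourier-perturbed ellipses (star-convex, hence connected) whose palette
blends into a textured mucosa background over a band of width
$\sigma_b$ pixels (the ambiguous boundary; $\sigma_b = 0$ yields a step
edge), backgrounds carry low-frequency value-noise texture and multiplicative
speckle, and specular glare disks appear with configurable probability.
Masks are the exact pre-blend blob supports. Defaults: 64 px images, 1–2
polyps of radius 0.12–0.25 of the image side, $\sigma_b = 2.5$ px, 3%
speckle, 30% glare probability — values chosen once as a plausible miniature
of endoscopic scenes.

What the generator does *not* emulate: real mucosal texture statistics,
specular reflections tied to scene geometry, camera vignetting and motion
blur, flat/sessile polyp morphologies, and inter-dataset distribution shift.
Passing the desk-scale tests therefore demonstrates that the architecture,
objectives, optimization and metrics are implemented correctly and can fit
polyp-like structure — not that benchmark-level clinical performance
transfers.

## Training recipe

The full-scale recipe is kept as stated: 128 epochs, batch 64, SGD with
separate learning rates for backbone (0.004) and head (0.4), halved every 32
epochs; flips and 90° rotations each with probability 0.5; color exchange
(per-channel mean/variance transfer between training images, applied to 50%
of each batch with a random partner — the rate is this package's choice);
multi-scale training by resizing to 352 and rescaling to a side drawn from
{256, 288, 320, 352} with probabilities {0.1, 0.2, 0.3, 0.4}. "Cropping
among sizes" is ambiguous between cropping and rescaling; rescaling is used
because a 256 crop of a 352 canvas can discard nearly half the area and
whole polyps, and a crop mode would change the label geometry. The rotation
set is {0°, 90°}; 180°/270° arise as compositions with flips. The optimizer
is SGD with Nesterov momentum 0.9, the convention of comparable released
segmentation recipes. No warmup or early stopping is used.

The desk-scale study preset (`train_config(preset = "tiny")`) runs the same
loop end to end at CPU scale: `tiny_test` backbone (five 3×3 conv stages,
~0.1 M parameters with head, same stride signature as the full backbones),
64 px inputs, batch 8, 10 epochs, learning rates 0.1 (head) and 0.01
(backbone) — the published rates target batch-64 SGD on a 24 M-parameter
pretrained backbone and do not transfer to a 60 k-parameter model trained
from scratch at batch 8, so the preset uses rates chosen once for stable
optimization at this scale (keeping the head an order of magnitude hotter
than the backbone, as in the full recipe). Multi-scale
resizing is off in the preset because the candidate sides are defined at
full scale. Problem sizes used by the tests and the acceptance script — 200
samples, 180/20 train/held-out split, 10 epochs — are the package's
desk-scale study conditions.

Determinism: every consumer of randomness reseeds from
`mix_seed(seed, stream)` — per-sample for generation, per-epoch for
shuffling/augmentation — so a shorter run reproduces the prefix of a longer
one and the whole study is a pure function of one seed.

## Design choices where the architecture was open

- **Upsampling** is bilinear with the half-pixel (align-corners = FALSE)
  convention; nearest neighbor is available for exact integer tests. The
  order is upsample-then-ReLU, following the printed operator composition.
- **Gate FCs** carry no biases; hidden width is $\max(1, \lfloor C/4
  \rfloor)$ (the squeeze-excitation reduction pattern; no ratio is stated).
  Each branch and each pyramid level owns its own $(W, Z)$ pair, the
  reading suggested by the per-level, per-branch subscripts.
- **Projection width** $C = 64$; post-projection widths are not stated, and
  64 matches the lightweight-head convention of comparable networks. This,
  plus the unspecified decoder, is why complexity parity is quoted within a
  tolerance rather than exactly.
- **Baseline ablation** decodes from projected $F_5$ alone through the same
  head (upsampled into both decoder slots); it builds no shallow projections,
  so the baseline has strictly fewer parameters than the attention variants.
- **Pyramid modes**: `full_fp` applies the block at both passes;
  `single_pass` only between $F_4$/$F_5$ (the shallow level is then the
  upsampled block output); `none` is the baseline pass-through.
- **Batch norm** uses batch statistics in training and running statistics in
  evaluation (momentum 0.1), making evaluation-mode forwards bit-exact
  reproducible.
- **Complexity accounting**: a $k\times k$ convolution costs
  $k^2 C_{in} C_{out}$ MACs per output pixel and the same parameter count
  (no biases); BN costs 2 parameters per channel and 2 ops per element; FCs
  cost their weight count; activations, pooling and interpolation are free.
  Counts are derived from the same layer records the builders register, so
  the static count equals the instantiated parameter count by construction.

## Known limitations

- The forward/backward engine is plain R on BLAS; it is sized for the tiny
  backbone and small images. The 50-layer backbones build and run, but
  training them at 352 px is far outside CPU budgets — they exist for
  architecture-faithful complexity accounting and for plugging in weights.
- Pretrained backbone weights are not downloaded or bundled; full-scale
  benchmark scores on the public colonoscopy datasets are out of scope.
- The weighted $F_\beta$ nearest-foreground scan is quadratic in pixels;
  fine up to ~128 px images, slow beyond.
- Gate adaptivity (reverse-attention weight rising on boundary-ambiguous
  data, shallow weight on noisy-background data) is observable through the
  diagnostics (`predict_mask(..., diagnostics = TRUE)`) but is an
  exploratory property of trained models, not an asserted invariant.
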