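---
title: "Evidential Dirichlet segmentation of diffuse ultrasound nodules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidential Dirichlet segmentation of diffuse ultrasound nodules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Diffuse liver-fibrosis nodules in B-mode ultrasound are hard to segment for
three reasons: their boundaries fade gradually into the surrounding
parenchyma (no sharp acoustic interface), their texture overlaps heavily
with the background in gray level, and conventional softmax segmenters are
overconfident exactly where the image is most ambiguous. `espdnet`
implements an uncertainty-aware encoder/decoder that treats per-pixel class
probabilities as a Dirichlet random variable, uses the resulting epistemic
uncertainty to gate its own feature propagation, and concentrates a final
geometric refinement step on the uncertain boundary band. A deterministic
speckle-phantom generator makes the whole pipeline trainable and testable
on one CPU.

## Model

### Evidential output head

For a two-class problem each pixel's class probability vector follows
`Dir(alpha)` with concentrations `alpha_k = 1 + softplus(z_k)` computed
from the evidence logits `z`. The total evidence `S = sum_k alpha_k` gives
the epistemic uncertainty

```
U = K / S,   K = 2,
```

so `U = 1` at total ignorance (`alpha = (1, 1)`) and `U -> 0` as evidence
accumulates. The predicted mask is the Dirichlet mean
`p_k = alpha_k / S` — not a separate softmax head — so mask and
uncertainty are consistent by construction. Two pixels with identical
`p ≈ 0.5` are distinguished by `S`: a high-evidence pixel is a confident
boundary, a low-evidence pixel an ambiguous region.

The softplus evidence activation is a deliberate choice (the source
architecture does not specify one): it guarantees `alpha >= 1` and
`U ∈ (0, 1]`, and its gradient never explodes the way exponential
activations do at batch size 4.

### Architecture

* **Encoder** — four stages of (two 3×3 convs + group norm + ReLU),
  attention, then 2× average pooling, giving pyramid strides 2/4/8/16.
  Stages 0–1 use squeeze-and-excitation channel gates (cheap, suited to
  low-level texture); stages 2–3 use CBAM channel + spatial attention.
  Group normalization is used throughout because the training protocol
  uses batch size 4. Skip features are taken after attention.
* **Dual-path bottleneck** — a semantic path of two deformable
  convolutions (offsets predicted per location, zero-initialized) on the
  stride-8 map, and a probabilistic path of windowed self-attention
  (window 4) on the stride-16 map upsampled to the stride-8 grid. The
  per-pixel variance across channels of the attention output, through a
  learnable affine, is the probabilistic attention map `A_prob`; fusion is
  `F_guided = F_sem * (1 + alpha * sigmoid(A_prob))` with `alpha`
  learnable from 0, followed by a pointwise FFN over the concatenated
  paths plus a residual projection of the bottleneck input. The variance
  map is passed through a learnable affine rather than a fixed sign
  because the direction of the variance–certainty relationship is left
  open by the architecture description; the network learns the polarity.
* **Evidential decoder** — four stages upsample 2× each; every stage has
  an evidence head whose Dirichlet field exports a per-scale uncertainty
  map (the evidence pyramid, coarsest to finest). Encoder skips are
  modulated by a Dirichlet attention map `A_Dir` — windowed single-head
  cross-attention with queries from the evidential probability mask
  (p and U) and keys/values from bottleneck semantics plus fused edges —
  via `F * (1 + alpha * A_Dir)` and a 1×1 channel reduction. The
  cross-attention runs at the two coarsest skip scales; the finest skip
  reuses the upsampled map (cost). A gated residual attention over
  `[Q_pred, K_conf = 1 − U, V_evidence]` re-weights decoder features; its
  zero-initialized final layer makes it start at exactly 0.5 and its
  modulation start at identity.
* **Boundary refinement** — Sobel magnitude of the raw image (normalized
  per image by its maximum, for contrast invariance) is fused with a
  learnable semantic edge map from the bottleneck features into
  `E_boundary = sigmoid(w1·E_sobel + w2·E_sem + b)`. The boundary
  attention combines `U`, the ambiguity `1 − 2|M − 0.5|`, and
  `E_boundary` through cascaded 3×3 convs. The mask update is the gated
  residual `M <- clamp01(M + A_boundary ⊙ ΔM)` with `ΔM` tanh-bounded and
  predicted by shared-weight convs, applied for 2 iterations with
  `A_boundary` recomputed each time so the gate tracks the evolving
  ambiguity band. Clamping (rather than renormalizing) preserves the
  identity `M_refined = M_coarse` wherever `A_boundary = 0` exactly.

### Losses

The region loss is `alpha·Dice + beta·Focal + gamma·Boundary` on the
refined mask with defaults `(1, 1, 0.5)`; the boundary term is the mean of
`pred ⊙ phi(target)` with `phi` the signed Euclidean distance map
(negative inside). The evidential loss is the expected cross-entropy under
the predicted Dirichlet, `sum_k y_k (digamma(S) − digamma(alpha_k))`,
annealed linearly from 0 over 10% of the scheduled epochs by default
(standard practice: applying it at full weight from the start collapses
evidence before features exist). Desk-scale runs pin the window at 10
epochs — the absolute scale implied by the full 256-epoch protocol —
because the collapse dynamics the anneal guards against operate on
absolute step counts, not on fractions of the schedule.

Two scheduling details matter in practice and are deliberate deviations
from a naive reading of the loss definition:

* The **boundary term is annealed** on the same linear ramp as the
  evidential term. Applied from epoch 0 it dominates the total gradient
  (its positive exterior mass scales with the image diagonal while Dice
  gradients are O(1/area)) and reliably drives the network into the empty
  prediction. The pure `liver_loss()` function keeps constant weights;
  only the training schedule ramps.
* The **focal foreground weight**: `loss_config()` defaults to the
  conventional `alpha_f = 0.25`, but desk-scale training of this task
  uses `alpha_f = 0.75`. With 3–8% foreground, weighting the rare class
  at 0.25 puts three quarters of the focal mass on background and
  reinforces the empty-prediction fixed point.

## Synthetic phantoms: what they emulate and what they do not

`generate_phantom()` produces single-channel speckle images with paired
binary masks in four morphologies — cord-like fragments, dispersed small
particles, massive dense clusters (pairwise gap at least 1 px, so
connected components equal the drawn nodule count), and fusiform
low-contrast spindles (contrast halved) — plus a mixed mode. The clean
field is a smooth heterogeneous background (~0.35 ± 0.05) plus
`contrast_delta` (default 0.15) inside nodules, blurred with a Gaussian of
`boundary_blur_sigma = 2` px to create gradual transitions, multiplied by
mean-1 gamma speckle, optionally crossed by a half-intensity vertical
shadow band (p = 0.2), and clipped to [0, 1]. Foreground fraction is
rejection-sampled into [0.03, 0.08] with geometric rescaling between
attempts. Everything derives from one seed; regeneration is byte-identical.

Parameter choices the source leaves open, fixed once here:

* `speckle_shape = 16` (≈25% multiplicative noise). This emulates
  *displayed*, log-compressed B-mode texture. It was calibrated once so
  that the desk-scale (64 px) phantoms sit in an achievable-segmentation
  regime comparable to the source data (where Dice ≈ 0.85 was reached),
  while preserving a large foreground/background histogram overlap
  (coefficient ≈ 0.6–0.8, well above the 0.3 regime bound). Heavier
  speckle (shape 4) makes the 64 px phantoms unsolvable by any method
  (optimal-threshold oracle Dice ≈ 0.3), which would contradict the
  stated desk-scale behaviour of the pipeline.
* **Feature-size floors** (cord thickness 4 px, particle radius 3.5 px,
  dense radius 4 px, fusiform semi-axes 8/3 px) keep nodules resolvable
  under the fixed 2 px blur at the 64 px test profile: the boundary
  transition width stays comparable to the nodule scale (the diffuse
  regime), but the nodule interior survives the blur. They are inactive
  at the 320 px protocol size and relax proportionally below 64 px.
  Nodule counts are chosen adaptively within the per-morphology ranges so
  the 3–8% target stays reachable at any size. The calibration criterion,
  applied once: the desk-scale world should sit in the same
  achievable-segmentation regime as the full-scale one, where simple
  baselines reach moderate Dice and the full model high Dice — not in a
  regime where nodules are smaller than the blur kernel and no method can
  recover them.

What a green desk-scale test does *not* establish: the phantoms have no
anatomy, no depth-dependent attenuation or focal zones, no correlated
(point-spread-function-shaped) speckle, and no inter-observer label noise.
Results at 64 px with the tiny channel profile demonstrate that the
mechanisms work and interact as designed, not clinical performance.

## Training protocol

`train_config("full")` reproduces the published protocol: AdamW, learning
rate 1e-4, weight decay 1e-5, batch 4 (gradient accumulation over
single-sample tapes), at most 256 epochs, ReduceLROnPlateau on validation
Dice (patience 5, factor 0.5), early stopping (patience 20), best
checkpoint by validation Dice, synchronized augmentation (flip p = 0.5,
rotation ±15°, scale ±10% applied identically to image and
nearest-neighbour mask; brightness/contrast ±20% and Gaussian noise on the
image only). The `amp` flag is accepted for interface compatibility but is
a no-op: this CPU implementation always computes in double precision.

The tiny profile scales this down for a single CPU: learning rate 1e-3
(the step size is scaled up because desk runs use ~30× fewer epochs) and
AdamW `beta2 = 0.99` (a 0.999 second moment barely adapts within a few
hundred steps). The desk-scale acceptance runs additionally use learning
rate 3e-3, per-scale (deep) supervision of the evidence heads — a config
flag; the package default supervises only the finest scale — and no
augmentation: with abundant fresh synthetic samples and few epochs,
underfitting is the binding constraint, not overfitting.

Two further training details. A light (weight 0.2) auxiliary Dice + Focal
term supervises the coarse probabilistic mask: without it the gradient
satisfies the mask losses entirely through the refiner and the evidence
head stays soft, which destabilizes the uncertainty–error coupling; a
heavy auxiliary weight instead leaves the refiner nothing to correct.
And by default the trainer keeps a running average of the weights over
the second half of the schedule (stochastic weight averaging), adopting
it if its validation Dice beats the best single epoch — short schedules
have noisy epoch-to-epoch validation trajectories, and the tail average
is usually at or above the trajectory's level. Group normalization makes
this safe (no running statistics to recompute).

## Evaluation

Region metrics (Dice, IoU, precision, sensitivity) use the standard
confusion-count definitions with the all-empty convention of 1.
Surface metrics extract boundary pixels by 8-connectivity erosion
difference and pool the directed nearest-neighbour distances of both
directions; HD95 is the 95th percentile (linear interpolation) of that
pooled multiset — some tools instead take the maximum of per-direction
percentiles; the pooled form is used consistently here and matched by the
brute-force oracle in the tests — and ASSD its mean. Boundary-F1 matches
boundary pixels within a 2 px tolerance. ECE bins `max(p, 1−p)`
confidences into 10 equal-width right-closed bins. The
uncertainty–error correlation is implemented as the point-biserial Pearson
correlation between per-pixel `U` and the 0/1 error indicator, pooled over
the evaluation split — the metric is named but not defined in the source;
this interpretation is flagged here deliberately. Degenerate (constant)
inputs return 0 with a `degenerate` attribute rather than NaN.

Model comparisons use a paired sign-flip permutation test on per-sample
metric differences (statistic: absolute mean difference), enumerated
exhaustively when `2^n` fits in the resample budget and add-one corrected
otherwise.

### Calibration at desk scale

Two facts about calibration in the synthetic desk-scale world deserve
stating plainly, because they differ from the clinical setting this model
family targets. First, a softmax baseline trained with Dice + Focal on
clean phantoms is itself well calibrated (ECE near 1%): the focal loss is
a calibrating loss, and the phantoms lack the label ambiguity that drives
softmax overconfidence on real data, so the large softmax calibration
errors reported on clinical material do not reproduce here. Second, the
full evidential model's final output inherits a mild overconfidence from
the refinement stage — the clamp maps many pixels to exactly 0/1, i.e.
confidence 1.0 at accuracy ~0.98 — while its raw Dirichlet mean is
underconfident, because the training gradient can satisfy the mask losses
through the refiner without ever sharpening the evidence head. The
evidential model's absolute ECE stays around 2%; but a desk-scale test
that expects it to beat the softmax baseline's calibration can fail for
these structural reasons, and the test suite documents exactly that.

## Numerical and degenerate-input decisions

* Empty target in the boundary loss: `mean(pred) · diagonal` (documented
  sentinel; the distance map is undefined).
* Empty mask in surface distances: both metrics return the image diagonal
  with a warning.
* Focal loss clips predictions to `[1e-7, 1 − 1e-7]`; gradients are zeroed
  in the clipped region.
* `refine` clamps rather than renormalizes, preserving the closed-gate
  identity exactly; clamping never increases the applied correction.
* Convolutions use zero padding (shape-preserving); Sobel uses reflect
  padding so constant images give exactly zero gradient.
* Windowed attention requires window-divisible grids and raises an error
  rather than padding implicitly.
* All tape gradients are validated against central finite differences in
  the test suite; the kink points of ReLU/clamp make those checks exact
  only away from the kinks, so the tests use interior-safe tolerances.

## Known limitations

The implementation is a from-scratch autodiff on one CPU: no GPU, no
mixed precision, practical image sizes up to the 320 px protocol for
inference and desk-scale sizes for training. The evidential decoder's
cross-attention wiring follows the prose description of the evidence
query/key-value paths; the original figure-level tensor wiring admits
other readings. K > 2 classes are parameterized but untested. The phantom
generator is a statistical surrogate, not an acoustic simulation.
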