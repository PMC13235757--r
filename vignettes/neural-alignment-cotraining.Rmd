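---
title: "Multi-stage neural alignment co-training: models, losses and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stage neural alignment co-training: models, losses and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Convolutional networks trained purely on object categorization are brittle
under common image corruptions. One hypothesis from visual neuroscience is
that constraining a network's intermediate representations to resemble
recordings from the primate ventral stream — V1, V4 and inferior temporal
(IT) cortex — transfers useful inductive biases and improves robustness.
`neuralign` implements this co-training paradigm end to end: a CORnet-Z
style backbone whose blocks are named after the cortical areas they model,
three alignment objectives that pull a block's representation towards
stimulus-matched neural responses, scoped backpropagation so each
alignment term only shapes the network prefix that produced it, a
shuffled-pairing control, and a matched-seed corruption-robustness
evaluation protocol.

## The combined objective

A run minimizes

L_total = Σ_block λ_block · L_align(block) + L_ce,

with block ∈ {V1, V4, IT}. λ_block = 0 for every block defines the
baseline (pure cross-entropy). λ values are arbitrary non-negative reals;
`alignment_spec(grid_check = TRUE)` restricts them to the replication grid
{0, 0.1, 0.25, 0.5, 0.75, 0.9}. The identity `total = ce + Σ λ·align` is
enforced exactly (`combined_loss()`), and the per-epoch metrics log lets
you re-verify it.

Two optimizers run side by side, as in the original recipe: the backbone
uses SGD (momentum 0.9, learning rate 1e-3, weight decay 1e-4) on the
full combined loss; each projector pair uses RMSprop (learning rate 1e-4,
weight decay 1e-5). Classification minibatches have 256 images, neural
minibatches 50 stimulus-response pairs; each aligned area consumes one
neural minibatch per classification step, cycling its dataset
independently with reshuffling on every pass.

### Scoped backpropagation

The alignment term for block B is computed by running the neural stimuli
forward only up to B, projecting the flattened tap with f_x, projecting
the response vectors with f_y, and evaluating the loss. Because the
forward pass for that term stops at B, its gradient reaches exactly the
projectors and the backbone prefix up to and including B; downstream
parameters receive identically zero gradient from it. This is verified in
the test suite by inspecting gradients and by checking that a V1-only
aligned step leaves V2/V4/IT/decoder parameters on the pure cross-entropy
trajectory bit for bit.

## Alignment losses

* **DCCA** — minus the sum of the top-C canonical correlations between
  the two projected views. The CCA core computes singular values of
  `T = S11^{-1/2} S12 S22^{-1/2}` with diagonal loading
  `rx = ry = 1e-3` on the within-view covariances; loading is needed
  because covariances are estimated per 50-sample minibatch. The loading
  biases each correlation towards `v/(v + r)` for a direction of variance
  `v`, so saturated correlations sit slightly below 1; the closed-form
  tests use a smaller loading to see the exact bound. C defaults to 10 —
  the projector output width, i.e. all pairs. Gradients follow the
  standard singular-value calculus for this construction.
* **InfoNCE (NT-Xent)** — the 2n model and brain embeddings are pooled;
  each matched pair is a positive and the 2n − 1 other samples are
  negatives under a cosine-similarity softmax at temperature τ = 0.5;
  the loss averages over both orderings of every positive pair. For
  identical embeddings it equals log(2n − 1).
* **VICReg** — weighted sum of invariance (mean squared pairwise
  distance), variance (per-dimension hinge `max(0, γ − sqrt(Var + ε))`
  towards target spread γ = 1) and covariance (scaled squared
  off-diagonal entries of the per-view covariance), with weights
  (α, μ, ν) = (2, 2, 1) and ε = 1e-4.

A note on the VICReg variance hinge: one printed form of the loss reads
`γ − Var + ε` inside the hinge, while the original VICReg formulation —
which this package follows by default — hinges on the regularized
standard deviation, `max(0, γ − sqrt(Var + ε))`, with ε described as a
variance stabilizer. We treat the variance-form as a likely typesetting
artifact but expose both behind `vicreg_params(variance_hinge =)`.

All three losses return analytic gradients with respect to both views;
the suite checks them against central finite differences, and DCCA
against an independent generalized-eigenvalue CCA solver.

## Architecture

The `cornet_z` backbone follows the published block layout (7×7 stride-2
V1 convolution, then three 3×3 blocks, 3×3 stride-2 max-pools, widths
64/128/256/512, global average pool, linear head), Xavier-uniform
initialized from the run seed. Features are tapped at each block's
post-nonlinearity, post-pool output and flattened — the Brain-Score
convention for CORnet-Z. Projector pairs are two independent MLPs (three
hidden layers of width 1024, ReLU, dropout 0.5, linear output of width
10), weights drawn from Normal(0, 0.01); the brain view receives raw
per-site response vectors, with no PCA or whitening.

The `tiny` variant (widths 8/16/16/32, 3×3 stride-1 V1, 2×2 pools) keeps
the block names, order and every tap contract, and exists so the full
pipeline runs quickly on a CPU. Halving the CORnet-Z widths would still
be far too heavy for that purpose, which is why the tiny widths are
fixed small rather than derived by halving.

## Reproducibility and the matched-seed design

One master seed drives everything through independent derived streams
(`derive_seed(seed, tag)`): backbone init, per-block projector init,
per-epoch data order, per-batch augmentation draws, per-step dropout,
response noise, pairing shuffles. Streams matter: a baseline run has no
projectors, so projector draws must not shift the classification data
order — with derived streams, every configuration sharing a seed starts
from identical backbone weights and sees the identical minibatch
sequence. Comparisons across configurations are therefore within-subject,
and significance is assessed with paired t-tests on seed-wise scores,
Benjamini–Hochberg corrected across the corruption family at q = 0.05
(two-sided; the family is one model-vs-baseline comparison across all
corruptions).

Relative gain is `(model avg / baseline avg) · 100` on severity-averaged
accuracies, computed per matched seed; error bars are the standard error
of the per-seed gains. A shuffled-control comparison reuses the same
machinery with the shuffled run in the baseline slot.

## The synthetic data

`generate_task()` draws class-conditional oriented gratings (orientation,
spatial frequency and colour tint depend on the class; phase is random)
plus Gaussian pixel noise, balanced across classes, split 80/10/10 and
normalized with training-split channel statistics. The signal is strong
enough that multinomial logistic regression on raw pixels comfortably
beats chance — calibrated in the suite — while a network still has
something to learn. Defaults are 8 classes × 250 images at 32×32.

`generate_responses()` implements a teacher construction: a frozen,
randomly initialized backbone of the same architecture family, a fixed
random linear readout of the matching block's features per area, and
rectification, optionally plus Gaussian noise. Site counts default to
166 (V1), 88 (V4) and 168 (IT), matching the recording-set shapes the
full-scale experiments use. The teacher gives every area
stimulus-dependent structure at the right depth of abstraction — which
is the property the shuffled-pairing control destroys — without claiming
biological realism: there are no tuning curves, receptive fields or
noise correlations, so passing desk-scale tests demonstrates sensitivity
to response *structure*, not fidelity to cortex.

`corrupt_images()` provides four of the corruption families used by
CIFAR-C style benchmarks — additive Gaussian noise, contrast reduction,
brightness shift, pixelation — each with five severities whose parameters
are monotone in severity (verified on a fixed probe set). The full
19-type corruption suite is consumed from the published dataset at full
scale and is deliberately not re-created here.

## Desk-scale experiment configuration

The CPU-scale study used by the acceptance tests and `scripts/acceptance.R`
runs the tiny backbone on an 8-class task of 100 images per class at
16×16 pixels, with 400 neural stimuli per area (sites 166/88/168,
noiseless teacher), λ = 0.5 on all three blocks, 15 epochs,
classification batches of 64, neural batches of 50, projector width 128,
and five matched seeds. Two deliberate departures from the full-scale
recipe, both consequences of scale:

* **Projector learning rate 1e-3** (instead of 1e-4). The full-scale
  rate is tuned for roughly 10^5 projector updates; at a few hundred
  updates the projectors would never leave their small-weight
  initialization regime — VICReg in particular sits on the variance-hinge
  plateau (outputs still collapsed, loss ≈ μ·2γ) for thousands of
  low-rate steps. Scaling the rate with the shortened schedule is the
  standard adjustment.
* **Classification batch 32** (instead of 256), so an epoch provides
  enough optimization steps at the small dataset size — 20 steps per
  epoch over 640 training images, hence 300 neural minibatches per
  aligned area across the 15 epochs.

Two desk-scale properties mirror the full-scale findings directionally:

1. **Co-training vs post-hoc alignment of the baseline.** Each
   co-trained run's final eval-mode per-block alignment loss is compared
   with a post-hoc fit on the matched baseline: the baseline backbone is
   frozen and fresh projectors are trained on the alignment loss alone
   (`posthoc_alignment()`), with the same number of updates co-training
   provided, the same optimizer and dropout. Equal update counts are
   essential — a post-hoc fit with fewer updates would be a strawman.
   The comparison carries a known desk-scale caveat, reported rather
   than hidden: the post-hoc fit trains against stationary features
   while co-training chases a moving backbone, and with a noiseless
   same-family teacher the baseline's features are themselves nearly
   maximally alignable, so at short schedules the post-hoc fit can
   converge faster than the co-trained run even when co-training has
   genuinely improved the representations. The suite asserts the strict
   per-block version of this comparison and the acceptance script
   reports the measured win fractions as they come out.
2. **Pairing structure matters.** With matched seeds, correct-pairing
   co-training ends at a lower total alignment loss than
   shuffled-pairing co-training for DCCA and VICReg — the desk-scale
   analogue of the shuffled-data control experiment's direction (InfoNCE
   is expected to be indifferent, as at full scale).

Both are asserted in ≥ 4 of 5 matched seeds, never as magnitudes.

## Numerical choices and degenerate inputs

* CCA requires n > d and non-constant views; violations raise
  numerical-degeneracy errors rather than producing silent nonsense.
  Singular-value ties are resolved by the SVD's ordering; only the sum
  enters the loss, so ties cannot change it.
* InfoNCE refuses zero-norm embedding rows (cosine undefined) instead of
  epsilon-patching them, and refuses n = 1 (no negatives).
* Zero-variance paired differences yield an explicit infinite-t, p = 0
  outcome with a warning (or t = 0, p = 1 for identical samples) rather
  than an error or a silent NaN.
* Best-checkpoint selection breaks validation-accuracy ties towards the
  earliest epoch.
* Neural stimuli are resized/normalized with the classification
  training statistics and are never augmented; neural data are never
  split — every epoch trains on all of them.

## Known limitations

* The teacher-based generator shares the trainee's architecture family,
  which inflates alignability relative to real recordings; real neural
  data are noisier, lower-yield and not generated by any feedforward
  network.
* Desk-scale runs cannot reproduce full-scale magnitudes (relative-gain
  percentages, t-statistics, ~45% CIFAR-100 accuracy at 500 epochs ×
  10 seeds); the package asserts directions and mechanism contracts at
  small scale and leaves magnitudes to full-scale runs with the real
  datasets.
* Checkpoint files use R's native serialization and are not
  interoperable with other ecosystems.
* No distributed or mixed-precision training; no adversarial or
  behavioural-alignment benchmarks.
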