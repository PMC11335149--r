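---
title: "Decoding spatial auditory attention from region-pair interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding spatial auditory attention from region-pair interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurixn)
```

## The problem and the model

When a listener attends to one of two concurrent speakers, the spatial locus
of attention (left vs right) can be decoded from single trials of EEG.
`neurixn` implements a decoding pipeline that is deliberately *not* a black
box: its convolutional decoder is constrained so that the only route from
the input to the classifier passes through the element-wise products of all
pairs of ten cortical region signals.  The kernel weights applied to those
product channels — the *spatial filters* — therefore state directly which
inter-regional interactions the decoder relies on, and they can be
clustered, thresholded and knocked out to interrogate the trained model.

The input representation is source-space EEG summarized as ten regions of
interest (left/right occipital, parietal, temporal, central, frontal; codes
`LO ... RF`), several source time courses per region, sampled at 64 Hz in
50-s trials with binary attention labels and categorical condition tags.
Raw scalp EEG and source reconstruction are out of scope: the package
starts from region-level source signals, and ships a synthetic generator
that emulates their structure with planted, class-dependent effects so the
whole pipeline is testable without any external data.

### GED band enhancement

Each region's sources are reduced to one component per frequency band
(delta–theta 2–8 Hz, alpha 8–13 Hz, beta 15–32 Hz) by generalized
eigendecomposition: with `S` the covariance of band-pass-filtered sources
and `R` the broadband covariance, the first generalized eigenvector of
`S w = λ R w` maximizes the band-to-broadband power ratio.  Choices made
where the procedure is underdetermined:

* **Estimation window.** Covariances are estimated per trial and averaged
  over the *training* trials of a fold before one eigendecomposition, so
  the enhancement never sees validation or test statistics.
* **Shrinkage.** The reference covariance is shrunk by 1% toward the scaled
  identity (`shrinkage = 0.01`) to guard the solve against rank deficiency.
* **Application to broadband data.** Component weights are applied to the
  *unfiltered* sources.  The bands only shape the GED objective; all
  frequencies survive into the 30 channels, which is what makes the
  band-removal retests of a trained model meaningful.
* **Standardization.** Each enhanced channel is centered and scaled to unit
  variance.  The scale of a unit-norm eigenvector is arbitrary, and
  heterogeneous channel scales would make the shared batch-normalization
  statistic of the first convolution stage meaningless.
* **Filters.** Band filtering is a zero-phase (forward–backward) order-4
  Butterworth band-pass.  A band whose upper edge reaches Nyquist (beta at
  64 Hz) degenerates to a high-pass.
* **Sign and solver.** Eigenvectors are sign-fixed (largest-magnitude
  weight positive) and unit-normalized; the solve goes through a Cholesky
  factor of `R`, and the test suite checks it against an independent
  eigen-based whitening oracle.

### The interaction decoder

For a 30 × T window (T = 320 samples = 5 s), the decoder applies:

1. a temporal convolution with 4 kernels of length 31 (≈ half the sampling
   rate, so every frequency above 2 Hz is representable), same padding, no
   bias, batch normalization per temporal map;
2. per map, a grouped pointwise convolution collapsing each region's three
   band channels to one signal, then a depthwise temporal convolution
   (10 groups, kernel length 31) — 10 region signals per map;
3. the **interaction stage**: element-wise products of all 45 unordered
   region pairs, giving 4 maps of 45 × T;
4. a depthwise spatial convolution with one (45, 1) kernel per map — the
   spatial filters, constrained to Euclidean norm ≤ 1 by projection after
   every optimizer step — followed by batch norm, ELU, average pooling
   (1, 4) (64 Hz → 16 Hz) and dropout 0.5;
5. a separable convolution (depthwise temporal kernel of length 16 = 1 s at
   16 Hz, then a pointwise 4 → 4 mix), batch norm, ELU, average pooling
   (1, 8), dropout;
6. flatten and a bias-free linear map to two units with softmax.

All convolutions are bias-free.  The default model has 1848 trainable
parameters.  Where the architecture is underdetermined, the package takes
the compact-EEG-decoder conventions: the separable stage's kernel length
(16), pointwise width (4) and second pooling width (8) are the standard
choices for this family of models, both poolings sit after the interaction
layer, the "no fully connected layer" reading is *no hidden dense layer*
(the flattened features go straight to the two-unit softmax), and the
grouped stage-2 convolution uses group size 3 (one group per region), which
is forced by the requirement of a single output signal per region.  Batch
normalization uses one statistic per temporal map (momentum 0.1, variance
floor 1e-5); in evaluation mode it is a fixed affine map, which is what
makes the region-knockout nullity below *exact* rather than approximate.

The implementation is written in R with the temporal convolutions, the
fused interaction/spatial stage and batch normalization as compiled
primitives; gradients for every tensor are verified against central finite
differences in the test suite.

### Training and evaluation

Cross-entropy loss, Adam (learning rate 1e-3, default moments — the
optimizer's standard settings, since only the optimizer is prescribed),
batch size 32, a fixed epoch budget with validation stopping: after every
epoch the validation loss is recorded, and the parameters of the
best-validation-loss epoch are restored before the test set is touched.
Batch shuffling and dropout are seeded, so a training run is exactly
reproducible.

Two evaluation protocols are provided.  *Within-participant*: trials are
assigned to four blocks by condition-and-label stratified shuffling; each
fold trains on two blocks, validates on one and tests on one, rotating the
test block.  Because every window inherits its trial's block, 50%-overlap
windows can never straddle a partition.  *Cross-participant*: each
participant is the test set in five iterations with four randomly drawn
validation participants — 90 folds for 18 participants, 13 training
participants each.  Fold accuracies are averaged per participant and the
median across participants is the headline summary.

The band-power baseline summarizes each input as 40 log Welch-power
features (10 regions × delta/theta/alpha/beta) fed to a single logistic
unit trained by full-batch gradient descent (learning rate 0.05, features
z-scored on the training set) under the same validation-stopping protocol.

### Interpretation and ablation

Spatial filters are sign-aligned (a filter and its negation implement the
same decoder up to downstream sign absorption), clustered per participant
by cosine k-means (k = 4, ten restarts, 100 iterations, best
within-cluster distance sum kept), and the per-participant centroids are
clustered at the group level by average-linkage agglomeration on cosine
distances — average linkage being our choice where only the metric is
prescribed.  Within a filter, *significant interactions* are entries whose
within-filter z-score (population SD, the array-zscore convention)
exceeds the two-sided normal 0.05 threshold; two-sided because
interpretable filters assign meaningful negative weights (e.g. hemispheric
contrasts).

Ablations re-test a trained model without retraining: kernel masks zero all
spatial-filter columns touching a lobe (17 of 45 columns), a hemisphere
(35 of 45) or a significant-interaction set; input-side ablations band-stop
or band-pass the test windows (band-pass adds a 0.5 Hz DC block for
numerical hygiene).  Because the classifier sees the inputs only through
the interaction channels, a region knockout makes the logits *exactly*
invariant to that region's input channels — a property the tests assert
bit-for-bit.

## The synthetic study conditions

The generator emulates the reference recording layout: 4 participants,
24 trials of 50 s at 64 Hz, 2 sources per region, balanced left/right
labels, three condition tags assigned round-robin (they carry no signal;
they exist to exercise stratification).  Each source mixes:

* pink 1/f background noise (SD 1.0);
* band-limited oscillations per canonical band — filtered white noise, not
  sinusoids, so GED covariances are well conditioned — at amplitude 0.5,
  i.e. each narrowband rhythm is a minority of the broadband power, with
  alpha power in the parietal regions multiplied by 2 contralateral to the
  attended side (attending left raises right-parietal alpha);
* for the planted RP–LP pair, a shared alpha-band oscillation modulated by
  a shared slow (< 1 Hz) positive envelope (depth 0.5), added to both
  regions at amplitude 1.0 in attend-left trials only.  The component is
  *coherent* across the two regions, which is exactly the structure a
  pairwise-product channel can express.

What passing tests on these data do and do not show: the generator plants
linear mixing, stationary band-limited rhythms and one coherent coupling;
real source-space EEG adds nonstationarity, volume-conduction leakage
between regions, artifacts and inter-participant variability.  Recovery of
the planted structure validates the *machinery* (enhancement, training,
interpretation, ablation), not performance claims on real recordings.

## Validation protocol and problem sizes

The acceptance script and the heavyweight tests run, at sizes chosen to
keep a full run in minutes on one core:

* **Parameter recovery** — 10 seeded replicates cycling over the 4
  synthetic participants; each trains one within-participant fold (12
  training / 6 validation / 6 test trials → 228/114/114 windows of 5 s)
  for 80 epochs, then checks that the planted RP–LP pair is significant in
  at least one centroid of either clustering level (the individual k-means
  centroids or their group-level agglomeration) and that an alpha
  band-stop of the test inputs causes the largest band-ablation drop.
  80 epochs sits past the point where the validation loss of these runs
  bottoms out (best epochs typically 60–75).  The recovery check is the
  tightest of the three: trained filters spread weight over every pair
  touching the coupled regions (their products all carry class-dependent
  variance), so the planted pair's within-filter z typically sits near
  2–2.5 and single replicates can miss the 1.96 threshold.
* **Null control** — one fold trained after globally permuting window
  labels; its test accuracy must stay inside the 99% binomial chance band
  for the test-window count.
* **Solver oracle** — 100 random 4-source instances comparing the
  Cholesky-based generalized eigensolve to the whitening oracle at 1e-6.

## Known limitations

* The decoder expects the canonical 10-region, 3-band, 64 Hz layout;
  other montages require regenerating the pair index and configuration.
* Cross-participant training pools windows across participants with
  per-participant GED enhancement fitted on each participant's own
  (unlabeled) data; alternative transfer schemes are not implemented.
* The exact Wilcoxon branch enumerates sign patterns only up to n = 15
  when absolute differences are tied; larger tied samples use the normal
  approximation.
* Batch normalization in training mode couples windows within a batch, so
  knockout nullity is exact in evaluation mode (the mode used for all
  reported accuracies and ablations).
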