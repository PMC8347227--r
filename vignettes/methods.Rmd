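---
title: "Cross-subject transfer learning for motor-imagery EEG: models and design choices"
author: "bcitransfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject transfer learning for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A sizeable fraction of brain–computer-interface users cannot produce
decodable motor-imagery (MI) patterns — so-called BCI inefficiency. This
package implements a cross-subject transfer-learning pipeline that tries to
lift the classification accuracy of such poor performers by (i) training a
"Deep-and-Wide" convolutional classifier per subject on topographic EEG
features, (ii) measuring between-subject similarity in a fused kernel space
that combines the EEG feature embedding with psychological-questionnaire
scores, (iii) selecting donor ("source") subjects among the best performers
by a marginal domain-distance statistic, and (iv) initializing the target's
network from the source's trained parameters before fine-tuning.

Because the package must be testable without any external recordings, it
ships a synthetic cohort generator that emulates the statistical structure
the pipeline exploits; the generator is first-class, tested code.

# Bi-domain topographic features

Each trial is a `C x T` matrix at sampling rate `fs` with a one-hot class
label. Preprocessing band-passes every channel to 8–30 Hz with a
fifth-order Butterworth filter applied forward–backward
(`signal::filtfilt`). Zero-phase filtering was chosen because the analysis
is strictly offline; the effective attenuation order doubles, which is
harmless here.

Trials are cut into sliding windows of `tau = 2` s stepped by 1 s. The
analyzed span defaults to a 6 s interval from trial onset, so that five
segments result; the span is configurable because acquisition protocols
differ in where the imagery interval sits inside the recorded trial.

Per segment and per band (mu 8–12 Hz, beta 12–30 Hz) two per-channel
feature vectors are formed:

* **CSP back-projection.** Common spatial patterns are fitted per
  (band, segment) slot on training trials only, with trace-normalized,
  shrinkage-regularized covariances (`(1-s)*Sigma + s*mean(diag)*I`,
  default `s = 0.1`; the regularizer is deliberately the simplest
  Ledoit–Wolf-style target since nothing more specific is required).
  Component log-variances are min–max normalized and mapped back to
  channel space through the magnitudes of the scalp patterns,
  `x_c = sum_k |A[c,k]| f_k`. This back-projection keeps the feature in
  channel space so it can be rendered as a scalp map; the absolute value
  discards pattern polarity, which is irrelevant for an energy feature.
* **Morlet band energy.** A complex Morlet continuous wavelet transform
  with 32 log-spaced scales spanning 8–30 Hz and bandwidth–centre-frequency
  product fixed at 1. "32" is interpreted as the number of scales: that
  reading is reproducible and makes the scale bank exactly cover the
  analysis band. The per-channel feature is the mean squared coefficient
  magnitude over the in-band scales. Note the spectral resolution this
  implies (about `f/4` at centre frequency `f`): tones within ~1 Hz of the
  12 Hz band edge excite both bands, which the tests respect by checking
  the *peak* scale rather than band averages near the edge.

Each feature vector is rendered as a `W x H` scalp image ("topogram"):
electrode positions are mapped by the azimuthal-equidistant projection
(vertex at the origin, equator on the unit circle, nose up), interpolated
with a thin-plate spline, masked to the unit disc and min–max normalized to
`[0, 1]`. A thin-plate spline was chosen over piecewise-cubic scattered
interpolation because it is exact at the electrode sites, smooth, globally
defined (no separate extrapolation step outside the convex hull), and is
the standard choice for EEG topographic maps. Constant maps normalize to
zero; the constancy test uses a relative `1e-9` span threshold so that
numerical noise in an analytically constant surface is not stretched to
full scale.

The stack has `Z = R * N_tau * N_bands` maps per trial (R = 2 feature
families), ordered deterministically: family first, then segment, then
band.

# The Deep-and-Wide classifier

Every topogram gets its own convolutional branch ("wide"): a 3x3 SAME
convolution with 2 filters and ReLU, per-channel batch normalization, and
2x2 max pooling to half resolution. The printed architecture lists pool
stride 1x1 together with a halved output size; the implementation uses
stride 2x2 because the output shape is load-bearing for every later layer.
Branch outputs are concatenated, flattened, batch-normalized, passed
through one fully-connected ReLU layer of `P'` units with an elastic-net
penalty and a max-norm (1.0) constraint, batch-normalized again, and read
out by a softmax layer (also max-norm constrained).

Training minimizes the mean squared error between the softmax output and
the one-hot labels — as specified, even though cross-entropy is the
conventional choice — with Adam (learning rate `1e-3`, batch size 256,
default 200 epochs), the elastic-net gradient `l1*sign(W) + 2*l2*W` on the
hidden weights, and a projection of each unit's incoming weight vector to
norm at most 1 after every update. Initialization is Glorot-uniform and
seeded; training is bit-reproducible for a fixed seed on one device.

Two numerical choices matter:

* **Batch-norm recalibration.** Running means/variances are tracked with
  momentum 0.99 during training, but with tens of epochs of full-batch
  updates they lag far behind the final parameters. After the last epoch
  the inference statistics are therefore recomputed in one pass over the
  training set. This also matters for transfer: without recalibration a
  fine-tuned network would keep the *source* subject's normalization
  statistics.
* **Fine-tuning learning rate.** Fine-tuning uses `0.3 x` the base
  learning rate by default (configurable), the usual practice to stay near
  the transferred initialization; with the full rate the fine-tuned
  solution drifts to the cold-start basin and the transferred information
  is lost. Zero fine-tuning epochs are exactly parameter copying. No
  layers are frozen.

Implementation note: the network is written in vectorized base R. The
convolutions are im2col matrix products; because the convolution is the
first layer, the im2col matrices are precomputed once per training set.
All branch activations live in one matrix with trials on columns, so batch
normalization and pooling vectorize across branches. The backward pass is
hand-derived and verified against finite differences in the test suite.

# Kernel matching and fusion

For the pooled trial set (J trials over M subjects) three feature matrices
are embedded with Gaussian kernels whose bandwidths follow the median
heuristic over strictly positive pairwise distances (zero distances are
excluded so that per-trial replicas of a subject's questionnaire row do not
collapse the bandwidth):

* `U` (`J x G`): the flatten-layer activations of each subject's trained
  network on its own trials;
* `V` (`J x Lambda`): predicted label probabilities. By default these are
  stratified K-fold validation predictions (the network predicting a trial
  never saw it), avoiding trivially overfit probabilities; plain in-sample
  predictions are available by configuration. The CSP stage *is* refit
  inside each fold; the wavelet maps are split-free and cached.
* `S`: per-subject questionnaire item scores, integer-encoded, z-scored
  per item (constant items dropped with a warning), replicated per trial.

A projection `Upsilon` (`G x G'`, default `G' = 50`) is learned by
maximizing the centered kernel alignment between the Gaussian kernel of
`U %*% Upsilon` and the kernel of `V`. The objective as printed contains no
projection; the implemented reading — align the kernel of the *projected*
features with the label-probability kernel — is the only one in which
`Upsilon` appears in the objective. Optimization is gradient ascent from a
PCA initialization with backtracking line search, so the objective trace is
non-decreasing up to `1e-6`; the projected kernel's bandwidth is
re-estimated every iteration and treated as a constant inside each gradient
(the envelope-style approximation is exact at convergence of the line
search and keeps the gradient closed-form).

The EEG and questionnaire embeddings are fused by the entrywise (Hadamard)
product, which is exactly the kernel of the tensor-product feature space
and preserves positive semi-definiteness by the Schur product theorem.
Optionally the fused kernel is reduced by kernel PCA (double-centering,
eigendecomposition with a `1e-12` eigenvalue floor, scores `v_k
sqrt(lambda_k)`) and re-embedded with a Gaussian kernel.

# Subject similarity and source selection

The fused (or KPCA re-embedded) `J x J` kernel is reshaped to `M x J` by
averaging each subject's trial rows. From the squared-Euclidean distance
matrix between subject profiles, the *neighboring similarity* is the sample
covariance (normalizer `1/(M-1)`; the constant is irrelevant to rankings
but fixed for reproducibility) between subject rows, with both rows ordered
by decreasing baseline accuracy. The ordering is one shared permutation —
the reading consistent with preserving neighbor structure — and the
covariance is therefore invariant to which shared permutation is applied,
which the tests verify. The marginal domain distance of a subject is the
mean absolute neighboring similarity over all subjects, self term included
(a configurable exclusion is provided).

Subjects are grouped into three BCI-skill tiers by deterministic 1-D
k-means on baseline accuracy (centers initialized at the minimum, median
and maximum; with exactly three subjects each forms its own tier); manual
thresholds are accepted. Sources come from Group I, targets are Group III.
The single-source strategy picks the Group-I subject with the *largest*
marginal distance — as specified, even though the optimality of "largest"
is asserted rather than derived; the multi-source strategy takes the four
largest. On desk-scale cohorts Group I can be smaller than four; the
implementation then takes all of Group I, so the stated behaviour holds
whenever the cohort is large enough.

Multi-source pre-training concatenates the sources' topogram stacks and
trains one network on the union; single-source transfer reuses the
source's already-trained baseline network. Fine-tuning always runs on the
target's own training split, and the reported gain is fine-tuned test
accuracy minus the target's cold-start test accuracy on the identical
90/10 split.

# The synthetic cohort

Each trial is spectrally shaped `1/f` background noise on every channel
plus 10 Hz (mu) and 20 Hz (beta) sinusoids with random phase and mild
lognormal amplitude jitter on the sensorimotor channels (C3/P3 left,
C4/P4 right by default). From one second after trial onset the rhythm
amplitude over the hemisphere contralateral to the imagined hand is
attenuated by `1 - skill * 0.8` — event-related desynchronization modeled
as amplitude attenuation, which is the feature the pipeline exploits.
Higher skill yields deeper ERD and hence higher decodability; the noise
amplitude (4 in rhythm units) was fixed once so that a mid-skill subject
lands near 75% accuracy under the reference CSP + LDA decoder, placing the
default three-tier cohort (skills 0.95/0.85, 0.55/0.45, 0.15/0.05) on both
sides of typical BCI-inefficiency boundaries.

What the generator does *not* emulate: volume conduction from dipolar
sources (channels are conditionally independent given the rhythms), ocular
and muscular artifacts, non-stationary drifts, and inter-channel noise
correlation. Passing tests on this cohort therefore demonstrate that the
pipeline recovers the structure it assumes — lateralized band-power
differences — not that it handles every pathology of real EEG.

# Desk-scale problem sizes

The default experiment configuration used by the tests and by
`scripts/acceptance.R` runs the complete pipeline on the default cohort
(M = 6 subjects, 40 trials per class, 16 channels, 128 Hz, 6 s trials)
with 16x16 topograms, 40 training epochs, 2-fold validation predictions
for `V`, 10 CKA ascent iterations at `G' = 50`, and 15 fine-tuning epochs. These
sizes keep a full multi-seed experiment in the minutes range while leaving
every qualitative property intact; all of them are configuration fields,
and the full-scale values (40x40 maps, 200 epochs, 10 folds) remain the
package defaults for `feature_config()` and `train_config()`.

# Known limitations

* With eight test trials per subject (10% of 80), per-subject test
  accuracy is quantized in steps of 0.125; transfer gains on a single
  split are correspondingly coarse, which is why gain statements are made
  over multiple seeds.
* The MSE-on-softmax loss saturates more easily than cross-entropy; with
  very small hidden layers the optimizer can stall at the uniform output.
* The ordinal questionnaire encoding (integers, z-scored) is deliberately
  plain; richer categorical embeddings are out of scope.
* `epsilon`, the domain-distance threshold appearing in the transfer
  formulation, is retained in the configuration for completeness but never
  instantiated operationally — selection uses the marginal distance
  ranking only.
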