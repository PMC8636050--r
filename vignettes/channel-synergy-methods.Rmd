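---
title: "Channel-synergy movement prediction from surface EMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-synergy movement prediction from surface EMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(synergynet)
```

## The problem

Paraplegic users of a lower-limb exoskeleton cannot produce reliable leg
sEMG, but their upper-limb muscles show movement-specific co-activation
while they brace on crutches during the two-second *movement-preparation
posture* that precedes each movement. `synergynet` classifies that
preparation-period activity — 12 channels of upper-limb surface EMG sampled
at 1500 Hz, arranged so channel $k$ and channel $k + 6$ are left/right
mirror muscles — into one of four intended lower-limb movements: sit,
stand, walk, or upstairs.

## Processing pipeline

Each trial is notch-filtered at 50 Hz (second-order IIR biquad, $Q = 30$)
and band-passed to 10–450 Hz (4th-order Butterworth), both applied
forward–backward for zero phase with reflection padding, once per trial and
before segmentation so window boundaries see no filter transients. The
preparation period is cropped using the trial's annotation, then segmented
into 200 ms windows (300 samples) advancing by 100 samples; a trailing
remainder shorter than one window is discarded. Only the corner frequencies are fixed by the acquisition protocol; filter
order, type, and the zero-phase realization are this package's explicit
(and configurable) choices.

Class imbalance (walking has twice the trials) is handled by
inverse-frequency class weights, $w_c = \max_k n_k / n_c$, so the majority
class has weight exactly 1.

## The network

For a window $X \in \mathbb{R}^{C \times L}$:

1. **Channel-wise LSTM.** Each channel's scalar sequence runs through its
   own LSTM with hidden size $H$; the final hidden state is that channel's
   timing-feature row, giving $F_{temp} \in \mathbb{R}^{C \times H}$.
   Mirror channels $(k, k+C/2)$ share one LSTM's weights (shared storage,
   so tying is exact at every training step). The hidden size is set to
   $H = L = 300$ and the final hidden state is the 300-length feature row;
   the alternative of using per-timestep scalar outputs is rejected
   because a scalar output sequence cannot supply a 300-dimensional
   feature per channel while keeping $F_{temp}$ of size $C \times L$.
2. **Temporal + depthwise convolution.** $F_1$ filters of size
   $(1, 65)$, same-padded, yield $F_1$ maps of size $C \times H$; a
   depthwise convolution of size $(C, 1)$ with depth multiplier $D$
   collapses the electrode axis into $F_2 = D F_1$ spatiotemporal channels.
   $F_2$ is fixed to $D F_1$ because the separable block must preserve
   size.
3. **Separable convolution.** Per-channel depthwise $(1, 15)$ kernels,
   same-padded, followed by $F_2$ pointwise $(1,1)$ filters mixing
   channels.
4. **Channel attention.** Average- and max-pooling over the length axis
   give two $F_2$-vectors; a shared two-layer perceptron (hidden size
   $F_2 / r$, ReLU) maps both, and
   $w = \sigma(\mathrm{MLP}(avg) + \mathrm{MLP}(max))$ gates the channels.
   The reduction $r$ is a free parameter; the default is $r = 4$.
5. **Head.** Flatten and a dense softmax over $N = 4$ classes.

ELU follows every convolution. There is no batch normalization, dropout,
or pooling layer — none is part of the architecture description. Defaults
are $(D, F_1, L) = (2, 12, 300)$, $H = 300$.

Two reference baselines share the training loop: a two-convolution network
(the temporal and depthwise stages straight on the raw window, then
softmax) and a hybrid with two stacked per-channel LSTM layers followed by
the temporal, depthwise, and separable-depthwise stages. Their remaining
widths are only loosely constrained; the choices here (hidden 300 in both
LSTM layers, no pointwise mixing in the hybrid's third convolution) are
documented package decisions.

### Training

Adam at its default hyperparameters minimizes class-weighted cross-entropy
for a fixed epoch budget (1000 at full scale); each batch is 10
*temporally consecutive* windows from one trial, with trial order shuffled
between epochs. After every epoch the validation loss is computed and the
weights with minimum validation loss are returned ("validation stopping").
Initialization is uniform Glorot for convolution/dense weights, orthogonal
per gate for LSTM recurrent matrices, forget-gate bias 1 — all fixed by a
seed, and the whole loop is reproducible bit-for-bit given that seed.

The forward/backward core is hand-written C++ (RcppArmadillo), templated
on the element type: training runs in single precision; gradient
verification runs in double precision against central finite differences
on a tiny configuration ($C=2$, $L=16$, $H=8$, $F_1=2$, $D=1$), agreeing
to better than $10^{-4}$ relative error.

## Classical baselines

Per window and channel: mean absolute value, waveform length,
zero-crossing count (dead band $\varepsilon = 0$ by default; real sEMG
practice often uses a small positive threshold, so it is configurable),
six Burg autoregressive coefficients (sign convention
$x_t \approx \sum_j a_j x_{t-j}$), and the mean Welch PSD over 10–450 Hz
(Hann window, 128-sample segments, 50% overlap — all pinned so the
Parseval test constrains the estimator). Classifiers: LDA (full covariance
within-subject, diagonal cross-subject), a decision tree capped at 100
splits, kernel-density Naive Bayes (an "RBF-kernel" Naive Bayes, realized as
Gaussian kernel densities per feature),
linear SVM ($C=1$) and RBF SVM ($C=1.9$), both one-vs-one, 1-NN with
Mahalanobis metric (implemented as pooled-covariance whitening followed by
Euclidean 1-NN), and a 28-unit single-hidden-layer network. All use the
inverse-frequency class weights; because those weights are exactly
inverse-frequency, the weighted empirical prior is uniform, which is how
the prior-based learners (LDA, Naive Bayes) receive them.

## Evaluation protocols

Splits are **always at the trial level**: with a 100-sample stride,
adjacent windows overlap by two thirds, so window-level splitting would
leak test content into training. Within-subject: a stratified 7:3
trial split per subject, with 4-fold cross-validation folds over the
training 70% used for validation stopping; accuracy is reported on the
held-out 30%. Cross-subject: 3 training subjects vs 2 validation subjects
per repetition, 10 repetitions by default. Results tables carry per-cell
accuracies plus mean and two standard errors. Repeated-measures ANOVA is
out of scope; the two-standard-error bars serve the same descriptive role.

The ablation study retrains, on *identical* splits and seeds (verified by
a split hash), the full network and three variants: depthwise removed
(replaced by a parameter-free channel average so downstream shapes hold),
separable removed (depthwise output feeds attention directly), and
attention removed (separable output feeds the flatten directly). All
reconciliations are parameter-free so the comparison isolates the removed
computation.

## Synergy analysis

Muscle synergies appear as non-negative channel loadings. The package
rectifies an activation map (absolute value; sEMG and layer activations
are signed while NMF requires non-negative input), averages it over the
windows of one class, and factorizes it with rank-1 multiplicative-update
NMF (the Frobenius objective is asserted non-increasing at every
iteration). Channels whose basis loading exceeds $\tau = 0.5$ of the
maximum are "dominant". Information flow is then traced through the
weights: each depthwise filter is scored by the fraction of absolute
weight mass on the dominant channels, filters strictly above the
per-layer median form the flow set, the same screening is applied to the
pointwise mixing matrix, and the final flow set is compared (Jaccard
index) with the top quartile of attention weights. Thresholds are explicit
configuration because "large weight" is inherently a qualitative
criterion.

## The synthetic cohort

No recordings ship with the package; a generator stands in for the
acquisition experiment with planted ground truth. Each channel is
amplitude-modulated band-limited Gaussian noise — the standard
interference-pattern surrogate for surface EMG: per-class non-negative
loadings (a primary mirror pair at 1.0, a secondary pair at 0.7, baseline
0.15) scale a trapezoidal envelope (0.2 s ramps over the 2 s window)
multiplying a 20–450 Hz unit-variance carrier; mirror channels share a
carrier component with weight 0.5; 50 Hz mains (amplitude 0.2) and a white
noise floor (0.05) are added. Per-subject log-normal loading jitter
(sd 0.1) emulates across-subject muscle compensation. Trial counts default
to the acquisition design: 10 per movement and 20 for walking. All
randomness derives from one master seed through named per-subject,
per-trial substreams.

What the simulator does *not* emulate: motor-unit firing statistics,
electrode lift artifacts, crutch-force coupling, non-stationary fatigue
drift. Passing tests on this cohort therefore show that the pipeline's
machinery — filtering, segmentation, learning, ablation bookkeeping,
synergy recovery — behaves correctly on signals with the stated structure;
they do not certify the accuracies reported on real recordings, which
require the original dataset.

## Desk-scale study sizes

The experiments the package runs in its tests and acceptance script use a
**compact profile** (`mcsnet_compact_config()`): hidden size 48, temporal
kernel 25, separable kernel 9, with every block, the channel count, the
300-sample window, $F_1 = 12$ and $D = 2$ unchanged. On a single CPU core
one forward+backward pass over a 10-window batch costs about 0.2 s, so the
following problem sizes complete a full study in minutes:

* *End-to-end learning*: one subject, 6 trials per class, windows strided
  by 300 samples, 100 epochs — 12 training trials (120 windows), validated
  on one CV fold, tested on the held-out 30%. Fewer trials or sparser
  striding leave the network overfitting trial-specific carrier noise even
  though the classes stay trivially separable by channel energy, so this
  is the smallest cohort on which training is meaningful. The chance-level
  control trains on trial-shuffled labels (shuffled before splitting, so
  stratification still sees every class) for 30 epochs — a null model's
  accuracy does not depend on its epoch budget.
* *Ablation*: five subjects, 2 trials per class, stride 600, 30 epochs,
  3 seeds, one cross-subject repetition per seed, at a further narrowed
  width (hidden 32, kernels 15/7) so all four conditions train to
  convergence; under-trained comparisons are dominated by how fast each
  variant converges rather than by what it can represent.
* *Synergy analysis*: dominant-channel recovery uses five one-subject
  cohorts (2 trials per class, no loading perturbation); the
  attention-versus-flow comparison reuses the end-to-end models (real and
  label-shuffled), averaged over the four classes.

These sizes were chosen as the smallest cohorts on which the planted
structure is comfortably learnable (the pilot criterion being validation
accuracy, not the downstream test thresholds). The architecture's
*default* configuration remains the full-width one; the compact profile
exists so that training-based checks are routinely runnable.

## Numerical and degenerate-input decisions

* Same-padding is symmetric zero padding; kernels must be odd.
* Attention max-pool ties break to the first index (backward routes the
  gradient there).
* ELU derivatives are recovered from the activation value ($y + 1$ for
  $y \le 0$), avoiding pre-activation caches.
* NMF divisions are guarded by $10^{-12}$; a zero row yields zero loading,
  and an all-zero weight row in flow tracing scores mass fraction 0.
* Constant signals: AR features warn and return zeros; zero windows
  produce zero features rather than errors.
* The zero-crossing dead band treats exact zeros as non-crossings for any
  $\varepsilon \ge 0$.

## Known limitations

* The weights-only information-flow statistic is weaker than the
  qualitative account it formalizes: on these synthetic cohorts the
  attention-versus-flow Jaccard agreement of well-trained models does not
  separate from that of label-shuffled control models (the acceptance
  suite computes exactly this comparison). The four planted class
  synergies share channels, so depthwise filters serve several classes at
  once and their class-specific weight-mass fractions carry little signal,
  while the attention gate selects globally useful channels. The
  dominant-channel NMF recovery, by contrast, is robust.

* Accuracies on the synthetic cohort say nothing quantitative about real
  sEMG; accuracies on real recordings can only be established on real
  recordings.
* The LSTM reading (final hidden state as feature row) and the baseline
  widths are design decisions among several defensible alternatives.
* Single-precision training is deterministic on a fixed BLAS but not
  bit-portable across BLAS implementations.
* The kernel-density Naive Bayes is $O(n_{train})$ per prediction and is
  the slowest classical baseline at scale.
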