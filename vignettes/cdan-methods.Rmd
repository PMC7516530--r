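---
title: "Conditional domain-adversarial decoding of motor-imagery EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional domain-adversarial decoding of motor-imagery EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cdaneeg)
```

## The problem

A motor-imagery (MI) brain-computer interface asks a user to imagine a
movement (left hand, right hand, feet, or rest) and decodes the imagined
class from multichannel EEG.  The physiological signal is class-specific
band-power modulation: imagining a hand movement attenuates the mu/alpha
(~10 Hz) and beta (~20 Hz) rhythms over the contralateral sensorimotor
cortex (event-related desynchronization, ERD), while rest shows the
opposite, idling pattern.  Decoders trained on one person transfer poorly to
another: electrode impedances, skull geometry and background spectra differ
enough that the feature distributions shift between subjects, so a
classifier fitted on other people's trials degrades on a new user.

This package treats the new user as an *unlabelled target domain*: labelled
trials from the other subjects form the source domain $D_s =
\{(X_i^s, y_i^s)\}_{i=1}^{n_s}$, the new subject's unlabelled trials form
$D_t = \{X_j^t\}_{j=1}^{n_t}$, with each trial $X \in \mathbb{R}^{c \times
t}$ (channels x samples).  Training aligns the two feature distributions
adversarially so the source-trained classifier works on the target subject
without any target labels.

## The model

Three subnetworks are trained jointly.

**Feature extractor** $G(\cdot;\theta_f)$, a densely connected ConvNet:

1. *Spatio-Temporal block* — a 1x1 convolution projects the $c$ physical
   channels to `n_proj` (default 35) virtual channels, learning spatial
   dependencies in the spirit of CSP spatial filters; a temporal convolution
   (kernel `k_temporal` = 25 samples, per virtual channel) learns frequency-
   selective filters; a spatial convolution (kernel 1 x `n_proj`) collapses
   the virtual channels; ELU; max pool (3, stride 3).
2. *Dense-Conv block* — a 1x1 convolution, a temporal convolution (kernel
   `k_dense` = 11), then the block's input and output feature maps are
   stacked along the map axis (the densely connected shortcut, which gives
   gradients a direct path to the earlier layers); max pool (3); flatten; a
   fully connected layer to the feature vector $f \in \mathbb{R}^{d_f}$
   (default $d_f = 512$).

Every convolution is followed by batch normalization and dropout.  Within a
unit the order is conv -> batch norm -> activation -> dropout; convolutions
are valid (no padding) with stride 1, pools have stride equal to their size.
These orderings, the map counts (25/25/50), dropout rate 0.5 and batch-norm
momentum 0.1 are choices of this package — the method's description fixes
only the kernel sizes, the 35 virtual channels, and where dropout and
normalization appear.  We also apply ELU after the Dense-Conv block
convolutions (`elu_dense = TRUE`): the architecture's description places an
ELU explicitly only after the spatial convolution, but is silent about
activations inside the Dense-Conv block, and the Deep ConvNet family it
descends from activates every convolutional unit.  In practice the
band-power features that separate MI classes are second-order in the signal,
and a network with a single ELU underfits badly at the reduced sizes used in
our tests; the switch is exposed so the stricter reading remains available.

**Classifier** $C(\cdot;\theta_c)$: a two-layer fully connected network
(hidden width 256, ELU) with a softmax over the $C = 4$ classes, giving
$p = C(f)$.  The method's description gives the classifier "256 input units"
while selecting $d_f = 512$ for the extractor output in its hyperparameter
study; the two are never reconciled.  We follow the hyperparameter study for
the default ($d_f = 512$) and keep both configurable; with `d_f = 256` the
stated classifier geometry is reproduced exactly.

**Conditional domain discriminator** $D(\cdot;\theta_d)$: a fully connected
network with one sigmoid output scoring "source vs target" (source labelled
1, target 0).  Its input is the *multilinear map*

$$h = f \otimes p, \qquad h_{(i-1)C + j} = f_i \, p_j,$$

so that domain alignment is conditioned on the classifier's belief: the
joint distribution of features and predicted classes is aligned, not the
marginal feature distribution.  The probability vector entering $h$ is
*detached*: the discriminator loss never backpropagates into the classifier,
matching the update rules in which only $\theta_d$ and $\theta_f$ learn from
$L_d$.  The ablations are `"dan"` (discriminator on raw $f$ — no
conditioning) and `"cdan1"` ($h$ but no entropy weights).

## Losses and training

With cross-entropy classifier loss $L_c$ on the source batch, prediction
entropy $H(p) = -\sum_c p_c \log p_c$ and the transferability weight

$$w(H) = 1 + e^{-H} \in (1, 2],$$

the discriminator loss is the weighted binary cross-entropy

$$L_d = -\mathbb{E}_s \, w(H(p^s)) \log D(h^s)
        -\mathbb{E}_t \, w(H(p^t)) \log (1 - D(h^t)),$$

averaged within each domain and summed.  Confidently classified trials get
weights near 2 and dominate alignment; maximally uncertain ones get ~1.25.
The weights are treated as constants in the gradient.  The full objective is
the minimax

$$L(\theta_f, \theta_c, \theta_d) = L_c(\theta_f, \theta_c)
  - \lambda \, L_d(\theta_f, \theta_d),$$

with trade-off $\lambda = 0.6$ by default, held fixed over training (no
annealing schedule: the method presents $\lambda$ as a single
hyperparameter).  The alternating min/max updates are realised by a
*gradient reversal layer* between $h$ and the discriminator: the forward
pass is the identity; in the backward pass the gradient flowing from $L_d$
into the extractor is multiplied by $-\lambda$.  One combined update per
iteration then implements

$$\theta_c \leftarrow \theta_c - \alpha \partial L_c / \partial \theta_c,
  \quad
  \theta_d \leftarrow \theta_d - \alpha \partial L_d / \partial \theta_d,
  \quad
  \theta_f \leftarrow \theta_f - \alpha \left(
     \partial L_c / \partial \theta_f
     - \lambda \, \partial L_d / \partial \theta_f \right).$$

The test suite verifies on a quadratic toy that this simultaneous form
agrees with the explicit alternating updates to first order in the learning
rate, and by central finite differences that the reversed gradient equals
$-\lambda$ times the unreversed one.

Optimisation is mini-batch SGD with momentum 0.9 and the inverse-decay
learning rate $\alpha = \alpha_0 (1 + u\tau)^{-\beta}$ with $\alpha_0 =
0.01$, $u = 10$, $\beta = 0.75$, where $\tau \in [0,1]$ is training
progress.  Per iteration one source batch and one equally sized target batch
are drawn (batch composition is our choice; the method does not state it).
Training stops at the configured iteration budget.  Non-finite losses abort
with a diagnostic rather than continuing silently.

### Batch normalization across domains

Batch-norm *running* statistics are tracked separately for the source and
target domains, and each domain is evaluated under its own statistics
(training always uses the current batch's statistics, so this changes no
gradient).  The reasoning: with a strong domain shift, a single running
average is a mixture that mis-normalizes both domains at evaluation time —
we observed training losses improving while evaluation accuracy sat at
chance before making this choice, which follows established
domain-adaptation practice (AdaBN / domain-specific BN).  The target
statistics derive only from unlabelled target batches, so no label
information is involved; a source-only model has no target statistics and
evaluates everything under the source ones.  `predict_proba(...,
domain = "auto")` uses target statistics when they exist (the trained model
serves the target subject), and `domain = "source"` is used for
source-domain diagnostics.

### Input standardization

The method's description is silent on input normalization.  We standardize
each channel to zero mean and unit variance with statistics fitted on the
source training set, frozen, and reused for all target data (`standardize`
switch in `train_config()`).  Frozen source statistics mean that target
channel-gain shifts remain visible to the network — removing them per-domain
would silently solve part of the adaptation problem outside the model.

### Seeds and determinism

One integer seed determines everything.  Internally it derives two
independent RNG streams: the source stream (parameter initialisation of
extractor and classifier, source batch sampling, source-side dropout) and
the target stream (discriminator initialisation, target batch sampling,
target-side dropout).  Because a `lambda = 0` adversarial run adds exactly
zero gradient contributions and consumes only target-stream draws for its
target side, its extractor/classifier trajectory is *bitwise identical* to
the source-only run with the same seed — an executable decoupling check in
the test suite.  All pipelines rerun with the same seed reproduce their
outputs bitwise on a single-threaded CPU.

## The synthetic EEG generator

Testing adaptation needs multi-subject data with a known ground truth, so
the package ships a generator (`synthetic_spec()`, `generate_pool()`) that
emulates the relevant statistics of MI EEG:

* **Background**: $1/f^{\gamma}$ noise per channel (default exponent 1,
  RMS 6 uV), generated by spectrally shaping white Gaussian noise.
* **Rhythms**: narrowband sources (10 Hz alpha/mu, bandwidth 2 Hz; 20 Hz
  beta, bandwidth 4 Hz) as band-pass filtered Gaussian noise.  Filtered
  Gaussian noise has a Rayleigh-distributed envelope, so rhythm amplitude
  waxes and wanes in bursts, as real sensorimotor rhythms do — trial band
  power is stochastic by design, not a fixed constant per class.
* **Class structure**: each source carries per-class power multipliers.
  The default 8-channel, 4-class layout places alpha and beta sources on
  left, right, central and posterior channel pairs; hand classes attenuate
  the contralateral sources to 25% power (alpha) and 40% (beta), feet
  attenuate the central ones, rest raises alpha to 130% (idling).
* **Domain shift**, applied per subject in the order gain -> spectral tilt
  -> additive noise: log-normal per-channel gains (sd 0.4), a random
  spectral-tilt exponent (sd 0.3, pivoted at 10 Hz), and extra white sensor
  noise (mean 4 uV RMS, log-normal sd 0.5).  These sizes were chosen once to
  produce the kind of transfer failure the method targets: a band-power
  classifier fitted on pooled source subjects loses well over ten accuracy
  points on a held-out subject (a property-style test asserts the drop).

Default conditions: 100 trials per class per subject, 8 channels,
500 samples at 125 Hz (4 s trials), 4 classes.  The generator does **not**
emulate volume conduction between channels, eye/muscle artifacts,
within-session nonstationarity, or realistic electrode geometry; passing
tests on synthetic pools therefore demonstrates that the adversarial
machinery works as specified, not that any particular accuracy will be
reached on real recordings.

## Scaled-down study conditions

The experiments the package runs on itself (test suite and
`scripts/acceptance.R`) use a reduced instance of the architecture sized for
a single CPU: trials cropped to their first 2 s with `crop_window()` (the
post-cue interval carries the ERD; 2-s windows are standard in MI decoding),
8 virtual channels, 8/8/16 feature maps, $d_f = 32$, classifier hidden width
32, discriminator hidden width 32, dropout 0 (at these widths dropout 0.5
removes too much of an 8-map representation; the full-size default remains
0.5), batch size 32 per domain, and a 200-iteration budget with 3 source
subjects and one held-out target (`adaptation_study()`).  Kernel lengths,
pools, losses and schedule keep their defaults.  The conditional variants
run at the standard $\lambda = 0.6$; the unconditional `dan` ablation runs
at $\lambda = 0.15$, because at 0.6 its discriminator reliably drives this
scaled-down extractor into the degenerate domain-invariant optimum —
features collapse to constants, the classifier returns to chance — which is
precisely the failure mode that motivates conditioning the discriminator on
the class posterior.  At 0.15 the unconditional adversary adapts stably and
the expected ordering source-only < DAN $\le$ CDAN emerges.

The interpretability validation (`sign_recovery_study()`) trains a
two-class decoder on data whose class 1 carries elevated 10 Hz power on a
known channel pair, then checks that the alpha-band map is positive on that
pair.  Three measurement choices matter there: (i) with only two classes,
$h = f \otimes p$ carries little more than $f$ itself, so the adversary
behaves like the unconditional one and the study uses $\lambda = 0.3$;
(ii) the map is taken on source-domain trials, where the trained decoder is
accurate enough for its responses to carry signal; and (iii) it correlates
on the logit scale with amplitude-noise sd 30 — a confident softmax is
saturated, so probability deltas under small perturbations sit at numerical
noise, while logit deltas stay linear in the input change.

## Interpretation: perturbation correlation maps

`correlation_map()` quantifies which electrodes and bands drive the
decisions of a trained model.  For a frequency band, every trial is
Fourier-transformed per channel, i.i.d. Gaussian noise (mean 0, sd 1) is
added to the amplitudes of the bins inside the band (amplitudes clipped at
zero, phases kept, conjugate symmetry maintained), and the signals are
transformed back.  The per-channel summed amplitude change is then Pearson-
correlated, across trials and repeats, with the change in each class
probability.  Conventions chosen here (the procedure's description leaves
them open): "prediction change" means the pre-argmax class probability, one
map per class; amplitudes are magnitudes of the full-trial FFT; correlation
is Pearson's r on trial-wise summed deltas.  Zero-variance channels or
outputs yield r = 0 with a flag rather than NaN.  Maps are arrays plus
electrode names; topographic drawing is left to plotting layers.

## Evaluation harness

`evaluate_model()` reports accuracy, macro-averaged precision and recall
(percentages), macro F1 (fraction) and the confusion matrix (macro
averaging is our choice; micro/macro is not specified in the method's
tables).  `compare_variants()` trains any subset of
{source_only, dan, cdan1, cdan} across seeds (and across left-out subjects
when given a pool) and tabulates per-run source and target accuracies.
`sweep_param()` implements the cross-validation protocol for hyperparameter
choice: the last 20% of source trials (chronological) form the validation
set, adaptation still uses the unlabelled target training set, and one row
per parameter value is reported.

## Numerical choices

* Batch-norm epsilon $10^{-5}$; biased batch variance; running statistics
  updated with momentum 0.1.
* Discriminator scores are clamped to $[10^{-12}, 1 - 10^{-12}]$ inside the
  loss to avoid infinite logs in saturated regimes.
* He-scaled normal initialisation for all weights, zero biases.
* Max-pool ties break toward the earliest window position.
* The densely connected shortcut crops `(k_dense - 1) %/% 2` samples from
  each side of the block input so input and output maps align in time
  before stacking.
* `signal::resample()` (polyphase, anti-aliased) backs `resample_trials()`;
  the rational factor is reduced to lowest terms first.

## Known limitations

* Desk-scale synthetic experiments only: the headline accuracies of the
  full-scale study (High Gamma Dataset, GPU training of the full-width
  network) are out of reach here and are not reproduced.
* The unconditional `"dan"` ablation is fragile at small scale: with a
  strong adversary it can collapse features to a domain-invariant but
  class-uninformative solution — precisely the failure that multilinear
  conditioning was introduced to fix.  See the variant-comparison settings
  in `scripts/acceptance.R`.
* No artifact rejection, montage interpolation or ICA cleaning; inputs are
  assumed pre-epoched and cue-locked.
* Reading BBCI/HGD `.mat` containers directly is not supported (no Matlab
  I/O dependency); convert externally to the package's RDS/JSON container
  (`write_trials()` documents the schema) and apply the standard chain
  `select_channels()` (44 motor electrodes) -> `crop_window(-0.5, 4,
  cue_index)` -> `resample_trials(250)`.
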