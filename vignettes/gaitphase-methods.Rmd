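---
title: "Continuous gait-phase estimation with an interpretable patch-token transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous gait-phase estimation with an interpretable patch-token transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lower-limb exoskeletons that assist walking need to know *where in the gait
cycle* the wearer is, continuously: the cycle is parameterised as a phase
from 0 to 100% between successive initial-contact events of the same foot.
`gaitphase` implements a complete pipeline for estimating that phase from
multimodal wearable sensors — inertial measurement units (joint angles,
angular velocities, accelerations), surface EMG and knee stretch sensors —
with a transformer whose attention weights double as a channel-importance
measure, so that sensor configurations can be pruned rather than stacked
blindly.

```{r setup, message = FALSE}
library(gaitphase)
```

## Labels: stride segmentation and circular encoding

Foot pressure is the labelling signal, never a model input. The pressure
series is smoothed with a centered moving average (default 15 samples at
100 Hz; the window shrinks at the record edges rather than padding, so no
pressure values are fabricated), and its strict local maxima — subject to a
minimum peak distance (default 50 samples, half a second, comfortably below
any stride at treadmill speeds) and a topographic prominence of at least 10%
of the smoothed range — mark initial contacts. Between consecutive peaks the
phase ramps linearly from 0 to (just below) 100. Samples before the first
and after the last peak carry no stride context and are flagged invalid
rather than extrapolated.

Because 0% and 100% are nearly the same posture, phases are regressed on the
unit circle: a phase `p` becomes the pair `(sin, cos)(2*pi*p/100)` and
predictions are decoded with `atan2`, wrapping negative angles. Squared
error in label space therefore never penalises the wrap. The round trip is
exact to machine precision:

```{r}
p <- seq(0, 99.99, length.out = 7)
cartesian_to_phase(phase_to_cartesian(p))
```

Windows are `M` channels by `L = 100` time steps (one second at 100 Hz),
advanced one step at a time, each labelled with the phase at its **last**
sample — the causal convention, matching what a real-time controller can
see. EMG natively sampled at 2000 Hz is brought onto the common clock by
zero-phase Butterworth low-pass filtering followed by decimation
(`downsample_channel()`); raw decimation behind an anti-alias filter was
chosen over RMS-envelope extraction as the more conservative reading of
"downsampled", and the envelope is easy to add upstream since the generator
and windowing are agnostic to channel content.

## The model

Each channel's window is cut into `L/P` non-overlapping patches of length
`P = 10`, linearly projected into `d` dimensions by a projection shared
across channels, prefixed with a **per-channel learnable token**, offset
with a learnable positional table, and passed through `N` post-norm
transformer encoder layers (`a = LN(x + MHA(x))`, `out = LN(a + FFN(a))`,
GELU feed-forward expanding to `4d`). The per-channel tokens are kept
channel-specific even though the patch projection is shared: without them,
two channels with similar content would be indistinguishable to the
cross-attention stage and the importance weights would be meaningless.

The encoded token (row 0) of every channel forms an `M x d` matrix that a
single learnable global query token pools via dot-product cross-attention —
as printed, one attention call with no residual or feed-forward around it.
The per-head softmax rows over channels are the **channel importance
weights**; a two-layer MLP maps the pooled feature to the `(sin, cos)`
prediction, with no output activation (targets lie on the unit circle,
predictions need only point in the right direction).

Two points where the printed equations were under-determined:

* The attention-scale line sets `d_k = d`, which is dimensionally
  inconsistent with concatenating `h` heads of width `d/h`. The default is
  the standard per-head scaling `sqrt(d/h)`; `scale_by_full_d = TRUE`
  honours the literal reading.
* Pre-norm variants are common in practice, but the equations print
  post-norm, so post-norm is what `encoder_layer()` computes.

Dropout (rate 0.1 on the two sub-layer outputs) exists for training only and
is never active in evaluation mode, so every reported forward pass is
deterministic.

The publication-scale configuration (`d = 768`, 12 heads, 6 layers) is
expressible but all bundled experiments use reduced configurations
(`d` 16–64, 1–2 layers) that train on one CPU core in minutes; the tests and
the acceptance script state their exact sizes.

## Training and evaluation

Adam on mean-squared label error, batch 32. The protocol defaults
(`learning rate 4e-6`, 200 epochs, 7:3 split) are kept as `train_config()`
defaults; the reduced synthetic experiments override them (typically
`1e-3` for 10–15 epochs) because a small model on clean synthetic data
converges several orders of magnitude faster than a 768-dimensional model on
five participants' noisy recordings.

With stride-1 windows, a random 7:3 split would place near-duplicates of
training windows in the test set, so the default split is **chronological
with an overlap gap**: the first `ceiling((L - 1) / stride)` held-out
windows are discarded, guaranteeing train and test windows share no time
steps. Random splitting
stays available behind `split_mode = "random"` for fidelity comparisons.
Channels are z-scored with training-partition statistics stored in the
checkpoint.

Evaluation decodes predictions to phase and stratifies by the **true** phase
into the four reporting bins — pre-stance (0–30%), post-stance (31–60%),
pre-swing (61–80%), post-swing (81–100%) — computing RMSE and R² per bin
with plain linear differences. Deliberately *not* circular: an estimate of
99.8% against a truth of 0.1% counts as an error of ~99.7 phase units. This
reproduces the characteristic boundary behaviour of this reporting
convention (large pre-stance/post-swing errors, occasionally negative per-bin
R²) even when the circular fit is excellent; the interior bins (post-stance,
pre-swing) are the faithful measure of tracking quality.

## The synthetic generator

Human treadmill recordings are not distributable with this package, so
`synthetic_spec()`/`generate_recording()` produce recordings with a known
ground-truth phase: strides of configurable mean length and uniform length
jitter, and channels of four kinds —

* `kinematic-sinusoid`: two phase-locked harmonics with a channel-specific
  offset (an idealised joint-angle/gyro trace);
* `emg-burst`: rectified white noise gated by a von-Mises-like envelope
  centred at a phase offset (defaults: one burst near 40%, push-off; one
  near 90%, swing);
* `stretch-ramp`: a smoothed piecewise-linear rise-and-fall (a knee-like
  flexion trace);
* `noise`: white noise, carrying no phase information by construction.

Foot pressure is a smooth pulse peaking exactly at each stride boundary.
The `snr` field is the amplitude ratio `sd(signal)/sd(noise)` of added
Gaussian noise, with `snr = 0` meaning the noise-free limit (no noise
added); defaults are 20 for kinematic/stretch and 10 for EMG channels,
roughly the regime of well-placed sensors. What the generator does **not**
emulate: soft-tissue artifacts, sensor drift, cross-talk between EMG
electrodes, inter-subject variability, or non-stationary cadence. Passing
tests therefore demonstrate the pipeline's correctness and the
architecture's mechanics, not clinical performance on human data.

## Channel attribution and its failure mode

On a six-channel task (three phase-informative channels, three white-noise
channels) a small trained model assigns higher mean cross-attention weight
to the informative channels. This property is **convergence-dependent**, and
the package's experiments document an instructive failure mode: in
under-trained models (too few windows or epochs), attention mass drifts
onto *noise* channels. The mechanism is visible in the token statistics —
a white-noise channel's encoded token is nearly constant across windows
(patch averaging washes the noise out), so it acts as a stable "readout
rail" whose softmax coefficient, modulated by the informative channels'
keys, can carry phase information without the noise channel contributing
any content. Whether a run escapes that plateau depends on the weight
initialisation, and the two outcomes are separated by an order of magnitude
in final training MSE (converged runs sit near 1e-4 on the clean task,
stalled ones above 0.1). `train_restarts()` therefore retries from fresh
derived initialisation seeds until the training loss reaches a target
(default 0.05) — the same logic as `nstart` in k-means, judged on training
loss alone. The bundled attribution experiment uses ~1,500 windows, 12
epochs at learning rate 2e-3, and up to three restarts; with a converged
model the informative-channel tilt is decisive (informative channels
typically hold over 80% of the attention mass). The interpretability
functions should only be trusted on models trained to convergence.

## Channel selection arithmetic

From a 34-channel base registry (16 IMU, 16 EMG, 2 stretch;
`standard_channel_registry()` lists the exact names), four fused 16-channel
configurations are built from a weight report: IMU+EMG takes the top 8 per
modality; Stretch+EMG and IMU+Stretch take both stretch channels plus the
top 14 of the other modality; IMU+Stretch+EMG takes 2 + 7 + 7. Ties break
lexicographically so selections are deterministic.

## Baselines

Five classical families share the transformer's forward contract
(`M x L` in, 2 out): a dual-branch CNN (kernel sizes 5 and 3, three
conv/ReLU/average-pool blocks per branch), four-block LSTM and GRU stacks of
width 128, and CNN+LSTM / CNN+GRU hybrids (three conv blocks into three
recurrent blocks). All are trained with the same optimizer and loss. Like
the transformer, they are implemented with hand-written backward passes
validated by finite-difference tests.

## Numerical choices

* Attention softmax is computed with row-max subtraction; every attention
  row must sum to 1 within 1e-6 (asserted in tests).
* Layer norm uses population variance with epsilon 1e-5.
* GELU uses the standard tanh approximation.
* Initialisation: truncated normal (sd 0.02) for tokens and the positional
  table, uniform fan-in for linear maps; all seeds explicit.
* Peak detection ties (equal-height peaks inside one exclusion distance)
  resolve in favour of the earlier-scanned taller peak; exact weight ties in
  channel selection resolve lexicographically.
* `r2()` refuses constant truth vectors rather than returning NaN; bins with
  fewer than two evaluation windows report `NA` metrics.

## Known limitations

* The synthetic task is far easier than human data; reduced models reach
  interior-bin RMSE well under 1 phase unit on it, which says nothing about
  the RMSE achievable on real recordings.
* Attention-weight attribution is correlational; the package deliberately
  implements no gradient-based saliency.
* Training is single-threaded CPU; the publication-scale configuration is
  supported but not practical to train here.
* Real-time streaming (FIFO window updates, actuator control) is out of
  scope; the pipeline is offline.
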