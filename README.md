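# gaitphase

Continuous gait-phase estimation from multimodal wearable sensors, with an
interpretable patch-token transformer.

## The problem

Active lower-limb exoskeletons need a continuous estimate of where the
wearer is in the gait cycle — a phase from 0 to 100% between successive
initial contacts of the same foot — to time their assistance. The phase can
be estimated from wearable sensors (IMUs on the thighs/shanks/trunk, surface
EMG over tibialis anterior and gastrocnemius, stretch sensors over the
knees), but naively stacking sensor channels inflates computation without
improving accuracy, and classical sequence models (CNN/LSTM/GRU) give no
insight into which channels matter.

`gaitphase` implements an end-to-end pipeline around a transformer designed
for exactly this problem:

* **Labels** come from a foot-pressure signal: smoothed with a moving
  average, its local maxima mark stride boundaries, and phase ramps linearly
  0→100 between them. Phase `p` is regressed on the unit circle as
  `y = (sin 2πp/100, cos 2πp/100)` and decoded with `atan2`, so the 0/100
  wrap never inflates the training loss.
* **The model**: each channel's 100-step window is cut into ten 10-step
  patches, linearly embedded, prefixed with a learnable per-channel token,
  and encoded by post-norm transformer layers
  (`a = LN(x + MultiHead(x)); out = LN(a + FFN(a))`, GELU feed-forward of
  width 4d). A learnable global token pools the encoded channel tokens with
  cross-attention — `Weights = softmax(QKᵀ/√d_k)` — and those weights are
  per-channel **importance scores**. An MLP head emits the two-component
  prediction.
* **Interpretation**: `channel_weights()` aggregates the cross-attention
  weights over evaluation windows, `attention_scope()` averages encoder
  self-attention maps (by default the last 3 layers × last 6 heads), and
  `select_top_channels()` / `build_fused_source_specs()` turn a weight
  report into the four fused 16-channel sensor configurations (8+8 IMU+EMG,
  2+14 for the two stretch pairings, 2+7+7 for all three modalities).
* **Baselines**: CNN, LSTM, GRU, CNN+LSTM and CNN+GRU families with the same
  windows-in, `(sin, cos)`-out contract.
* **Synthetic data**: because the underlying human recordings are not
  public, `synthetic_spec()`/`generate_dataset()` produce stride-periodic
  multimodal recordings (kinematic harmonics, phase-gated EMG bursts,
  knee-like stretch ramps, pure-noise channels, and a pressure pulse train)
  with exact ground-truth phase, so every stage is testable end to end.

The transformer, its backward pass, and all baselines are implemented in
this package (vectorised R with RcppArmadillo attention kernels) and
validated against scalar nested-loop oracles and finite-difference
gradients.

## A worked example

```r
library(gaitphase)

# six synthetic channels: three phase-informative, three pure noise
channels <- tibble::tibble(
  name     = c("kin_a", "kin_b", "stretch_a", "noise_a", "noise_b", "noise_c"),
  modality = c("IMU", "IMU", "STRETCH", "EMG", "EMG", "EMG"),
  kind     = c("kinematic-sinusoid", "kinematic-sinusoid", "stretch-ramp",
               "noise", "noise", "noise"),
  phase_offset = c(0, 30, 0, 0, 0, 0),
  snr = 0)                       # snr = 0: noise-free limit

spec <- synthetic_spec(n_strides = 16, stride_len_mean = 100,
                       channels = channels, seed = 101)
ds  <- generate_dataset(spec, window_len = 100, stride = 1)

cfg <- ptt_config(n_channels = 6, window_len = 100, patch_len = 10,
                  embed_dim = 32, n_heads = 4, n_layers = 1, dropout = 0)
fit <- train_restarts(cfg, ds,
                      train_config(batch_size = 32, learning_rate = 2e-3,
                                   epochs = 12, seed = 1))

evaluate_per_phase(fit, ds)          # held-out chronological split
channel_weights(fit, ds[fit$split$test])
```

(`train_restarts()` retries from fresh initialisation seeds if a run stalls
on the optimisation plateau described in the methods vignette; here the
first attempt converges.) The evaluation table stratifies held-out windows
by true phase into the four reporting bins (pre-stance 0-30%, post-stance
31-60%, pre-swing 61-80%, post-swing 81-100%):

```
# A tibble: 5 x 4
  bin             n   rmse     r2
  <chr>       <int>  <dbl>  <dbl>
1 pre-stance     93 17.9   -3.02
2 post-stance   103  0.193  1.000
3 pre-swing      80  0.181  0.999
4 post-swing     76  0.225  0.998
5 overall       352  9.22   0.896
```

Interior bins track the phase to a fraction of a percent. The large
pre-stance RMSE is the boundary effect of the reporting convention: errors
are measured with plain differences, so a prediction of 99.8% against a
truth of 0.1% counts as ~99.7 phase units even though the circular error
is 0.3. The channel-weight report on the same fit:

```
# A tibble: 6 x 4
  channel   modality mean_weight sd_weight
  <chr>     <chr>          <dbl>     <dbl>
1 kin_a     IMU           0.400    0.0968
2 kin_b     IMU           0.348    0.0303
3 stretch_a STRETCH       0.180    0.0561
4 noise_a   EMG           0.0265   0.0129
5 noise_b   EMG           0.0235   0.0105
6 noise_c   EMG           0.0231   0.00983
```

The three informative channels hold ~93% of the attention mass; the noise
channels are correctly ignored. `autoplot()` on either result draws the
standard figures, and `build_fused_source_specs()` applies the selection
arithmetic to a full 34-channel report.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/gaitphase.R simulate --strides 20 --seed 1 --out rec.csv
Rscript inst/cli/gaitphase.R label    --input rec.csv --out labels.csv
Rscript inst/cli/gaitphase.R pipeline --out-dir run1 --seed 1
```

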