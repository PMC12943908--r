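# stridekit

Stride-length estimation from foot-mounted inertial sensors, for gait
analysts and wearable-sensing engineers who need per-stride spatial
parameters from a 50 Hz accelerometer log plus pre-detected gait-event
indices.

## What it implements

Walking acceleration is noisy and carries large heel-strike transients, so
naive double integration of a stride's acceleration drifts badly. `stridekit`
implements a processing-and-estimation pipeline:

1. **Preprocessing** — db4 wavelet denoising (multilevel orthogonal
   decomposition, universal-threshold soft shrinkage) followed by a
   five-point local cubic least-squares smoother whose interior stencil is
   the classical `[-3, 12, 17, 12, -3]/35` and whose signal ends use derived
   one-sided stencils.
2. **Modified Kalman filter** — a three-state filter, x = [p, v, a]ᵀ
   (displacement, velocity, acceleration), with constant transition
   A = [[1, Δt, 0], [0, 1, Δt], [0, 0, 1]], measurement model
   z = Hx + v, H = [0 0 1], and gain K = P̄Hᵀ(HP̄Hᵀ + R)⁻¹. Two gait-specific
   modifications: the effective R is rescaled for a few samples after each
   acceleration zero-crossing (transient gain regulation around gait
   events), and a sign-consistency rule keeps the reported displacement
   from reversing sign between adjacent samples. Per-stride length is
   |p_end − p_start| with the filter reinitialized at each stride start.
3. **LSTM regressor** — a single 50-unit LSTM layer plus linear readout,
   trained with Adam/MSE, dropout and early stopping on per-stride
   segments (raw or filtered) against reference lengths; implemented in
   base R with BPTT verified against numerical gradients.
4. **Synthetic gait generator** — quasi-periodic strides with exactly known
   per-stride displacement, configurable Gaussian sensor noise and
   zero-net-area heel-strike rings, so the whole pipeline is testable
   without human data.

Estimates are scored with the absolute relative error
|actual − predicted| / |actual| (reported as ratio and percent) and with
MAE / MSE / RMSE / R².

## Worked example

```r
library(stridekit)

walk <- generate_walk(synth_gait_config(n_strides = 20, seed = 42))
est  <- estimate_stride_lengths(walk$seq$az, walk$events, mode = "mekf")
error_summary(walk$true_lengths, est)
```

```
<metrics_report> n = 20
  mean_error     0.0564954
  sd_of_errors   0.104194
  min_error      0.00172495
  max_error      0.49041
```

Mean relative error is 0.056 (5.6 %) over the 20 strides. The maximum,
0.49, is the record-initial stride: the first stride of any record lacks
left context for the denoiser, so its heel-strike ring is only partially
suppressed — excluding it the errors sit in the 0–7 % range. The filter
itself is a classed object with the usual methods:

```r
pre  <- cubic_smooth(wavelet_denoise(walk$seq$az))
seg2 <- segment_strides(pre, walk$events)[[2]]
fit  <- run_mekf(seg2$samples, filter_config())
fit
#> <mekf> 47 samples filtered (dt = 0.02 s)
#>   boost: factor 10 for 3 samples at 4 zero-crossings; sign rule on
#>   final state: p = 1.2002 m, v = 0.1284 m/s, a = -3.5653 m/s^2
plot(fit)                       # measured vs filtered, states
stride_length_from_states(fit)  # 1.200184 m for this stride
```

A three-way experiment (raw double integration vs plain EKF vs modified
EKF) is one call per mode:

```r
cfg <- default_pipeline_config(seed = 1)
run_pipeline(cfg, mode = "mekf")$metrics
```

and the LSTM route is `prepare_sequences()` → `stride_lstm()` →
`predict()`. A thin command-line front end
(`exec/stridekit simulate|filter|train|predict|evaluate|run`) wires the
same functions to files.

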