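---
title: "Methods: multimodal tactile classification of frost-damaged fruit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal tactile classification of frost-damaged fruit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(graspfusion)
```

## The problem and the approach

Freeze injury degrades fruit pulp (water-soaked, translucent, mechanically
weakened tissue) before any visual symptom appears on the peel, so damaged
fruit cannot be sorted by imaging alone. A robotic gripper that squeezes
each fruit under closed-loop force control can instead sense the damage
mechanically, through two complementary tactile modalities inspired by
cutaneous mechanoreception: a 6x6 pressure-matrix sensor records the
quasi-static spatial load distribution (~20 Hz), and a piezoelectric film
records transient vibration during contact loading (~200 Hz). Both are
digitised as 10-bit ADC counts.

`graspfusion` implements the complete analysis around this sensing scheme:

1. a generative simulator of labelled grasp trials (`simulate_grasp_dataset()`),
2. signal preprocessing into fixed 50-step model inputs (`preprocess_dataset()`),
3. a dual-branch single-block Transformer fusion classifier with
   single-modality ablations and RNN/CNN/LSTM baselines (`graspnet()`),
4. a repeated stratified-split evaluation protocol (`repeat_protocol()`), and
5. residual-aware attention-rollout temporal attribution
   (`attribute_dataset()`).

## The simulator: what it emulates, and what it does not

No public grasp recordings exist for this task, so the package ships a
generative model whose defaults encode the acquisition protocol it
emulates: fingers close at 50 mm/s, load to a 20 N set-point, hold for 5 s,
then release; 120 fruit per class; fruit diameter drawn from
Normal(73.54, 3.41) mm truncated to [66.31, 81.34] mm.

Each trial is produced by an explicit mechanical model:

* **Force ramp.** After contact at `t0` (slightly earlier for larger
  fruit), grip force follows `F(t) = 20 (1 - exp(-(t - t0)/tau))` N over a
  1 s loading window, is clamped at 20 N during the hold, and ramps down
  linearly at release. The time constant `tau` is the stiffness surrogate:
  soft (frost-damaged) tissue loads more slowly.
* **Pressure footprint.** Cell counts follow a Gaussian spatial footprint
  (weights normalised to sum 1) scaled by `gain * F(t)` on top of an
  8-count baseline, quantised and clipped to [0, 1023]. The footprint
  spread is larger for damaged tissue at contact; during the hold both
  classes creep towards a common redistribution spread (time constant
  0.8 s), so the hold phase is deliberately almost uninformative.
* **Vibration.** A 512-count midpoint plus a sub-5 Hz sinusoidal drift, a
  damped sinusoid transient at contact (`A e^{-zeta omega t} sin(omega_d t)`),
  Poisson-timed micro-transients during loading, and white noise.
  Frost damage lowers the transient frequency, raises damping, and raises
  the micro-event rate.

Class offsets (at `effect_size = 1`: `delta_tau` = 0.10 s, `delta_sigma` =
0.35 grid units, `delta_freq` = 15 Hz, `delta_damping` = 0.04,
`delta_event_rate` = 6 Hz) are scaled by `effect_size` and multiplied by
per-fruit lognormal jitter (10% SD) for biological variability. Two
consequences are built in by design: the pressure modality carries the
stronger cues (the offsets were chosen so a pressure-only classifier beats
a vibration-only one), and all discriminative structure is concentrated at
contact onset and early loading — ramp shape, footprint spread before
creep, transient envelope, micro-events — mirroring where a grasp is
physically informative.

At `effect_size = 0` the two classes are distributionally identical by
construction, which provides an exact null for calibration checks.

The simulator does **not** model contact mechanics (no FEM), thermal
effects, sensor calibration drift, cross-talk between cells, fruit pose
variation, or heterogeneous (partial) frost injury. Passing tests on
synthetic data therefore demonstrate that the pipeline recovers signal
that is present and stays at chance when it is absent — not that real
fruit are this separable.

## Preprocessing

Raw trials become 50x36 pressure and 50x1 vibration sequences through a
fixed pipeline (`build_model_input()`), with these choices where the
acquisition chain leaves room:

* **Grasp segmentation.** Contact onset is the first frame whose summed
  pressure exceeds the leading-baseline mean by 5 baseline SDs; release is
  detected symmetrically from trailing frames. The baseline window is the
  first/last 6% of frames (`onset_baseline_frac`): with a ~0.5 s approach
  inside a ~7 s trial at 20 Hz, a longer window would overlap contact and
  contaminate the baseline statistics.
* **Temporal denoising** is a centred moving average (window 3,
  shrunken at the edges): linear-phase, simple, and exactly testable.
* **Resampling** is linear interpolation onto 50 uniform points over the
  detected segment; endpoints are preserved exactly.
* **Pressure normalisation** is one min-max over all 50x36 entries of the
  trial. Per-channel scaling was rejected because it would destroy the
  spatial load pattern that the pressure modality is meant to carry.
* **Vibration filtering** is a causal single-pass second-order Butterworth
  high-pass (30 Hz cutoff, bilinear design with prewarping at the nominal
  200 Hz rate) applied after mean removal; gain at the cutoff is 1/sqrt(2)
  and the DC gain is zero. Zero-phase (forward-backward) filtering was
  rejected: it squares the cutoff gain and is acausal.
* **Vibration amplitude** is z-scored per trial after resampling. Only the
  length standardisation is inherited from the acquisition description;
  the z-score is this package's addition for optimiser conditioning.
* **Conventions.** Channels are flattened row-major (`p00..p05, p10..p55`);
  one-hot labels are `normal = [1, 0]`, `frost_damaged = [0, 1]`.

## Network architecture

Each modality branch is a single-block Transformer encoder in pre-LN
residual form,

```
Y = Dropout(LN2(X + MHA(LN1(X)))),
```

with fixed sinusoidal positional encoding added to the normalised input,
two attention heads of key dimension 32, output projection back to the
modality width, and dropout 0.3. The pre-LN residual ordering is the one
arrangement consistent with both the listed layer sequence (LN, MHA, LN,
dropout) and the presence of a residual connection around the attention
sub-layer.

Two details are this package's decisions:

* **Layer-norm axis.** Feature-axis statistics are degenerate for the
  width-1 vibration branch — every time step would normalise to the shift
  parameter, erasing the signal. Layer normalisation therefore uses
  feature-axis statistics when the modality width is > 1 and time-axis
  statistics when it is 1.
* **Positional encoding at odd width.** The unpaired trailing column uses
  the sine term; at width 1 the encoding is simply `sin(t)`.

Branch outputs are concatenated (50x37), flattened (1850), and classified
by dense-64 (ReLU) / dropout / dense-64 (ReLU) / softmax-2. Single-modality
ablations keep one branch and attach the same head to its flattened
output. The RNN/CNN/LSTM baselines are fixed, capacity-comparable designs
(per-modality encoders of 32 units — simple recurrent, 1-D convolution
with 32 filters of kernel 5 plus global average pooling, LSTM — feeding the
identical head); they exercise the comparison protocol rather than
reproduce any particular published baseline.

The flatten-1850 head makes the fusion model ~132k trainable parameters.
The architecture description this reimplements quotes a much smaller
count, which no straightforward reconstruction of the stated layers
yields; the achieved count is recorded in every fitted object
(`fit$n_params`) and in run metadata, and is treated as non-binding.
Dropout is applied once per branch (after LN2) and once in the head; none
is applied inside the attention weights.

All forward and backward passes, and the Adam optimiser, are implemented
in vectorised base R and verified against central finite differences for
every architecture (relative error < 1e-3 on sampled coordinates; see
`test-network.R`).

## Training and evaluation protocol

Training uses Adam (learning rate 0.001, batch size 16), categorical
cross-entropy, at most 300 epochs, and early stopping on validation loss
with patience 20; the best-validation checkpoint is restored before
evaluation. Ties: only a *strict* decrease in validation loss resets the
patience counter. One run seed controls the split, parameter
initialisation, batch shuffling and dropout, and is logged in the result.

Data are split 7:2:1 by stratified sampling (floor allocation plus
largest-remainder top-up, ties resolved in train/validation/test order —
exact at 120 per class: 84/24/12). The protocol repeats over 10 seeds;
every model kind sees byte-identical subsets per seed, and metrics
(accuracy, per-class precision/recall/F1 from the 2x2 confusion matrix)
are aggregated as arithmetic mean and sample SD (n-1). Per-run metrics are
averaged across runs (not pooled confusion counts). Zero-denominator
metric cases return 0 with a warning flag rather than NaN.

## Temporal attribution

For each sample and branch, the per-head post-softmax attention maps are
averaged (`average_heads()`), residual-adjusted and row-normalised —
`(A_bar + I)/2` for a row-stochastic input (`residual_adjust()`) — and
rolled out across layers by matrix product (`attention_rollout()`; with a
single block the rollout *is* the adjusted map). The temporal score
`s(t)` is the mean incoming attention to step `t` over all query
positions (column means), which sums to 1 exactly. Profiles are min-max
normalised per sample (epsilon 1e-8), fused across branches by
equal-weight averaging, and summarised by the peak step `t*`
(argmax, ties broken to the earliest index) and a fixed-width interval
histogram (default width 5 steps, i.e. 10 bins over 50 steps — the width
is a display choice and configurable). Attention is always extracted in
inference mode (dropout off). Heatmap export is numeric-first (per-sample
fused profile rows in `attributions/profiles.csv`); profiles are
normalised per sample, so heatmaps are comparable in shape, not absolute
scale. Attribution is a post hoc description of model emphasis, not a
causal statement.

## Numerical choices and degenerate inputs

* Layer-norm variance guard 1e-5; min-max and z-score guards 1e-8
  (constant inputs map to zero rather than NaN); cross-entropy log guard
  1e-12.
* Softmax rows subtract the row maximum before exponentiation.
* Constant attribution profiles give `t* = 0` via the earliest-index rule.
* A trial whose summed pressure never crosses the contact threshold raises
  `"no contact detected"` rather than producing an arbitrary segment.

## Problem sizes used by the shipped analyses

The package's own test-suite and acceptance analyses run at the emulated
study scale — 240 trials, 10 repeated splits — with training capped at 60
epochs (default-effect recovery) and 40 epochs (null calibration); early
stopping typically halts well before the cap. These caps are the package's
chosen analysis sizes; the protocol defaults (300 epochs, patience 20)
remain available for larger studies.

## Known limitations

* Synthetic-data conclusions transfer to real recordings only insofar as
  the generative model captures the relevant physics; the simulator's
  non-goals above list what it omits.
* The vibration branch operates on a heavily subsampled (50-step) view of
  a 200 Hz signal; most spectral content above ~8 Hz of the standardised
  timeline is aliased away by design, as in the emulated pipeline, so the
  branch mainly sees envelope and early-transient shape.
* Attention-rollout attribution on a single block is a linear summary of
  one attention layer; it does not account for the value pathway or the
  classification head.
* The RNN/CNN/LSTM baselines are reasonable fixed designs, not tuned
  competitors; their numbers contextualise the protocol rather than rank
  architectures definitively.
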