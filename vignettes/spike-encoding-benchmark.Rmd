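---
title: "Benchmarking spike encodings of time-varying signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking spike encodings of time-varying signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikebench)
```

## The problem

A spiking neural network consumes discrete, timestamped events, while
microphones, accelerometers and most other commodity sensors produce
uniformly sampled continuous signals. The translation step — spike
encoding — is not innocuous: different algorithms preserve different
features of the signal (amplitude, change, latency, phase), emit wildly
different numbers of spikes, and therefore condition both the energy cost
and the achievable accuracy of whatever spiking classifier sits
downstream. `spikebench` implements a complete, reproducible pipeline for
quantifying these trade-offs on two regimes of time-varying data: a
mid-frequency audio-like regime (spoken-digit-style mono recordings at
8 kHz) and a very-low-frequency inertial regime (tri-axial wearable
traces at 20 Hz).

The stages are: cochlea-inspired frequency decomposition, spike encoding,
sonogram feature extraction, supervised training of a constrained CNN,
conversion of that CNN into a leaky integrate-and-fire (LIF) twin,
evaluation of the twin on Poisson-encoded inputs, and optional synaptic
pruning with masked fine-tuning. Each stage is exposed as ordinary R
functions so any sub-pipeline can be exercised on its own.

## Filter bank

The cochlea decomposes sound along the basilar membrane into overlapping
frequency channels; the standard engineering analogues are gammatone and
Butterworth band-pass banks, both provided here.

* **Gammatone** (default order 4): center frequencies are equally spaced
  on the Glasberg–Moore ERB-rate scale between `f_low` and `f_high`, the
  conventional choice in auditory modelling. Each filter is realized as a
  truncated-impulse-response FIR (`t^{n-1} e^{-2\pi b t}\cos 2\pi f_c t`)
  normalized to unit gain at `f_c`. The nominal bandwidth
  `b = 1.019\,\mathrm{ERB}(f_c)` is capped at `0.8 f_c`: the ERB scale is
  calibrated for audio frequencies, and without the cap a sub-10-Hz bank
  (the inertial regime) would degenerate into low-pass filters whose
  response no longer peaks at the center frequency. The contract is the
  location of the magnitude peak, not a particular filter realization.
* **Butterworth** (default order 2): `[f_low, f_high]` is partitioned
  into contiguous bands with logarithmically spaced edges (constant edge
  ratio), matching the cochlea's log-frequency organization; the nominal
  center of each band is the geometric mean of its edges.

Both banks are applied forward–backward (zero phase). Since sonogram bins
downstream are only tens of milliseconds wide, per-channel group delay
would systematically skew event times between low and high channels; zero-
phase filtering removes that artifact at the cost of a non-causal filter,
which is irrelevant for offline benchmarking. Default bands are
100–3800 Hz for 8 kHz audio and 0.1–9.5 Hz for 20 Hz inertial data, both
Nyquist-bounded.

## The eleven encoders

All encoders process channels independently, are deterministic (Poisson
excepted, which takes a seed), use *strict* inequalities at thresholds —
so a constant signal produces no events — and support a refractory period
`tau_ref` enforced by dropping any event closer than `tau_ref` to the
previously retained event on the same channel. With `tau_ref = 0` the
unconstrained train is returned unchanged.

**Poisson rate.** Values are interpreted as rates; inter-spike intervals
are drawn by inversion, `ISI_i = -\log(1 - x_i)/r`, and cumulated until
the encoding interval `\Delta t` is exhausted, which realizes the Poisson
count law `P_n(\Delta t) = (r\Delta t)^n e^{-r\Delta t}/n!`. For matrix
input each sample is a rate held over its `dt` bin; by memorylessness the
generator restarts independently at each bin boundary, which is exact.

**Threshold-based representation (TBR).** Per channel, the threshold is
`mean(\Delta S) + \gamma\,sd(\Delta S)` over the *signed* first
differences with the population standard deviation — the formula as
printed, applied literally. A spike of polarity `sign(\Delta S_i)` is
emitted where `|\Delta S_i|` strictly exceeds the threshold. `\gamma`
widens the noise-rejection band: 0 keeps every variation above the mean,
values above 1 suppress noisy channels.

**Moving window (MW).** Emission compares the signal itself (not its
variation) against a sliding baseline: the mean of the previous `window`
samples, initialized as the mean of the first `window` samples. Here the
threshold uses the mean *absolute* variation: on oscillatory signals the
signed mean is approximately zero, which would degenerate the noise band
to nothing. This deviation from the TBR statistic is deliberate and
recorded in the train's metadata. The window length is nowhere fixed by
convention; the default is `L/10`, configurable.

**Step-forward (SF).** The baseline starts at the first sample and steps
by ±threshold on every emitted spike, tracking the signal like a delta
modulator. The threshold is `mean(jump)/\gamma` where `jump` is each
channel's peak-to-peak range and the mean runs over channels — a single
shared threshold, as the defining formula states. Without the baseline
update rule SF would collapse onto MW with a frozen base, so the
Kasabov-style step tracking is used.

**Zero-crossing step-forward (ZCSF).** Inherits the SF threshold,
replaces the baseline with half-wave rectification: positive spikes only,
where `S_i > 0` and `S_i >` threshold.

**Deconvolution family (HSA / MHSA / BSA).** These invert the
reconstruction problem "convolve a unipolar spike train with a FIR kernel
to approximate the signal". Scanning left to right: HSA emits where the
signal segment dominates the kernel pointwise and subtracts the kernel;
MHSA softens the gate to an accumulated shortfall
`\sum_j \max(0, h_j - S_{i+j-1}) \le` threshold; BSA (Petro's variant)
emits where `\sum_j |S_{i+j-1} - h_j| \le \theta \sum_j |S_{i+j-1}|`,
default `\theta = 0.955`. The default kernel is a rectangular window of
width `max(2, \lfloor L/32\rfloor)` whose total mass equals the channel's
peak amplitude; a kernel whose *height* equaled the peak would render HSA
all but silent and make BSA reconstruction meaningless, so the mass
convention was chosen and is exposed as a parameter. A silent channel
yields no spikes rather than a degenerate all-zero kernel.
`reconstruct_deconv()` provides the inverse convolution for quality
checks.

**Phase encoding.** Per channel the signal is rectified and min–max
normalized to `[0, 1]`; each sample expands into `\beta` sub-steps
carrying its truncated binary fraction, one spike per 1-bit. Values below
the channel maximum are clipped into `[0, 1 - 2^{-\beta}]` so the
expansion is well defined; the maximum itself maps to the all-ones burst,
so the largest value produces the densest pattern.

**Time-to-first-spike (TTFS).** Each normalized value `v` crosses the
decaying membrane threshold `P_{th}(t) = \theta_0 e^{-t/\tau_{th}}`
(defaults `\theta_0 = 1`, `\tau_{th} = 0.1` s) at
`t^* = -\tau_{th}\log(v/\theta_0)` and emits one spike at the earliest
point of a uniform 64-point latency grid at or after `t^*`; `v = 0` never
crosses and latencies beyond the encoding interval are dropped. How a
whole sampled waveform (rather than a single stimulus value) should be
latency-coded is genuinely open; this per-sample global-latency scheme is
a reconstruction, as is the optional `bitwise` mode that expands each
value into a grid-spaced binary burst, and both are flagged as such in
the documentation and metadata.

**Burst encoding.** The normalized value controls both the spike count
`\lceil rate \cdot N_{max}\rceil` and, when more than one spike is
emitted, the inter-spike interval
`\lceil t_{max} - rate\,(t_{max} - t_{min})\rceil` in raster steps:
strong inputs give long, tight bursts. Defaults `N_{max} = 5`,
`t_{min} = 2`, `t_{max} = 10`.

## Characterization metrics

`metrics_record()` summarizes a train with five quantities. The raster is
rebuilt at the train's own `dt` with a ternary per-step alphabet
{−1, 0, +1} (sign of the net polarity), which treats bipolar and unipolar
encoders uniformly.

* **S** — Shannon entropy (bits/symbol) of the pooled symbol
  distribution; 0 for a silent train.
* **MIS** — mutual information between the raster symbols and the source
  amplitudes (discretized into `Q = 8` equal-width bins, repeated when the
  raster is finer than the sample grid), normalized by the symbol entropy;
  defined as 0 when the train is silent. Always in `[0, 1]`.
* **HS** — Hoyer sparsity of the per-channel binned counts,
  `(\sqrt{n} - \|x\|_1/\|x\|_2)/(\sqrt{n} - 1)`, averaged over channels;
  1 for one-hot, 0 for uniform, and 1 by convention for an empty channel.
* **ε** — spiking efficiency, one minus raster-slot occupancy,
  `1 - N/(n_{steps}\,c)`, clipped to `[0, 1]`.
* **density** — events per second, total and per channel.

The published definitions behind S, MIS and ε are not available in
computable form, so all three are reconstructions; the record carries a
`metrics_version` tag so downstream tables are comparable only within a
version. `complexity_label()` returns the per-algorithm asymptotic cost in
`l` (length), `c` (channels), `n` (bit depth) and `w` (kernel width).

## Sonograms

`time_bin()` counts events over non-overlapping windows into a
`channels × bins` image. Bins are half-open `[k w, (k+1) w)` with the
final boundary closed, so an event exactly at the end of the interval is
counted rather than dropped and the count sum always equals the event
count. Polarities are merged by default (`merged_abs`, a single image);
`two_plane` stacks positive over negative counts for bipolar encoders
where sign matters. `sonogram_to_rates()` rescales counts by the *global*
maximum into Poisson input rates, preserving inter-channel intensity
ratios — per-channel normalization would erase exactly the contrast the
classifier needs. Whether to merge or split polarities in the image is an
open choice; merging was chosen as the default because a single-plane
image matches the usual sonogram visualization, and the two-plane variant
is kept for sign-sensitive analyses.

## CNN training and the LIF twin

The classifier is a deliberately constrained CNN, `C{I}-C{J}-F{K}`:
conv(`I` maps) → average pool → conv(`J` maps) → average pool → `K`
fully-connected layers → softmax, with 3×3 kernels and 2×2 pools by
default. Three constraints make it convertible: every bias is identically
zero (not merely initialized to zero — it does not exist as a parameter),
pooling is average (realizable as a fixed uniform synaptic fan-in of
weight `1/p^2`), and the activation is a plain unit-slope rectifier with
an optional saturation cap. Under these constraints the network is
positively homogeneous: scaling any layer's weights by `\alpha > 0`
scales the logits monotonically and never changes the argmax. Training is
plain seeded SGD on softmax cross-entropy (implemented in-package with
im2col convolutions; gradients are verified against finite differences in
the test suite). Inputs are sonogram counts normalized by their global
maximum — the same scaling the SNN receives via the rate conversion.

`transfer_weights()` builds the spiking twin: identical topology, every
synaptic weight copied bit-exactly, LIF units with exponential leak
(`v \leftarrow v e^{-dt/\tau_m} + I`), hard reset on threshold crossing,
and Bernoulli input spikes at `rate \cdot dt` per step. Defaults:
`\tau_m = 20` ms, `v_{th} = 1`, `v_{reset} = 0`, `dt = 1` ms,
`T_{sim} = 0.5` s, peak input rate 500 Hz — values chosen for stable rate
coding at desk scale. Classification is the argmax of output spike
counts, ties broken toward the lowest class index.

Copied weights alone put each layer's operating point wherever the CNN's
activation scale happens to sit, so `threshold_balance()` rescales the
firing threshold of layer `l` by `\lambda_l/\lambda_{l-1}`, where
`\lambda_l` is a high percentile (default 0.9) of the layer's positive
activations pooled over a calibration set. By positive homogeneity this
leaves the predicted class untouched while placing every unit in its
linear rate-coding regime. Balancing on the *maximum* activation instead
is brittle: a single activation outlier inflates `\lambda`, deep layers
then fire at a few hertz, and the leak's dead zone swallows weak logits
entirely (observed as near-zero output counts for one class). The
percentile form is the standard data-based normalization used in
ANN-to-SNN conversion practice and is exposed as a parameter. Balancing
thresholds rather than rescaling weights was chosen deliberately so the
weight copy remains bit-exact.

## Compression

`prune_by_quantile()` pools `|w|` over both convolutions and the
fully-connected stack (pooling layers have no trainable synapses and are
exempt by construction), takes the linear-interpolation empirical
`q`-quantile as threshold, and removes every synapse with `|w| \le`
threshold — ties at the threshold go, which is why pruning all-equal
weights at the median removes everything. The pooled (global) scope
follows the idea of a single weight distribution; a per-layer scope is
available as an option. One boundary consequence of the `\le` convention
with an interpolated quantile: as `q \to 0^+` the threshold sits just
above the smallest magnitude, so that one synapse is still removed — the
convention cannot simultaneously remove ties and remove nothing in the
limit, and the tie behavior was judged the more important contract.
`fine_tune()` retrains the survivors for 5 epochs by default (10–20 is
also reasonable and configurable) with the mask re-applied after every
update, so eliminated weights are exactly zero at all times, including
after transfer to the twin.

## Synthetic corpora

The generators exist so that every stage, including end-to-end
classification, is testable without downloads.

* `gen_audio_like()`: each class is a fixed two-tone template with
  geometrically spaced fundamentals inside 500–2000 Hz (the mid-frequency
  band), a raised-cosine envelope, 10 % silence pads at both ends
  (emulating trimmed spoken-digit recordings), uniform random phase,
  ±10 % amplitude jitter and Gaussian noise (`noise_sd = 0.05` by
  default). Defaults: 3 classes × 20 samples, 0.25 s at 8 kHz.
* `gen_imu_like()`: tri-axial signals at 20 Hz cycling through three
  motion archetypes — gait-like oscillation (1–3 Hz fundamental plus
  harmonic), near-static posture, and impulsive bursts — with a constant
  gravity offset on the z axis and Gaussian noise (`noise_sd = 0.1`).
  Defaults: 3 classes × 20 samples, 10 s.

Class difficulty is controlled by template frequency spacing and
`noise_sd`; the defaults are set so the full pipeline separates the
classes while leaving headroom for regressions to be visible. What the
generators do **not** emulate: speaker variability, co-articulation,
reverberation, real biomechanics, sensor drift, or class imbalance.
Passing the pipeline's tests on these corpora demonstrates that the
machinery is correct and that the transfer/compression contracts hold; it
does not predict accuracy on real speech or activity data.

## Numerical choices and problem sizes

* Strict threshold inequalities everywhere (constant signals silent).
* Half-open raster and sonogram bins with the final boundary closed.
* Type-7 (linear interpolation) quantiles for pruning thresholds.
* Event lists sorted by time with ties broken by channel index; stable
  radix sort keeps duplicate (time, channel) events in generation order.
* Seeds: one global seed fans out into per-stage child seeds via a fixed
  integer recurrence kept below 2^31, so stages are individually
  reproducible.
* Degenerate inputs: silent channels encode to empty trains; empty trains
  have entropy 0, MIS 0, sparsity 1, efficiency 1; an all-zero sonogram
  maps to all-zero rates and classifies to class 1 by the tie rule.

The package's benchmark defaults are desk-scale: 3-class corpora of 60
signals, 16-channel banks, 16×20 sonograms, ~3000-parameter networks, and
0.5 s of simulated time per classification. A full
encoder × filter grid cell (encode, train, transfer, simulate) runs in
tens of seconds on one core; the shipped test suite and acceptance script
each complete in a few minutes.

## Known limitations

* The gammatone realization is FIR-truncated and zero-phase; it matches
  the magnitude-peak contract but not any specific published filter
  cascade.
* TTFS semantics for full waveforms, the exact MW window, the TBR/MW
  variation statistics and the S/MIS/ε formulas are reconstructions of
  under-specified procedures; all are flagged in metadata and exposed as
  parameters rather than hard-coded.
* The LIF twin uses Bernoulli thinning of Poisson rates at 1 ms
  resolution; sub-millisecond dynamics and conductance-based effects are
  out of scope.
* Training is plain SGD without augmentation or scheduling — adequate for
  the synthetic corpora, not tuned for real datasets.
* No spike-based learning (STDP, surrogate-gradient BPTT) and no
  neuromorphic-hardware deployment; the twin runs in-package only.
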