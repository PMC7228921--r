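---
title: "Reservoir computing with a volatile memristor: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reservoir computing with a volatile memristor: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memrc)
```

`memrc` simulates a reservoir-computing (RC) system whose reservoir is a
single volatile ("dynamic") memristor: a two-terminal device whose
conductance is raised by applied voltage and relaxes spontaneously back
toward its high-resistance state. The relaxation gives the device fading
memory on a ~100 ms timescale, which is what makes it useful for analyzing
neural spike trains: the device state at any moment is a nonlinear summary
of the recent spike history. Only a small readout layer is trained; the
reservoir itself is fixed physics.

This vignette documents the models, their parameters and units, and the
design decisions taken where the underlying experimental description left
choices open. Every empirical number quoted here is computed by the test
suite or by `scripts/acceptance.R`.

## 1. The device model

All times are in ms, voltages in mV, currents in nA. The device carries one
internal state variable $w \in [0, 1]$, the degree of conduction-channel
formation. Voltage drives channel growth through a `sinh` nonlinearity
(field-accelerated ion migration); the channel decays spontaneously with
time constant $\tau$:

$$\frac{dw}{dt} = \lambda_g \sinh(\eta V) - \frac{w}{\tau}.$$

The device current mixes channel conduction and background leakage,

$$I = w^{p}\,\gamma \sinh(\delta V)
    + (1 - w^{p})\,\mathrm{sgn}(V)\,\alpha\,(1 - e^{-\beta |V|}),$$

with a filament-area exponent $p$ on the state-to-conduction map. The model
is integrated by explicit Euler at `dt = 0.1` ms (stability bound
`dt <= tau/100`; halving `dt` changes reported currents by well under 0.5%).
The inner loop is compiled (Rcpp), so simulating the full 7200-group
synchronization protocol takes seconds.

### Calibration

`calibrate_memristor()` solves the free parameters against the measured
device contract, and `default_params()` holds the committed solution:

| quantity | target | role |
|---|---|---|
| HRS read at 30 mV | 0.003 nA (~1e10 ohm) | fixes `alpha` |
| LRS read at 30 mV | 3 nA (~1e7 ohm) | fixes `gamma` |
| relaxation time | 100 ms | fixes `tau` |
| current at end of 100 mV / 5 ms pulse | 20 nA | fixes `lambda_g` |
| energy of one 100 mV / 500 µs pulse | 50 fJ | fixes `p` |

The voltage nonlinearities (`eta` = 0.02, `delta` = 0.05, `beta` = 0.01 per
mV) are structural choices: they set how strongly programming (100 mV)
couples relative to reading (30 mV) and are held fixed during calibration.

Two consequences of this calibration are worth stating explicitly, because
they are forced by the mathematics rather than chosen:

* **The 500 µs programming pulse ends near 2 nA, with a mean current of
  ~1 nA.** Once $\tau = 100$ ms and the 5-ms response are fixed, the state
  ratio $w(5\,\mathrm{ms})/w(0.5\,\mathrm{ms}) = 9.78$ is locked for any
  single-exponential relaxation, so the final current of the short pulse
  cannot independently be 1 nA. The 50 fJ energy figure equals
  100 mV × 1 nA × 0.5 ms, i.e. it identifies ~1 nA as the pulse's
  *characteristic* (mean) current, which the calibrated model reproduces
  exactly; the package adopts that reading.
* **The pulse-width response is mildly sub-linear.** The current at the end
  of a 4-ms pulse is slightly *less* than twice that of a 2-ms pulse
  (16.05 vs 16.10 nA): conduction is near-linear in $w$ ($p \approx 1.011$)
  and $w(t)$ is concave under constant drive. The device's nonlinearity —
  what the RC system actually exploits — lives in the voltage couplings and
  in the state relaxation, not in pulse-width super-linearity.

Reads are non-perturbative: the physical −30 mV / 0.5 ms read pulses are
modeled as instantaneous queries of the conduction law at |30 mV| (read
charge is about three orders of magnitude below programming charge).
Optional multiplicative Gaussian read noise (`noise_rel`, default off, 2%
in the robustness tests) models measurement scatter; the experimental
device noise was not characterized.

## 2. Spike-train generators

Neural spikes are emulated as 100 mV / 2 ms square pulses inside labeled
windows (620 ms for pattern tasks, 900 ms for synchronization). The four
firing patterns follow fixed rules:

* **Tonic** — constant-interval pulses; per-train mean interval uniform in
  [60, 80] ms, individual intervals Gaussian with 5% relative SD; first
  spike at t = 0.
* **Bursting** — groups of 3–6 pulses, intra-group intervals Gaussian
  (10 ms, 10% SD); the next group starts one inter-group interval
  (per-train mean uniform in [100, 200] ms, 8% SD) after the *last onset*
  of the previous group (end-to-start convention; the start-to-start
  reading is equally consistent with the description, the end-to-start one
  was fixed here once).
* **Irregular** — 12-ms segments, each firing one spike at its start with
  probability 0.5. The canonical 620-ms window uses 50 segments (600 ms of
  segments and a 20-ms tail; `floor(620/12)` would give 51, but the stated
  protocol divides the train into 50).
* **Adapting** — first interval 6 ms; each subsequent interval grows by a
  Gaussian percentage with mean 30% and SD 5 percentage points,
  compounding on the realized previous interval.
* **Transition** — two distinct patterns in series, split point uniform in
  [0.25, 0.75] of the window; the boundary is kept in `meta$split_ms`.

Jitter draws are truncated Gaussians (resampled below the pulse width), so
generated trains always satisfy the container invariants: strictly
increasing onsets, no overlapping pulses, everything inside the window.

Synchronization groups use bursting trains. In-phase neurons share one
burst skeleton with 1 ms timing jitter (10% of the intra-burst interval —
the description says only "a standard deviation of 10%"); anti-phase
neurons are shifted round-robin by 1/n of the burst period; no-phase
neurons are independent. Two generator-level choices matter here:

* **Random start phase.** Burst rhythms start at a uniformly random phase
  rather than with a burst at t = 0. The window alignment is not specified
  by the generation rules; phase-locking every train to its window start
  (a) lets the readout exploit an artifact that does not exist for sliding
  windows over a stream, and (b) gives "uncorrelated" no-phase neurons a
  spurious coincident first burst.
* **What a green test establishes.** A no-phase window whose two
  independent rhythms happen to lock for 900 ms is genuinely
  indistinguishable from in-/anti-phase; the three classes overlap and
  100% accuracy is not attainable even in principle. Held-out accuracy is
  ~87–88% at the 7200-group protocol scale.

## 3. Reservoir and readouts

The read current is sampled every 20 ms (`t = 20 n` ms), giving 31 virtual
nodes per 620-ms window and 45 per 900-ms window. Features are scaled to
[0, 1] by a *global* min–max fitted on the training split only — a single
lo/hi pair, not per-column, so that scaling commutes with sliding a window
along the node axis.

Three readouts are trained by full-batch gradient descent on a one-vs-all
sigmoid cross-entropy ("logistic regression"), with seeded uniform
initialization in [−0.1, 0.1] and argmax decisions (ties to the lowest
class index). A softmax output is available behind
`train_config(output = "softmax")` but is not the default; in the streaming
task it sharpened per-window decisions and *increased* false transition
flags.

| task | architecture | committed optimizer |
|---|---|---|
| pattern recognition | FC 31×4 | lr 2, 4000 epochs |
| streaming (5 classes) | conv 27×1, stride 1 → 5×5 perceptron | lr 2, 30000 epochs |
| synchronization (3 classes) | conv 6×2, stride 2 → 20×3 perceptron | lr 2, 40000 epochs |

The committed learning rates and epoch counts were chosen so that training
loss is non-increasing (monotone full-batch descent) and validation
accuracy has plateaued; at lr = 5 and above the conv readouts oscillate.
The convolution layer uses exactly one shared kernel — the stated feature
map sizes (31→5 with k = 27, 45×2→20 with k = 6, stride 2) only work with a
single filter — and sigmoid hidden activation, consistent with the
logistic-regression training rule.

## 4. The three experiments

**Pattern recognition** follows the protocol exactly: 1600 trains
(400/pattern), each simulated from the fully relaxed device (w = 0),
stratified 80/20 split, FC readout. Clean simulation reaches ~99% held-out
accuracy — comfortably above the ~87% experimental figure, as expected for
a noise-free simulator; with 2% read noise enabled the accuracy drops by
well under 10 points.

**Streaming transition detection** trains the 5-class conv readout on 2000
labeled 620-ms trains and then classifies 31-node sliding windows (hop one
node = 20 ms, so each window spans exactly 620 ms of history) over a long
concatenated stream simulated on one continuously running device. Windows
whose span crosses a segment boundary are scored as transitions (bands one
window wide); a boundary's detection is the first window after it whose
argmax is the transition class. Two training-data decisions resolve the
cold-start/warm-device mismatch that the protocol leaves open:

* training responses are collected *continuously* — the 2000 trains are fed
  back-to-back through one device in seeded shuffled order, because a
  physical device in a streaming deployment is never reset; and
* half of each pure class's trains are two independent same-pattern draws
  in series ("splice" augmentation), still labeled as the pure pattern, so
  that a re-draw of the same pattern inside a window is not mistaken for a
  transition. This cut false transition flags on single-pattern streams
  roughly fourfold.

Long evaluation streams are built by tiling canonical 620-ms pattern
windows, so that e.g. an adapting segment shows repeated adaptation events
rather than one event followed by seconds of silence.

With these choices every true boundary in the evaluation stream is
detected within one window length of the boundary. What the trained system does **not** achieve is zero false
transition flags on single-pattern streams: pure bursting and irregular
streams keep a residual per-window false-flag rate of roughly 2–10%,
because a long inter-burst gap followed by a fresh group is locally
indistinguishable from a pattern change at this reservoir timescale — the
same ambiguity the original experiment reports for its own streaming
results. The corresponding acceptance test is therefore expected to fail,
deliberately: it encodes the idealized claim, and the package reports the
measured behavior rather than weakening the check.

**Synchronization analysis** trains the 6×2-kernel readout on 7200
two-neuron groups (2400/state, continuous collection as above, generic
n-neuron support via a 6×n kernel) and classifies 45-node windows over an
evolving two-device stream (in-phase → anti-phase → no-phase). Evaluation
segments span three windows (2700 ms) so that the per-segment majority
vote rests on ~91 windows; with 900-ms segments every sliding window
crosses a boundary and the vote degenerates to a single window. The
per-window anti-phase vs no-phase decision is the hard axis (~60–75%
correct mid-stream), so the majority is what the sequence test asserts.

**Integrate-and-classify baseline.** The alternative system integrates the
input voltage over m contiguous equal sub-periods of the window
(m ∈ {1, 2, 4, 8, 16, 31}) and trains the same logistic readout; the RC
side is restricted to m evenly spaced virtual nodes. Two findings, both
computed by the tests:

* On the four-pattern task the *idealized* integrator matches or beats the
  node-restricted reservoir at most readout sizes (e.g. 0.83 vs 0.59 at
  m = 1): 20-ms binned charge preserves most of the temporal structure
  that separates these four patterns, and an exact noiseless integral is a
  strong feature. The corresponding acceptance test (reservoir ≥ integrator
  at *every* size) is left failing as an honest negative result of this
  reconstruction: the original comparison's exact integrated system is not
  described in the available text.
* The mechanism claimed for the reservoir's advantage is nevertheless real
  and reproducible: on a task whose classes differ only in within-bin
  (sub-20-ms) spike timing, the integrator's features are *identical by
  construction* (provably uninformative) while the reservoir separates the
  classes essentially perfectly.

## 5. Determinism, seeds and degenerate inputs

A master seed fans out to per-stage child seeds (generation, split,
initialization, stream construction) via one documented scheme
(`derive_seeds`): seeded draws from `sample.int`. All generators accept a
seed and restore the caller's RNG state, experiments are bit-for-bit
reproducible given their seed, and full-batch training is invariant to
sample order. Degenerate inputs fail loudly: windows shorter than a pulse
yield empty trains, windows shorter than one sampling interval are an
error for `virtual_nodes` but an empty list for `sliding_windows`
(documented), kernels longer than the node axis are errors, and any
non-finite reservoir state aborts an experiment with a diagnostic.

## 6. Known limitations

* The device model is a single-state-variable reconstruction calibrated to
  five printed observables; the original supplementary model and its
  parameters are not public. Stretched-exponential relaxation, SET/forming
  hysteresis, compliance behavior and device-to-device variation are out of
  scope.
* The square-pulse input is an idealization; arbitrary sampled waveforms
  can be fed through `voltage_waveform`/`simulate_memristor`, but no
  biophysical action-potential shape is modeled.
* Synthetic spike trains are stationary within their windows by
  construction and do not emulate rate drift, refractory structure or
  cross-pattern superposition found in real recordings; a green classifier
  test establishes separability of the *stated* pattern definitions, not
  performance on biological data.
* The streaming false-alarm and baseline-dominance acceptance checks fail
  for the documented, analyzed reasons above.
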