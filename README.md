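# memrc

Reservoir computing with a simulated volatile memristor, for neural
spike-train analysis.

Dynamic (volatile) memristors are two-terminal devices whose conductance is
raised by applied voltage pulses and then relaxes spontaneously, giving them
short-term memory on a ~100 ms timescale. Driven directly by emulated neural
spikes (100 mV, 2 ms square pulses), such a device acts as the fixed
nonlinear reservoir of a reservoir-computing (RC) system: its conductance,
sampled every 20 ms, forms a chain of *virtual nodes* that summarize the
recent spike history, and only a small readout layer is trained. `memrc` is
a complete software simulator of that system, for computational
neuroscientists and neuromorphic-hardware researchers who want to study or
extend it without a probe station.

The package provides:

- **Spike-train generators** for the four canonical firing patterns —
  tonic, bursting, irregular, adapting — plus pattern transitions and
  multi-neuron synchronization states (in-phase, anti-phase, no phase),
  rendered as square-pulse voltage waveforms.
- **A calibrated device model.** One internal state variable `w ∈ [0, 1]`
  with nonlinear voltage-driven growth and spontaneous relaxation,

  ```
  dw/dt = lambda_g * sinh(eta * V) - w / tau
  I     = w^p * gamma * sinh(delta * V) + (1 - w^p) * sgn(V) * alpha * (1 - exp(-beta * |V|))
  ```

  calibrated (see `calibrate_memristor()`) so that the simulated device
  reproduces the measured contract: HRS ~1e10 Ω and LRS ~1e7 Ω read at
  30 mV, ~20 nA at the end of a 100 mV / 5 ms pulse, a 100 ms read-current
  relaxation time, and ~50 fJ per 100 mV / 500 µs programming pulse.
- **The virtual-node reservoir** (31 nodes per 620-ms window, 45 per 900-ms
  window; sliding windows for streaming analysis).
- **Trained readouts**: a 31×4 fully connected sigmoid classifier for
  firing-pattern recognition, a bilayer CNN (27×1 kernel → 5×5 perceptron)
  for streaming recognition with a transition class, and a bilayer CNN
  (6×2 kernel, stride 2 → 20×3 perceptron) for two-neuron synchronization
  states — all trained by full-batch logistic-regression gradient descent.
- **End-to-end experiments** (`run_pattern_recognition()`,
  `run_streaming()`, `run_sync()`, `run_integrator_baseline()`) with
  deterministic seed fan-out, plus CSV/JSON interchange for trains,
  waveforms, traces, parameters and datasets, and a thin command-line
  front end (`inst/cli/memrc`).

## Worked example

```r
library(memrc)

# firing-pattern recognition at reduced scale (50 trains per pattern)
r <- run_pattern_recognition(seed = 7, n_per_class = 50)
cat(sprintf("held-out accuracy: %.3f\n", r$accuracy))
print(round(r$confusion, 3))

# the calibrated device's programming response
tr5 <- simulate_memristor(voltage_waveform(0.1, rep(100, 50)), default_params())
cat(sprintf("I(end of 100 mV / 5 ms pulse) = %.2f nA\n", tail(tr5$currents, 1)))
```

```
held-out accuracy: 0.975
           
            TONIC BURSTING IRREGULAR ADAPTING
  TONIC         1      0.0       0.0        0
  BURSTING      0      0.9       0.1        0
  IRREGULAR     0      0.0       1.0        0
  ADAPTING      0      0.0       0.0        1
I(end of 100 mV / 5 ms pulse) = 20.01 nA
```

The accuracy is the held-out fraction correct on a stratified 20% split;
the confusion matrix rows are true classes, normalized to occurrence
probabilities (each row sums to 1). The 20 nA figure is the device current
at the end of a single 100 mV / 5 ms programming pulse from the fully
relaxed state — one of the calibration contract points. At the full
protocol scale (400 trains per pattern) the held-out accuracy is ~99%.

See `vignettes/memrc-methods.Rmd` for the model equations, calibration
logic, the design decisions behind the generators and readouts, and known
limitations.

## Acceptance script

`scripts/acceptance.R` recomputes the headline quantities from scratch with
the installed package — the full-protocol pattern-recognition accuracy, the
calibrated device's 5-ms pulse response, fitted relaxation time and 500-µs
pulse energy, and the adapting/irregular generator statistics over 1000
seeded trains — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
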