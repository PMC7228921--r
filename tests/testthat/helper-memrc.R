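# Shared fixtures: everything is generated in code at test time.

quick_params <- function(...) default_params(...)

# A padded-duration spike train of `pattern` (wraps generator defaults).
quick_train <- function(pattern, duration = 620, seed = 1) {
  pattern_generator(pattern)(duration, seed = seed)
}

# Device state after simulating pulses (onsets in ms, 100 mV / 2 ms) from
# w = 0 up to `t_end`.
state_after_pulses <- function(onsets, t_end, params = default_params()) {
  tr <- spike_train(onsets, t_end + 2, "TONIC")
  wf <- render_waveform(tr, dt = 0.1)
  n <- round(t_end / 0.1)
  tail(simulate_memristor(voltage_waveform(0.1, wf$samples[1:n]),
                          params)$states, 1)
}
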