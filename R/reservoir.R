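# Virtual-node reservoir.
#
# A single physical device driven by a pulse stream is sampled at fixed
# intervals; the sampled read currents form a chain of virtual nodes that
# multiplies the effective reservoir dimension. A 620-ms train sampled every
# 20 ms yields 31 nodes (t = 20 * n ms, n = 1..31); a 900-ms window yields 45.

#' Reservoir sampling configuration
#'
#' @param sample_interval virtual-node sampling interval (ms), default 20.
#' @param read_voltage read voltage (mV), default 30.
#' @param window_nodes nodes per analysis window: 31 for the 620-ms pattern
#'   tasks, 45 for the 900-ms synchronization tasks.
#' @param dt simulation step (ms), default 0.1 (20 samples per 2-ms pulse).
#' @return an object of class `reservoir_config`.
#' @export
reservoir_config <- function(sample_interval = 20, read_voltage = 30,
                             window_nodes = 31, dt = 0.1) {
  if (sample_interval <= 0) stop("`sample_interval` must be positive")
  if (window_nodes < 1) stop("`window_nodes` must be at least 1")
  structure(list(sample_interval = sample_interval,
                 read_voltage = read_voltage,
                 window_nodes = window_nodes, dt = dt),
            class = "reservoir_config")
}

#' Reservoir-state matrix
#'
#' @param values numeric matrix, one row per device, one column per virtual
#'   node (read currents, nA; all >= 0).
#' @param sample_times node sampling times (ms), one per column.
#' @return an object of class `reservoir_states`.
#' @export
reservoir_states <- function(values, sample_times) {
  values <- rbind(values)
  if (ncol(values) != length(sample_times))
    stop("one sampling time is required per node column")
  if (any(values < 0)) stop("read currents must be non-negative")
  structure(list(values = values, sample_times = as.numeric(sample_times)),
            class = "reservoir_states")
}

#' @export
print.reservoir_states <- function(x, ...) {
  cat(sprintf("<reservoir_states> %d device(s) x %d nodes (t = %g..%g ms)\n",
              nrow(x$values), ncol(x$values),
              min(x$sample_times), max(x$sample_times)))
  invisible(x)
}

# Read currents of a simulated trace at t = k * interval, k = 1..n_nodes.
sample_trace <- function(trace, n_nodes, config, params, measure = FALSE) {
  idx <- round((1:n_nodes) * config$sample_interval / trace$dt)
  w <- trace$states[idx]
  vapply(w, read_current, numeric(1), params = params,
         v_read = config$read_voltage, measure = measure)
}

#' Compute virtual-node reservoir states for one spike train
#'
#' Renders the train as a 100 mV / 2 ms square-pulse waveform, simulates the
#' device from the fully relaxed state, and reads the current at
#' t = k * `sample_interval` for k = 1..floor(duration / interval).
#'
#' @param train a `spike_train`.
#' @param params a `memristor_params`.
#' @param config a `reservoir_config`.
#' @param measure apply read noise if enabled in `params`.
#' @return a one-row `reservoir_states`.
#' @export
virtual_nodes <- function(train, params = default_params(),
                          config = reservoir_config(), measure = FALSE) {
  if (train$duration < config$sample_interval)
    stop("train shorter than one sampling interval")
  n_nodes <- floor(train$duration / config$sample_interval)
  wf <- render_waveform(train, dt = config$dt)
  trace <- simulate_memristor(wf, params)
  vals <- sample_trace(trace, n_nodes, config, params, measure)
  reservoir_states(matrix(vals, nrow = 1),
                   (1:n_nodes) * config$sample_interval)
}

#' Reservoir states for a multi-neuron group (one device per neuron)
#'
#' Simulates one independent device per spike train; row i of the result is
#' the virtual-node chain of neuron i's device.
#'
#' @param group a `sync_group`.
#' @inheritParams virtual_nodes
#' @return a `reservoir_states` with one row per neuron.
#' @export
multi_device_states <- function(group, params = default_params(),
                                config = reservoir_config(window_nodes = 45),
                                measure = FALSE) {
  stopifnot(inherits(group, "sync_group"))
  rows <- lapply(group$trains, function(tr)
    virtual_nodes(tr, params, config, measure)$values)
  vals <- do.call(rbind, rows)
  n_nodes <- ncol(vals)
  reservoir_states(vals, (1:n_nodes) * config$sample_interval)
}

#' Cut sliding windows from a reservoir-state stream
#'
#' @param states a `reservoir_states` (possibly long stream).
#' @param window nodes per window.
#' @param hop hop between window starts (nodes), default 1.
#' @return a list of `reservoir_states`, each carrying attribute `end_ms`
#'   (the sampling time of its last node); empty if the stream is shorter
#'   than one window.
#' @export
sliding_windows <- function(states, window, hop = 1) {
  n <- ncol(states$values)
  if (n < window) return(list())
  starts <- seq(1L, n - window + 1L, by = hop)
  lapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    out <- reservoir_states(states$values[, idx, drop = FALSE],
                            states$sample_times[idx])
    attr(out, "end_ms") <- states$sample_times[idx[window]]
    out
  })
}

# Global min-max scaling to [0, 1], fitted on training data only (keeps the
# sigmoid readout in its sensitive range without test-set leakage). A single
# lo/hi pair is used so that scaling commutes with sliding a window along
# the node axis.
fit_minmax <- function(X) {
  lo <- min(X)
  hi <- max(X)
  if (hi - lo < 1e-12) hi <- lo + 1
  list(lo = lo, hi = hi)
}

apply_minmax <- function(X, scaler) {
  (X - scaler$lo) / (scaler$hi - scaler$lo)
}
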