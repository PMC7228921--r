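# Plain-text interchange: CSV event tables and waveforms, JSON spike trains,
# model and parameter files.

#' Write / read spike trains as CSV event tables
#'
#' The event-table format has columns `neuron_id` and `time_ms`, one row per
#' spike. A single train is written as neuron 1; a `sync_group` writes one
#' neuron id per train. The reader needs the window metadata, which the event
#' table does not carry.
#'
#' @param x a `spike_train` or `sync_group`.
#' @param path file path.
#' @export
write_spike_csv <- function(x, path) {
  if (inherits(x, "spike_train")) x <- list(x)
  if (inherits(x, "sync_group")) x <- x$trains
  df <- do.call(rbind, lapply(seq_along(x), function(i)
    if (length(x[[i]]$times))
      data.frame(neuron_id = i, time_ms = x[[i]]$times)))
  if (is.null(df)) df <- data.frame(neuron_id = integer(0),
                                    time_ms = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @param duration window length (ms) of the recorded trains.
#' @param label pattern label to attach.
#' @param pulse_width pulse duration (ms).
#' @return `read_spike_csv` returns a list of `spike_train`s (one per
#'   neuron id).
#' @export
read_spike_csv <- function(path, duration, label = "TONIC",
                           pulse_width = 2) {
  df <- utils::read.csv(path)
  if (!all(c("neuron_id", "time_ms") %in% names(df)))
    stop("expected columns `neuron_id`, `time_ms`")
  lapply(split(df$time_ms, df$neuron_id), function(tt)
    spike_train(sort(tt), duration, label, pulse_width))
}

#' Write / read a spike train as JSON (full round trip)
#'
#' @param train a `spike_train`.
#' @param path file path.
#' @export
write_spike_json <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  jsonlite::write_json(list(times = train$times, duration = train$duration,
                            label = train$label,
                            pulse_width = train$pulse_width,
                            meta = train$meta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_json
#' @export
read_spike_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spike_train(x$times, x$duration, x$label, x$pulse_width,
              meta = as.list(x$meta))
}

#' Write / read a voltage waveform as two-column CSV
#'
#' Columns `time_ms` (sample start times at fixed dt) and `voltage_mV`.
#'
#' @param waveform a `voltage_waveform`.
#' @param path file path.
#' @export
write_waveform_csv <- function(waveform, path) {
  n <- length(waveform$samples)
  utils::write.csv(data.frame(time_ms = (seq_len(n) - 1) * waveform$dt,
                              voltage_mV = waveform$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "voltage_mV") %in% names(df)))
    stop("expected columns `time_ms`, `voltage_mV`")
  if (nrow(df) < 2) stop("waveform needs at least two samples")
  dts <- diff(df$time_ms)
  if (diff(range(dts)) > 1e-9) stop("waveform must be uniformly sampled")
  voltage_waveform(dts[1], df$voltage_mV)
}

#' Write / read a simulated current trace as CSV
#'
#' Columns `time_ms`, `voltage_mV`, `current_nA`, `w`.
#'
#' @param trace a `current_trace`.
#' @param waveform the driving `voltage_waveform`.
#' @param path file path.
#' @export
write_trace_csv <- function(trace, waveform, path) {
  n <- length(trace$currents)
  utils::write.csv(data.frame(time_ms = seq_len(n) * trace$dt,
                              voltage_mV = waveform$samples,
                              current_nA = trace$currents,
                              w = trace$states),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write / read memristor parameters as JSON
#'
#' @param params a `memristor_params`.
#' @param path file path.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(memristor_params, as.list(x))
}

#' Write reservoir states as CSV (one row per device)
#'
#' The header carries the node sampling times.
#'
#' @param states a `reservoir_states`.
#' @param path file path.
#' @export
write_states_csv <- function(states, path) {
  m <- states$values
  colnames(m) <- sprintf("t%g", states$sample_times)
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_states_csv
#' @export
read_states_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  reservoir_states(as.matrix(df),
                   as.numeric(sub("^t", "", colnames(df))))
}

#' Save a labeled dataset bundle with its manifest
#'
#' Writes `states.csv` (one sample per row), `labels.csv` and
#' `manifest.json` (seed, parameter values, creation call) to a directory;
#' byte-identical for a fixed seed.
#'
#' @param states numeric sample matrix (samples x features).
#' @param labels per-sample class labels.
#' @param dir output directory.
#' @param seed,params provenance recorded in the manifest.
#' @param force overwrite an existing non-empty directory.
#' @export
save_dataset <- function(states, labels, dir, seed = NA,
                         params = default_params(), force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(states), file.path(dir, "states.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(label = labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = seed, n = nrow(rbind(states)),
                            params = unclass(params)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
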