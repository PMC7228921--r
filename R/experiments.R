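# End-to-end experiments: firing-pattern recognition, streaming transition
# detection, synchronization-state analysis, and the integrate-and-classify
# baseline.

# Fan a master seed out to per-stage child seeds (generation, split,
# initialization, ...) via one documented scheme.
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

# Stratified train/test split: seeded shuffle within each class, first
# `train_fraction` of each class to training.
stratified_split <- function(y, train_fraction, seed) {
  with_seed(seed, {
    train <- logical(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      ntr <- round(train_fraction * length(idx))
      train[idx[seq_len(ntr)]] <- TRUE
    }
    train
  })
}

#' Build the labeled firing-pattern dataset
#'
#' Generates `n_per_class` spike trains for each of the four firing patterns
#' (plus, optionally, the transition class) and computes the 31 virtual-node
#' reservoir states of each train.
#'
#' @param n_per_class trains per class (protocol default 400, i.e. 1600
#'   trains for four patterns and 2000 for five).
#' @param classes character vector of classes to generate.
#' @param duration train length (ms), default 620.
#' @param params a `memristor_params`.
#' @param config a `reservoir_config`.
#' @param seed integer seed.
#' @param measure apply read noise if enabled in `params`.
#' @param continuous if `TRUE`, feed the trains back-to-back (in seeded
#'   shuffled order) through one continuously running device instead of
#'   resetting it to the relaxed state before every train, as a physical
#'   device in a streaming deployment would be driven. Used to train the
#'   streaming readout so that its inputs cover warm-device starts.
#' @param splice_frac fraction of each pure pattern class generated as two
#'   independent same-pattern draws in series (split uniform in
#'   \[0.25, 0.75\]), still labeled as the pure pattern. Used by the
#'   streaming readout so that a re-draw of the same pattern inside a window
#'   is not mistaken for a pattern transition; 0 (the default) reproduces
#'   the plain protocol.
#' @return list with `states` (samples x nodes matrix), `labels`, `trains`.
#' @export
make_pattern_dataset <- function(n_per_class = 400, classes = PATTERNS,
                                 duration = 620, params = default_params(),
                                 config = reservoir_config(), seed = 1,
                                 measure = FALSE, continuous = FALSE,
                                 splice_frac = 0) {
  stopifnot(n_per_class > 0, splice_frac >= 0, splice_frac <= 1)
  with_seed(seed, {
    trains <- list()
    labels <- character(0)
    for (cls in classes) {
      gen <- pattern_generator(cls)
      for (i in seq_len(n_per_class)) {
        tr <- if (cls != "TRANSITION" && i <= splice_frac * n_per_class)
          gen_same_pattern_splice(cls, duration)
        else gen(duration)
        trains[[length(trains) + 1L]] <- tr
        labels <- c(labels, cls)
      }
    }
    n_nodes <- floor(duration / config$sample_interval)
    if (continuous) {
      ord <- sample(length(trains))
      trains <- trains[ord]
      labels <- labels[ord]
      state <- memristor_state(0, 0)
      states <- matrix(0, length(trains), n_nodes)
      for (i in seq_along(trains)) {
        wf <- render_waveform(trains[[i]], dt = config$dt)
        trace <- simulate_memristor(wf, params, state)
        states[i, ] <- sample_trace(trace, n_nodes, config, params, measure)
        state <- memristor_state(trace$final_state$w, 0)
      }
    } else {
      states <- t(vapply(trains, function(tr)
        as.numeric(virtual_nodes(tr, params, config, measure)$values),
        numeric(n_nodes)))
    }
    list(states = states, labels = labels, trains = trains)
  })
}

#' Firing-pattern recognition experiment
#'
#' Full protocol: generate `n_per_class` trains per pattern, compute 31
#' virtual-node states per train, train the fully connected sigmoid readout
#' (31 x 4) by full-batch logistic-regression gradient descent on a
#' stratified 80% split, and evaluate on the held-out 20%.
#'
#' @param seed master seed; fanned out to generation, split and
#'   initialization stages.
#' @param n_per_class trains per pattern (default 400).
#' @param params,config device and reservoir settings.
#' @param train_cfg a `train_config` (seed field is overridden by the fanned
#'   out child seed).
#' @param measure apply read noise if enabled in `params`.
#' @param shuffle_labels permute training labels (negative control).
#' @return list with held-out `accuracy`, row-normalized `confusion`,
#'   the trained `model`, the `scaler`, and the `dataset`.
#' @export
run_pattern_recognition <- function(seed = 1, n_per_class = 400,
                                    params = default_params(),
                                    config = reservoir_config(),
                                    train_cfg = train_config(
                                      learning_rate = 2, epochs = 4000),
                                    measure = FALSE,
                                    shuffle_labels = FALSE) {
  s <- derive_seeds(seed, 4)
  ds <- make_pattern_dataset(n_per_class, PATTERNS, 620, params, config,
                             seed = s[1], measure = measure)
  if (any(!is.finite(ds$states))) stop("non-finite reservoir states")
  train <- stratified_split(ds$labels, train_cfg$train_fraction, s[2])
  scaler <- fit_minmax(ds$states[train, , drop = FALSE])
  Xtr <- apply_minmax(ds$states[train, , drop = FALSE], scaler)
  Xte <- apply_minmax(ds$states[!train, , drop = FALSE], scaler)
  ytr <- ds$labels[train]
  if (shuffle_labels) ytr <- with_seed(s[4], sample(ytr))
  cfg <- train_cfg
  cfg$seed <- s[3]
  model <- train_logistic(Xtr, ytr, cfg, classes = PATTERNS)
  ev <- evaluate(model, Xte, ds$labels[!train])
  list(accuracy = ev$accuracy, confusion = ev$confusion, model = model,
       scaler = scaler, dataset = ds, train_idx = train, seed = seed)
}

# Two independent draws of the same pattern in series, labeled as the pure
# pattern (restart-invariance augmentation for the streaming readout).
gen_same_pattern_splice <- function(pattern, duration, pulse_width = 2) {
  u <- stats::runif(1, 0.25, 0.75) * duration
  gen <- pattern_generator(pattern)
  a <- gen(u, pulse_width = pulse_width)
  b <- gen(duration - u, pulse_width = pulse_width)
  tb <- b$times + u
  if (length(a$times) && length(tb))
    tb <- tb[tb >= a$times[length(a$times)] + pulse_width]
  spike_train(c(a$times, tb), duration, pattern, pulse_width,
              meta = list(splice_ms = u))
}

# Integral of the drive voltage over m contiguous equal sub-periods,
# computed exactly from the pulse layout (mV * ms).
integrator_features <- function(train, m, pulse_amp = 100) {
  edges <- seq(0, train$duration, length.out = m + 1L)
  pw <- train$pulse_width
  vapply(seq_len(m), function(j) {
    a <- edges[j]; b <- edges[j + 1L]
    if (!length(train$times)) return(0)
    ov <- pmin(b, train$times + pw) - pmax(a, train$times)
    pulse_amp * sum(pmax(0, ov))
  }, numeric(1))
}

#' Integrate-and-classify baseline vs the reservoir
#'
#' The baseline replaces the dynamic reservoir by an integrator: its features
#' are the integrals of the input voltage waveform over m contiguous equal
#' sub-periods of the 620-ms window. For each readout size m the same
#' logistic readout is trained on the baseline features and on the reservoir
#' restricted to m virtual nodes (evenly spaced, so the nodes match the
#' integration sub-periods).
#'
#' @inheritParams run_pattern_recognition
#' @param m_values readout sizes to compare.
#' @return data frame with columns `m`, `n_weights_rc`, `accuracy_rc`,
#'   `accuracy_integrator`.
#' @export
run_integrator_baseline <- function(seed = 1, n_per_class = 400,
                                    m_values = c(1, 2, 4, 8, 16, 31),
                                    params = default_params(),
                                    config = reservoir_config(),
                                    train_cfg = train_config(
                                      learning_rate = 2, epochs = 4000)) {
  s <- derive_seeds(seed, 3)
  ds <- make_pattern_dataset(n_per_class, PATTERNS, 620, params, config,
                             seed = s[1])
  train <- stratified_split(ds$labels, train_cfg$train_fraction, s[2])
  n_nodes <- ncol(ds$states)
  int_feats <- function(m) {
    v <- vapply(ds$trains, integrator_features, numeric(m), m = m)
    if (m == 1L) matrix(v, ncol = 1L) else t(v)
  }
  fit_eval <- function(X) {
    scaler <- fit_minmax(X[train, , drop = FALSE])
    cfg <- train_cfg
    cfg$seed <- s[3]
    model <- train_logistic(apply_minmax(X[train, , drop = FALSE], scaler),
                            ds$labels[train], cfg, classes = PATTERNS)
    evaluate(model, apply_minmax(X[!train, , drop = FALSE], scaler),
             ds$labels[!train])$accuracy
  }
  res <- lapply(m_values, function(m) {
    node_idx <- round(n_nodes * seq_len(m) / m)
    Xrc <- ds$states[, node_idx, drop = FALSE]
    Xint <- int_feats(m)
    data.frame(m = m, n_weights_rc = (m + 1L) * length(PATTERNS),
               accuracy_rc = fit_eval(Xrc),
               accuracy_integrator = fit_eval(Xint))
  })
  do.call(rbind, res)
}

#' Concatenate labeled pattern segments into one long spike train
#'
#' Each segment is built by tiling canonical `tile_ms`-long trains of its
#' pattern (truncated at the segment end), so that every pattern keeps the
#' spike statistics of the protocol window length however long the segment
#' is (an adapting segment, for instance, shows repeated adaptation events
#' rather than one event followed by silence).
#'
#' @param segment_labels character vector of firing patterns, in order.
#' @param segment_ms length of each segment (ms); scalar or vector.
#' @param seed optional integer seed.
#' @param tile_ms canonical pattern window used to tile segments (ms).
#' @param pulse_width pulse duration (ms).
#' @return a `spike_train` whose `meta` holds `boundaries_ms` (segment
#'   boundaries) and `segment_labels`.
#' @export
build_stream <- function(segment_labels, segment_ms = 620, seed = NULL,
                         tile_ms = 620, pulse_width = 2) {
  segment_ms <- rep_len(segment_ms, length(segment_labels))
  with_seed(seed, {
    offs <- cumsum(c(0, segment_ms))
    times <- numeric(0)
    for (i in seq_along(segment_labels)) {
      gen <- pattern_generator(segment_labels[i])
      t0 <- offs[i]
      while (t0 < offs[i + 1L]) {
        span <- min(tile_ms, offs[i + 1L] - t0)
        tr <- gen(tile_ms, pulse_width = pulse_width)
        tt <- t0 + tr$times[tr$times <= span - pulse_width]
        if (length(times) && length(tt))
          tt <- tt[tt >= times[length(times)] + pulse_width]
        times <- c(times, tt)
        t0 <- t0 + span
      }
    }
    spike_train(times, sum(segment_ms), "STREAM", pulse_width,
                meta = list(boundaries_ms = offs[c(-1, -length(offs))],
                            segment_labels = segment_labels))
  })
}

# Ground-truth label of a window spanning [end - span, end]: TRANSITION if a
# segment boundary falls inside the span, else the segment's own label
# (mirrors the gray transition bands of width one window used for scoring).
stream_truth <- function(end_ms, span_ms, boundaries, labels, segment_ms) {
  starts <- cumsum(c(0, rep_len(segment_ms, length(labels))))
  vapply(end_ms, function(e) {
    a <- e - span_ms
    if (any(boundaries > a + 1e-9 & boundaries < e - 1e-9)) return("TRANSITION")
    labels[findInterval(e - 1e-9, starts)]
  }, character(1))
}

#' Streaming firing-pattern analysis with transition detection
#'
#' Trains the five-class bilayer convolutional readout (27 x 1 kernel,
#' stride 1, 5 x 5 perceptron) on whole 620-ms trains of the four patterns
#' plus the transition class, then simulates one continuous device along a
#' concatenated stream, slides 31-node windows (hop 1 node = 20 ms),
#' classifies every window, and reports each boundary's detection: the first
#' window after the boundary whose argmax is the transition class.
#'
#' @inheritParams run_pattern_recognition
#' @param n_per_class training trains per class (5 classes; protocol default
#'   400, i.e. 2000 trains).
#' @param stream_segments pattern labels of the evaluation stream segments.
#' @param segment_ms segment length (ms).
#' @param model optional pre-trained readout (list with `model`, `scaler`)
#'   to reuse across streams.
#' @param class_weights per-class loss weights for training (see
#'   [train_conv_readout()]).
#' @param splice_frac fraction of pure-class training trains generated as
#'   same-pattern splices (see [make_pattern_dataset()]).
#' @param tile_ms canonical pattern window used to tile evaluation-stream
#'   segments (see [build_stream()]); set to the stream length for a single
#'   unbroken draw of each segment's pattern.
#' @return list with the per-window prediction table (`windows`), boundary
#'   `detections` (boundary, detected time, latency), `false_alarms`,
#'   held-out accuracy of the readout (`holdout`), and the trained readout.
#' @export
run_streaming <- function(seed = 1, n_per_class = 400,
                          stream_segments = c("TONIC", "BURSTING",
                                              "IRREGULAR", "ADAPTING"),
                          segment_ms = 1860,
                          params = default_params(),
                          config = reservoir_config(),
                          train_cfg = train_config(learning_rate = 2,
                                                   epochs = 30000),
                          model = NULL, class_weights = NULL,
                          splice_frac = 0.5, tile_ms = 620) {
  s <- derive_seeds(seed, 5)
  classes5 <- c(PATTERNS, "TRANSITION")
  if (is.null(model)) {
    ds <- make_pattern_dataset(n_per_class, classes5, 620, params, config,
                               seed = s[1], continuous = TRUE,
                               splice_frac = splice_frac)
    train <- stratified_split(ds$labels, train_cfg$train_fraction, s[2])
    scaler <- fit_minmax(ds$states[train, , drop = FALSE])
    cfg <- train_cfg
    cfg$seed <- s[3]
    inputs_tr <- lapply(which(train), function(i)
      apply_minmax(ds$states[i, , drop = FALSE], scaler))
    net <- train_conv_readout(inputs_tr, ds$labels[train], kernel_size = 27,
                              stride = 1, config = cfg, classes = classes5,
                              class_weights = class_weights)
    inputs_te <- lapply(which(!train), function(i)
      apply_minmax(ds$states[i, , drop = FALSE], scaler))
    holdout <- evaluate(net, inputs_te, ds$labels[!train])
    model <- list(model = net, scaler = scaler)
  } else {
    holdout <- model$holdout
  }

  stream <- build_stream(stream_segments, segment_ms, seed = s[4],
                         tile_ms = tile_ms)
  long_cfg <- config
  long_states <- virtual_nodes(stream, params, long_cfg)
  wins <- sliding_windows(long_states, config$window_nodes, hop = 1)
  end_ms <- vapply(wins, attr, numeric(1), "end_ms")
  inputs <- lapply(wins, function(w) apply_minmax(w$values, model$scaler))
  P <- predict(model$model, inputs)
  pred <- decide(P, classes5)
  span <- config$window_nodes * config$sample_interval
  truth <- stream_truth(end_ms, span, stream$meta$boundaries_ms,
                        stream_segments, segment_ms)
  windows <- data.frame(end_ms = end_ms, pred = pred, truth = truth,
                        prob = apply(P, 1, max))
  detections <- lapply(stream$meta$boundaries_ms, function(b) {
    hit <- which(end_ms >= b & pred == "TRANSITION")
    if (length(hit))
      data.frame(boundary_ms = b, detected_ms = end_ms[hit[1]],
                 latency_ms = end_ms[hit[1]] - b)
    else data.frame(boundary_ms = b, detected_ms = NA_real_,
                    latency_ms = NA_real_)
  })
  detections <- do.call(rbind, detections)
  false_alarms <- windows[windows$pred == "TRANSITION" &
                            windows$truth != "TRANSITION", ]
  list(windows = windows, detections = detections,
       false_alarms = false_alarms, holdout = holdout, stream = stream,
       model = model, seed = seed)
}

#' Build the labeled synchronization dataset
#'
#' @param n_per_state groups per synchronization state (protocol default
#'   2400, i.e. 7200 groups).
#' @param n_neurons neurons (= devices) per group.
#' @param duration window length (ms), default 900.
#' @inheritParams make_pattern_dataset
#' @return list with `inputs` (list of devices x nodes matrices) and
#'   `labels`.
#' @export
make_sync_dataset <- function(n_per_state = 2400, n_neurons = 2,
                              duration = 900, params = default_params(),
                              config = reservoir_config(window_nodes = 45),
                              seed = 1, measure = FALSE,
                              continuous = TRUE) {
  with_seed(seed, {
    groups <- list()
    labels <- character(0)
    for (st in SYNC_STATES) {
      for (i in seq_len(n_per_state)) {
        groups[[length(groups) + 1L]] <- gen_sync_group(st, n_neurons,
                                                        duration)
        labels <- c(labels, st)
      }
    }
    if (continuous) {
      # groups fed back-to-back through the same device pair, as in a
      # streaming deployment (shuffled order, no reset between groups)
      ord <- sample(length(groups))
      groups <- groups[ord]
      labels <- labels[ord]
      n_nodes <- floor(duration / config$sample_interval)
      wstate <- rep(0, n_neurons)
      inputs <- vector("list", length(groups))
      for (i in seq_along(groups)) {
        vals <- matrix(0, n_neurons, n_nodes)
        for (j in seq_len(n_neurons)) {
          wf <- render_waveform(groups[[i]]$trains[[j]], dt = config$dt)
          trace <- simulate_memristor(wf, params,
                                      memristor_state(wstate[j], 0))
          vals[j, ] <- sample_trace(trace, n_nodes, config, params, measure)
          wstate[j] <- trace$final_state$w
        }
        inputs[[i]] <- vals
      }
    } else {
      inputs <- lapply(groups, function(g)
        multi_device_states(g, params, config, measure)$values)
    }
    list(inputs = inputs, labels = labels)
  })
}

# Concatenate one sync group per segment into per-neuron continuous trains.
build_sync_stream <- function(segment_states, n_neurons, segment_ms = 900,
                              seed = NULL, pulse_width = 2) {
  with_seed(seed, {
    offs <- cumsum(c(0, rep_len(segment_ms, length(segment_states))))
    per_neuron <- vector("list", n_neurons)
    for (i in seq_along(segment_states)) {
      g <- gen_sync_group(segment_states[i], n_neurons, segment_ms)
      for (j in seq_len(n_neurons)) {
        tt <- g$trains[[j]]$times + offs[i]
        prev <- per_neuron[[j]]
        if (length(prev) && length(tt))
          tt <- tt[tt >= prev[length(prev)] + pulse_width]
        per_neuron[[j]] <- c(prev, tt)
      }
    }
    trains <- lapply(per_neuron, spike_train,
                     duration = sum(rep_len(segment_ms,
                                            length(segment_states))),
                     label = "BURSTING", pulse_width = pulse_width)
    structure(list(trains = trains, sync_label = segment_states[1],
                   boundaries_ms = offs[c(-1, -length(offs))],
                   segment_labels = segment_states),
              class = "sync_group")
  })
}

#' Synchronization-state analysis experiment
#'
#' Trains the three-class bilayer convolutional readout (6 x 2 kernel,
#' stride 2, 20 x 3 perceptron) on two-neuron groups of in-phase, anti-phase
#' and unsynchronized bursting trains, evaluates on a held-out split, and
#' classifies an evolving stream (in-phase, then anti-phase, then no phase)
#' with 45-node sliding windows over two continuously simulated devices.
#'
#' @inheritParams run_pattern_recognition
#' @param n_per_state training groups per state (protocol default 2400).
#' @param n_neurons neurons per group (>= 2; the kernel is 6 x n_neurons).
#' @param duration window length (ms), default 900.
#' @param segment_ms evaluation-stream segment length (ms); the default of
#'   three windows per segment keeps the per-segment majority vote stable.
#' @param stream_segments synchronization states of the evaluation stream.
#' @return list with held-out evaluation, the per-window stream predictions,
#'   the per-segment majority labels, and the trained readout.
#' @export
run_sync <- function(seed = 1, n_per_state = 2400, n_neurons = 2,
                     duration = 900, segment_ms = 3 * duration,
                     stream_segments = c("IN_PHASE", "ANTI_PHASE",
                                         "NO_PHASE"),
                     params = default_params(),
                     config = reservoir_config(window_nodes = 45),
                     train_cfg = train_config(learning_rate = 2,
                                              epochs = 40000)) {
  if (n_neurons < 2) stop("`n_neurons` must be at least 2")
  s <- derive_seeds(seed, 5)
  ds <- make_sync_dataset(n_per_state, n_neurons, duration, params, config,
                          seed = s[1])
  train <- stratified_split(ds$labels, train_cfg$train_fraction, s[2])
  scaler <- fit_minmax(do.call(rbind, ds$inputs[train]))
  cfg <- train_cfg
  cfg$seed <- s[3]
  inputs_tr <- lapply(ds$inputs[train], apply_minmax, scaler = scaler)
  net <- train_conv_readout(inputs_tr, ds$labels[train], kernel_size = 6,
                            stride = 2, config = cfg, classes = SYNC_STATES)
  inputs_te <- lapply(ds$inputs[!train], apply_minmax, scaler = scaler)
  holdout <- evaluate(net, inputs_te, ds$labels[!train])

  stream <- build_sync_stream(stream_segments, n_neurons, segment_ms,
                              seed = s[4])
  states <- multi_device_states(stream, params, config)
  wins <- sliding_windows(states, config$window_nodes, hop = 1)
  end_ms <- vapply(wins, attr, numeric(1), "end_ms")
  inputs <- lapply(wins, function(w) apply_minmax(w$values, scaler))
  pred <- classify(net, inputs)
  span <- config$window_nodes * config$sample_interval
  truth <- stream_truth(end_ms, span, stream$boundaries_ms,
                        stream_segments, segment_ms)
  windows <- data.frame(end_ms = end_ms, pred = pred, truth = truth)
  interior <- windows[windows$truth != "TRANSITION", ]
  segment_majority <- vapply(stream_segments, function(lab) {
    p <- interior$pred[interior$truth == lab]
    names(sort(table(p), decreasing = TRUE))[1]
  }, character(1))
  list(holdout = holdout, windows = windows,
       segment_majority = segment_majority, model = net, scaler = scaler,
       seed = seed)
}
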