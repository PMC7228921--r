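# Spike-train generators and pulse-waveform rendering.
#
# All times are milliseconds, voltages millivolts. A "spike" is the onset of
# a square pulse (default 100 mV, 2 ms); spike trains never contain
# overlapping pulses.

#' Canonical class labels
#'
#' `PATTERNS` holds the four firing-pattern labels; `SYNC_STATES` the three
#' two-neuron synchronization states.
#' @export
PATTERNS <- c("TONIC", "BURSTING", "IRREGULAR", "ADAPTING")

#' @rdname PATTERNS
#' @export
SYNC_STATES <- c("IN_PHASE", "ANTI_PHASE", "NO_PHASE")

#' Construct a labeled spike train
#'
#' A spike train is an ordered set of pulse onset times inside a recording
#' window. Onsets must be strictly increasing, separated by at least one
#' pulse width, and every pulse must fit inside the window.
#'
#' @param times numeric vector of pulse onset times (ms), strictly increasing.
#' @param duration window length (ms).
#' @param label pattern tag, one of `"TONIC"`, `"BURSTING"`, `"IRREGULAR"`,
#'   `"ADAPTING"`, `"TRANSITION"` (or any string for user data).
#' @param pulse_width pulse duration (ms), default 2.
#' @param meta optional list of generator metadata (e.g. the transition
#'   split point).
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, duration, label = "TONIC", pulse_width = 2,
                        meta = list()) {
  times <- as.numeric(times)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be a single positive number (ms)")
  if (anyNA(times)) stop("spike times must not contain NA")
  if (length(times)) {
    if (is.unsorted(times, strictly = TRUE))
      stop("spike times must be strictly increasing")
    if (min(times) < 0 || max(times) > duration - pulse_width)
      stop("all pulses must lie inside [0, duration - pulse_width]")
    if (length(times) > 1L && min(diff(times)) < pulse_width - 1e-9)
      stop("consecutive onsets must be separated by at least one pulse width")
  }
  structure(list(times = times, duration = duration, label = label,
                 pulse_width = pulse_width, meta = meta),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes over %g ms (pulse %g ms)\n",
              x$label, length(x$times), x$duration, x$pulse_width))
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = use the
# current RNG stream).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Gaussian draw truncated to [lo, Inf) by resampling, so interval jitter can
# never produce non-positive or pulse-overlapping gaps.
rnorm_trunc <- function(n, mean, sd, lo) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo)
  tries <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo]
    tries <- tries + 1L
    if (tries > 1000L) { x[bad] <- lo; break }
  }
  x
}

#' Generate a tonic (regular low-rate) spike train
#'
#' Low-frequency pulses with an approximately constant interval. The
#' per-train mean inter-pulse interval is drawn uniformly from 60--80 ms;
#' individual intervals are Gaussian around it with 5% relative standard
#' deviation. The first spike is at t = 0.
#'
#' @param duration window length (ms), > 0.
#' @param seed optional integer seed (local to this call).
#' @param mean_interval fixed mean interval (ms); default `NULL` samples it
#'   uniformly from \[60, 80\].
#' @param rel_sd relative SD of individual intervals (default 0.05).
#' @param pulse_width pulse duration (ms).
#' @return a `spike_train` labeled `"TONIC"`.
#' @export
gen_tonic <- function(duration, seed = NULL, mean_interval = NULL,
                      rel_sd = 0.05, pulse_width = 2) {
  stopifnot(duration > 0)
  with_seed(seed, {
    m <- if (is.null(mean_interval)) stats::runif(1, 60, 80) else mean_interval
    times <- 0
    repeat {
      gap <- if (rel_sd > 0) rnorm_trunc(1, m, rel_sd * m, pulse_width) else m
      nxt <- times[length(times)] + gap
      if (nxt > duration - pulse_width) break
      times <- c(times, nxt)
    }
    if (duration <= pulse_width) times <- numeric(0)
    spike_train(times, duration, "TONIC", pulse_width,
                meta = list(mean_interval = m))
  })
}

# Internal bursting skeleton: list of per-group onset vectors plus the drawn
# inter-group interval mean. Groups have 3-6 pulses with ~10 ms intra-group
# intervals; the next group starts one inter-group interval after the LAST
# ONSET of the previous group (end-to-start convention).
burst_skeleton <- function(duration, intra_interval = 10, intra_rel_sd = 0.10,
                           inter_mean = NULL, inter_rel_sd = 0.08,
                           group_size = NULL, pulse_width = 2,
                           start = 0) {
  gm <- if (is.null(inter_mean)) stats::runif(1, 100, 200) else inter_mean
  groups <- list()
  t0 <- start
  while (t0 <= duration - pulse_width) {
    size <- if (is.null(group_size)) sample(3:6, 1) else group_size
    gaps <- if (intra_rel_sd > 0)
      rnorm_trunc(size - 1L, intra_interval, intra_rel_sd * intra_interval,
                  pulse_width)
    else rep(intra_interval, size - 1L)
    onsets <- t0 + c(0, cumsum(gaps))
    onsets <- onsets[onsets <= duration - pulse_width]  # truncate at window
    if (!length(onsets)) break
    groups[[length(groups) + 1L]] <- onsets
    gap <- if (inter_rel_sd > 0) rnorm_trunc(1, gm, inter_rel_sd * gm,
                                             pulse_width)
    else gm
    t0 <- onsets[length(onsets)] + gap
  }
  list(groups = groups, inter_mean = gm)
}

#' Generate a bursting spike train
#'
#' Groups of 3--6 high-frequency pulses. Intra-group intervals are Gaussian
#' around 10 ms (10% SD); the gap from the last pulse of one group to the
#' start of the next is Gaussian around a per-train mean drawn uniformly from
#' \[100, 200\] ms (8% SD). The first group starts at t = 0 and groups are
#' truncated at the window end.
#'
#' @inheritParams gen_tonic
#' @param intra_interval within-group inter-pulse interval mean (ms).
#' @param intra_rel_sd relative SD of within-group intervals.
#' @param inter_mean fixed inter-group interval (ms); `NULL` samples
#'   uniformly from \[100, 200\].
#' @param inter_rel_sd relative SD of inter-group intervals.
#' @param group_size fixed pulses per group; `NULL` samples uniformly
#'   from 3..6.
#' @return a `spike_train` labeled `"BURSTING"`; `meta$groups` holds the
#'   per-group onset vectors.
#' @export
gen_bursting <- function(duration, seed = NULL, intra_interval = 10,
                         intra_rel_sd = 0.10, inter_mean = NULL,
                         inter_rel_sd = 0.08, group_size = NULL,
                         pulse_width = 2) {
  stopifnot(duration > 0)
  with_seed(seed, {
    sk <- burst_skeleton(duration, intra_interval, intra_rel_sd, inter_mean,
                         inter_rel_sd, group_size, pulse_width)
    spike_train(unlist(sk$groups), duration, "BURSTING", pulse_width,
                meta = list(groups = sk$groups, inter_mean = sk$inter_mean))
  })
}

#' Generate an irregular (random) spike train
#'
#' The window is divided into segments of 12 ms; each segment independently
#' contains one spike (at the segment start) with probability 0.5. The
#' canonical 620-ms protocol window uses 50 segments (600 ms of segments
#' followed by a 20-ms tail); other durations use `floor(duration / 12)`
#' segments.
#'
#' @inheritParams gen_tonic
#' @param p_fire per-segment firing probability (default 0.5).
#' @param segment_ms segment length (ms, default 12).
#' @param n_segments number of segments; `NULL` applies the rule above.
#' @return a `spike_train` labeled `"IRREGULAR"`.
#' @export
gen_irregular <- function(duration, seed = NULL, p_fire = 0.5,
                          segment_ms = 12, n_segments = NULL,
                          pulse_width = 2) {
  stopifnot(duration > 0)
  if (is.null(n_segments)) {
    n_segments <- if (isTRUE(all.equal(duration, 620))) 50L
                  else floor(duration / segment_ms)
  }
  if (n_segments < 1L) stop("duration too short for one segment")
  with_seed(seed, {
    fire <- stats::runif(n_segments) < p_fire
    times <- (which(fire) - 1L) * segment_ms
    times <- times[times <= duration - pulse_width]
    spike_train(times, duration, "IRREGULAR", pulse_width,
                meta = list(n_segments = n_segments, p_fire = p_fire))
  })
}

#' Generate an adapting spike train
#'
#' Spike-frequency adaptation: the interval between the first two pulses is
#' 6 ms and each subsequent interval is the previous one increased by 30%
#' (the percentage increase is Gaussian with SD of 5 percentage points).
#' Spikes are emitted until the window is exhausted; the first spike is at
#' t = 0.
#'
#' @inheritParams gen_tonic
#' @param first_interval interval between the first two pulses (ms).
#' @param growth mean multiplicative interval growth per step (default 1.30).
#' @param growth_sd SD of the growth ratio (default 0.05).
#' @return a `spike_train` labeled `"ADAPTING"`.
#' @export
gen_adapting <- function(duration, seed = NULL, first_interval = 6,
                         growth = 1.30, growth_sd = 0.05, pulse_width = 2) {
  stopifnot(duration > first_interval)
  with_seed(seed, {
    times <- 0
    interval <- first_interval
    repeat {
      nxt <- times[length(times)] + interval
      if (nxt > duration - pulse_width) break
      times <- c(times, nxt)
      ratio <- if (growth_sd > 0)
        rnorm_trunc(1, growth, growth_sd, pulse_width / interval)
      else growth
      interval <- interval * ratio
    }
    spike_train(times, duration, "ADAPTING", pulse_width,
                meta = list(first_interval = first_interval, growth = growth))
  })
}

#' Generate a pattern-transition spike train
#'
#' Two shorter trains of distinct firing patterns in series. The split point
#' is uniform in \[0.25, 0.75\] of the window; each half is generated by its
#' own pattern rule. Labeled `"TRANSITION"`; the boundary and the two
#' patterns are recorded in `meta`.
#'
#' @inheritParams gen_tonic
#' @param patterns length-2 character vector of distinct patterns; `NULL`
#'   samples two of the four without replacement.
#' @param split split fraction in (0, 1); `NULL` samples uniformly from
#'   \[0.25, 0.75\].
#' @return a `spike_train` labeled `"TRANSITION"` with
#'   `meta$split_ms` and `meta$patterns`.
#' @export
gen_transition <- function(duration, seed = NULL, patterns = NULL,
                           split = NULL, pulse_width = 2) {
  stopifnot(duration > 0)
  with_seed(seed, {
    if (is.null(patterns)) patterns <- sample(PATTERNS, 2)
    if (length(patterns) != 2L || patterns[1] == patterns[2])
      stop("`patterns` must name two distinct firing patterns")
    if (is.null(split)) split <- stats::runif(1, 0.25, 0.75)
    split_ms <- split * duration
    gen1 <- pattern_generator(patterns[1])
    gen2 <- pattern_generator(patterns[2])
    a <- gen1(split_ms, pulse_width = pulse_width)
    b <- gen2(duration - split_ms, pulse_width = pulse_width)
    tb <- b$times + split_ms
    if (length(a$times) && length(tb))
      tb <- tb[tb >= a$times[length(a$times)] + pulse_width]
    spike_train(c(a$times, tb), duration, "TRANSITION", pulse_width,
                meta = list(split_ms = split_ms, patterns = patterns))
  })
}

#' Look up the generator function for a firing pattern
#'
#' @param pattern one of `"TONIC"`, `"BURSTING"`, `"IRREGULAR"`,
#'   `"ADAPTING"`, `"TRANSITION"`.
#' @return the generator function, callable as `f(duration, ...)`.
#' @export
pattern_generator <- function(pattern) {
  switch(pattern,
         TONIC = gen_tonic,
         BURSTING = gen_bursting,
         IRREGULAR = gen_irregular,
         ADAPTING = gen_adapting,
         TRANSITION = gen_transition,
         stop("unknown pattern: ", pattern))
}

#' Construct a multi-neuron synchronization group
#'
#' @param trains list of `spike_train`s of equal duration, one per neuron.
#' @param sync_label `"IN_PHASE"`, `"ANTI_PHASE"` or `"NO_PHASE"`.
#' @return an object of class `sync_group`.
#' @export
sync_group <- function(trains, sync_label) {
  if (length(trains) < 2L) stop("a sync group needs at least 2 neurons")
  durs <- vapply(trains, function(tr) tr$duration, numeric(1))
  if (length(unique(durs)) != 1L) stop("all trains must share one duration")
  sync_label <- match.arg(sync_label, SYNC_STATES)
  structure(list(trains = trains, sync_label = sync_label),
            class = "sync_group")
}

#' @export
print.sync_group <- function(x, ...) {
  cat(sprintf("<sync_group> %s: %d neurons, %g ms\n", x$sync_label,
              length(x$trains), x$trains[[1]]$duration))
  invisible(x)
}

# Jitter spike times, keep them valid (sorted, in-window, non-overlapping).
jitter_times <- function(times, sd, duration, pulse_width) {
  if (sd > 0) times <- sort(times + stats::rnorm(length(times), 0, sd))
  times <- times[times >= 0 & times <= duration - pulse_width]
  if (length(times) > 1L) {
    keep <- c(TRUE, diff(times) >= pulse_width)
    while (!all(keep)) {
      times <- times[keep]
      keep <- c(TRUE, diff(times) >= pulse_width)
    }
  }
  times
}

#' Generate spike trains for a multi-neuron synchronization state
#'
#' All neurons fire bursting patterns. For in-phase synchronization every
#' neuron shares the burst skeleton of a common base train, with Gaussian
#' timing jitter of 10% of the intra-burst interval (1 ms). For anti-phase
#' synchronization successive neurons are phase-shifted by 1/n of the burst
#' period (for two neurons, bursts alternate), with the same jitter. For no
#' phase synchronization the trains are independent bursting trains.
#'
#' @param sync_label `"IN_PHASE"`, `"ANTI_PHASE"` or `"NO_PHASE"`.
#' @param n_neurons number of neurons (>= 2).
#' @param duration window length (ms), default 900.
#' @param seed optional integer seed.
#' @param jitter_sd timing jitter SD (ms); default 1 (10% of the 10-ms
#'   intra-burst interval).
#' @param random_phase if `TRUE` (default) the burst rhythm starts at a
#'   uniformly random phase of its period rather than with a burst at t = 0,
#'   so an analysis window is not phase-locked to the group onset (and
#'   uncorrelated trains do not share a spurious coincident first burst).
#' @param pulse_width pulse duration (ms).
#' @return a `sync_group`.
#' @export
gen_sync_group <- function(sync_label, n_neurons = 2, duration = 900,
                           seed = NULL, jitter_sd = 1, random_phase = TRUE,
                           pulse_width = 2) {
  sync_label <- match.arg(sync_label, SYNC_STATES)
  if (n_neurons < 2L) stop("`n_neurons` must be at least 2")
  stopifnot(duration > 0)
  with_seed(seed, {
    if (sync_label == "NO_PHASE") {
      trains <- lapply(seq_len(n_neurons), function(i) {
        gm <- stats::runif(1, 100, 200)
        off <- if (random_phase) stats::runif(1, 0, gm) else 0
        sk <- burst_skeleton(duration, inter_mean = gm,
                             pulse_width = pulse_width, start = off)
        spike_train(unlist(sk$groups), duration, "BURSTING", pulse_width,
                    meta = list(groups = sk$groups, inter_mean = gm))
      })
    } else {
      gm <- stats::runif(1, 100, 200)
      off <- if (random_phase) stats::runif(1, 0, gm) else 0
      sk <- burst_skeleton(duration + gm, inter_mean = gm,
                           pulse_width = pulse_width, start = off)
      base <- unlist(sk$groups)
      starts <- vapply(sk$groups, function(g) g[1], numeric(1))
      period <- if (length(starts) > 1L) mean(diff(starts)) else sk$inter_mean
      trains <- lapply(seq_len(n_neurons), function(i) {
        shift <- if (sync_label == "ANTI_PHASE")
          (i - 1) * period / n_neurons else 0
        tt <- jitter_times(base + shift, jitter_sd, duration, pulse_width)
        spike_train(tt, duration, "BURSTING", pulse_width,
                    meta = list(shift = shift))
      })
    }
    sync_group(trains, sync_label)
  })
}

#' Render a spike train as a square-pulse voltage waveform
#'
#' Piecewise-constant waveform equal to `pulse_amp` during each pulse
#' (`[onset, onset + pulse_width)`) and 0 elsewhere. Defaults emulate neural
#' spikes as 100 mV, 2 ms square pulses.
#'
#' @param train a `spike_train`.
#' @param pulse_amp pulse amplitude (mV).
#' @param pulse_width pulse duration (ms); defaults to the train's.
#' @param dt sample spacing (ms); must be at most `pulse_width / 4`.
#' @return an object of class `voltage_waveform` with fields `dt` and
#'   `samples` (mV).
#' @export
render_waveform <- function(train, pulse_amp = 100, pulse_width = NULL,
                            dt = 0.1) {
  stopifnot(inherits(train, "spike_train"))
  if (is.null(pulse_width)) pulse_width <- train$pulse_width
  if (dt > pulse_width / 4 + 1e-12)
    stop("`dt` must be at most pulse_width / 4")
  if (length(train$times) > 1L && min(diff(train$times)) < pulse_width - 1e-9)
    stop("pulses overlap at this pulse width")
  n <- round(train$duration / dt)
  v <- numeric(n)
  npulse <- round(pulse_width / dt)
  for (t0 in train$times) {
    i0 <- floor(t0 / dt) + 1L
    idx <- i0:min(i0 + npulse - 1L, n)
    v[idx] <- pulse_amp
  }
  voltage_waveform(dt, v)
}

#' Construct a voltage waveform
#'
#' @param dt sample spacing (ms), > 0.
#' @param samples voltage samples (mV), piecewise-constant over each step.
#' @return an object of class `voltage_waveform`.
#' @export
voltage_waveform <- function(dt, samples) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number")
  structure(list(dt = dt, samples = as.numeric(samples)),
            class = "voltage_waveform")
}

#' @export
print.voltage_waveform <- function(x, ...) {
  cat(sprintf("<voltage_waveform> %d samples at dt = %g ms (%g ms total)\n",
              length(x$samples), x$dt, length(x$samples) * x$dt))
  invisible(x)
}
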