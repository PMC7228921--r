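test_that("spike_train enforces its invariants", {
  expect_s3_class(spike_train(c(0, 10, 20), 100), "spike_train")
  expect_error(spike_train(c(10, 5), 100), "increasing")
  expect_error(spike_train(c(0, 1), 100), "pulse width")
  expect_error(spike_train(99.5, 100), "inside")
  expect_error(spike_train(0, -1), "positive")
  expect_error(gen_tonic(0), "duration > 0")
})

test_that("tonic generator matches the constant-interval oracle", {
  # fixed 70-ms interval, no jitter: floor(618/70) + 1 = 9 spikes at 0..560
  tr <- gen_tonic(620, seed = 1, mean_interval = 70, rel_sd = 0)
  expect_equal(tr$times, seq(0, 560, by = 70))
  expect_identical(tr$label, "TONIC")
  # degenerate window shorter than one pulse: empty train
  expect_length(gen_tonic(0.5, seed = 1)$times, 0)
})

test_that("tonic interval statistics follow the 60-80 ms rule", {
  ivs <- unlist(lapply(1:300, function(s)
    diff(gen_tonic(620, seed = s)$times)))
  m <- mean(ivs)
  expect_gt(m, 60)
  expect_lt(m, 80)
  # per-train means lie in [60, 80] up to the 5% interval jitter
  per_train <- vapply(1:100, function(s)
    mean(diff(gen_tonic(620, seed = s)$times)), numeric(1))
  expect_true(all(per_train > 60 * 0.85 & per_train < 80 * 1.15))
})

test_that("bursting layout matches the deterministic group oracle", {
  # SDs 0, 4 pulses/group, 150 ms end-to-start inter-group interval:
  # group starts one interval after the previous group's last onset
  tr <- gen_bursting(620, seed = 1, inter_mean = 150, group_size = 4,
                     intra_rel_sd = 0, inter_rel_sd = 0)
  expect_equal(tr$times,
               as.numeric(outer(c(0, 10, 20, 30), c(0, 180, 360, 540), "+")))
  expect_length(tr$meta$groups, 4)
})

test_that("bursting statistics match the 10 ms / 10% and 3-6 pulse rules", {
  intra <- c(); sizes <- c()
  for (s in 1:300) {
    tr <- gen_bursting(620, seed = s)
    sizes <- c(sizes, lengths(tr$meta$groups))
    intra <- c(intra, unlist(lapply(tr$meta$groups, diff)))
  }
  expect_true(all(sizes >= 1 & sizes <= 6))  # trailing groups may truncate
  expect_lt(abs(mean(intra) - 10), 3 * stats::sd(intra) / sqrt(length(intra)))
  expect_lt(abs(stats::sd(intra) / mean(intra) - 0.10), 0.02)
})

test_that("irregular generator follows the 50-segment Bernoulli rule", {
  expect_length(gen_irregular(620, seed = 1, p_fire = 0)$times, 0)
  forced <- gen_irregular(620, seed = 1, p_fire = 1)
  expect_equal(forced$times, seq(0, 588, by = 12))   # 50 segments at 620 ms
  # spike-count distribution matches the Binomial(50, 0.5) oracle
  counts <- vapply(1:2000, function(s)
    length(gen_irregular(620, seed = s)$times), numeric(1))
  expect_lt(abs(mean(counts) - 25), 3 * sqrt(50 * 0.25) / sqrt(2000) * 3)
  expect_lt(abs(stats::sd(counts) - sqrt(50 * 0.25)), 0.35)
  # non-canonical durations: floor(duration / 12) segments
  expect_length(gen_irregular(240, seed = 1, p_fire = 1)$times, 20)
})

test_that("adapting generator matches the geometric-interval oracle", {
  # no jitter: onsets 20 * (1.3^k - 1); 14 spikes fit in 620 ms
  tr <- gen_adapting(620, growth_sd = 0)
  expect_length(tr$times, 14)
  expect_equal(tr$times[1:2], c(0, 6))
  expect_equal(tail(tr$times, 1), 20 * (1.3^13 - 1), tolerance = 1e-9)
  # mean successive-interval growth ratio is 1.30
  ratios <- unlist(lapply(1:300, function(s) {
    iv <- diff(gen_adapting(620, seed = s)$times)
    iv[-1] / iv[-length(iv)]
  }))
  expect_equal(mean(ratios), 1.30, tolerance = 0.02)
})

test_that("transition trains combine two distinct patterns at a recorded split", {
  tr <- gen_transition(620, seed = 1, patterns = c("TONIC", "BURSTING"),
                       split = 0.5)
  expect_identical(tr$label, "TRANSITION")
  expect_equal(tr$meta$split_ms, 310)
  # first half carries tonic statistics (sparse), second half bursting (dense)
  first <- tr$times[tr$times < 310]
  second <- tr$times[tr$times >= 310]
  expect_lt(length(first) / 310, length(second) / 310)
  expect_gt(min(diff(first)), 30)          # tonic intervals are >= 60ms * 0.85
  expect_lt(min(diff(second)), 20)         # bursting has ~10 ms intervals
  # split fraction stays within [0.25, 0.75]
  splits <- vapply(1:200, function(s)
    gen_transition(620, seed = s)$meta$split_ms / 620, numeric(1))
  expect_true(all(splits >= 0.25 & splits <= 0.75))
  expect_error(gen_transition(0), "duration > 0")
  expect_error(gen_transition(620, patterns = c("TONIC", "TONIC")), "distinct")
})

test_that("generated trains always satisfy the spike_train invariants", {
  for (s in 1:25) {
    for (pat in c(PATTERNS, "TRANSITION")) {
      tr <- quick_train(pat, seed = s)
      expect_false(is.unsorted(tr$times, strictly = TRUE))
      if (length(tr$times) > 1) expect_gte(min(diff(tr$times)), 2)
      if (length(tr$times)) {
        expect_gte(min(tr$times), 0)
        expect_lte(max(tr$times), tr$duration - 2)
      }
    }
  }
})

test_that("generators are deterministic given a seed", {
  for (pat in c(PATTERNS, "TRANSITION")) {
    a <- quick_train(pat, seed = 11)
    b <- quick_train(pat, seed = 11)
    expect_identical(a, b)
  }
  g1 <- gen_sync_group("ANTI_PHASE", 2, 900, seed = 3)
  g2 <- gen_sync_group("ANTI_PHASE", 2, 900, seed = 3)
  expect_identical(g1, g2)
})

test_that("sync groups realize the three synchronization states", {
  expect_error(gen_sync_group("IN_PHASE", n_neurons = 1), "at least 2")
  # zero jitter, phase fixed: in-phase trains are identical
  g <- gen_sync_group("IN_PHASE", 2, 900, seed = 5, jitter_sd = 0,
                      random_phase = FALSE)
  expect_identical(g$trains[[1]]$times, g$trains[[2]]$times)
  # anti-phase: zero-lag spike coincidences are rarer than half-period-lag
  # coincidences (cross-correlogram oracle)
  coinc <- function(a, b, lag, tol = 5)
    mean(vapply(a, function(t) any(abs(b - (t + lag)) <= tol), logical(1)))
  z <- h <- numeric(0)
  for (s in 1:20) {
    g <- gen_sync_group("ANTI_PHASE", 2, 900, seed = s)
    a <- g$trains[[1]]$times; b <- g$trains[[2]]$times
    lag <- g$trains[[2]]$meta$shift
    z <- c(z, coinc(a, b, 0)); h <- c(h, coinc(a, b, lag))
  }
  expect_lt(mean(z), mean(h))
  # all trains share the group duration
  g <- gen_sync_group("NO_PHASE", 3, 900, seed = 1)
  expect_length(g$trains, 3)
  expect_equal(unique(vapply(g$trains, `[[`, numeric(1), "duration")), 900)
})

test_that("render_waveform places square pulses exactly", {
  empty <- spike_train(numeric(0), 620, "TONIC")
  wf <- render_waveform(empty, dt = 0.1)
  expect_length(wf$samples, 6200)
  expect_true(all(wf$samples == 0))
  # one spike at 3 ms: samples 31..50 (0-based 30..49) at 100 mV
  one <- spike_train(3, 620, "TONIC")
  wf <- render_waveform(one, dt = 0.1)
  expect_true(all(wf$samples[31:50] == 100))
  expect_true(all(wf$samples[-(31:50)] == 0))
  # conservation: total on-time = n_spikes * 2 ms; one rising edge per spike
  tr <- gen_tonic(620, seed = 2)
  wf <- render_waveform(tr, dt = 0.1)
  expect_equal(sum(wf$samples > 0) * 0.1, length(tr$times) * 2)
  edges <- sum(diff(c(0, wf$samples)) > 0)
  expect_equal(edges, length(tr$times))
  expect_error(render_waveform(tr, dt = 1), "pulse_width / 4")
})
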