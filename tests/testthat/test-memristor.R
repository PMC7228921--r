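p <- default_params()

test_that("step follows the state equation with clamping", {
  # pure decay: w <- w * (1 - dt/tau)
  st <- step_memristor(memristor_state(0.5, 0), V = 0, dt = 1, params = p)
  expect_equal(st$w, 0.495)
  expect_equal(st$t, 1)
  # 100 ms of decay stays within 1% of the closed-form exponential
  st <- memristor_state(0.8, 0)
  for (i in 1:1000) st <- step_memristor(st, 0, 0.1, p)
  expect_equal(st$w, 0.8 * exp(-1), tolerance = 0.01)
  # negative voltage: odd-symmetric growth term drives w down
  st <- step_memristor(memristor_state(0.5, 0), V = -100, dt = 0.1, params = p)
  expect_lt(st$w, 0.5)
  expect_gte(st$w, 0)
  # stability bound
  expect_error(step_memristor(memristor_state(0, 0), 0, 2, p), "tau / 100")
})

test_that("device current reproduces the HRS/LRS read levels", {
  expect_equal(device_current(0, 30, p), 0.003, tolerance = 1e-6)  # ~1e10 ohm
  expect_equal(device_current(1, 30, p), 3, tolerance = 1e-6)      # ~1e7 ohm
  expect_identical(device_current(0.5, 0, p), 0)
  # read_current strictly increasing in w
  grid <- seq(0, 1, by = 0.1)
  reads <- vapply(grid, read_current, numeric(1), params = p)
  expect_true(all(diff(reads) > 0))
})

test_that("calibrated pulse responses match the device contract", {
  # 100 mV / 5 ms pulse from rest: ~20 nA, monotone rise from < 1 nA
  tr5 <- simulate_memristor(voltage_waveform(0.1, rep(100, 50)), p)
  expect_equal(tail(tr5$currents, 1), 20, tolerance = 0.02)
  expect_lt(tr5$currents[1], 1)
  expect_true(all(diff(tr5$currents) > 0))
  # zero drive: currents all zero, state decays
  z <- simulate_memristor(voltage_waveform(0.1, rep(0, 100)),
                          p, memristor_state(0.5, 0))
  expect_true(all(z$currents == 0))
  expect_lt(z$final_state$w, 0.5)
})

test_that("relaxation of the read current has a ~100 ms time constant", {
  tr <- simulate_memristor(voltage_waveform(0.1, rep(100, 20)), p)
  w0 <- tr$final_state$w
  tt <- 1:500
  w <- w0 * (1 - 0.1 / p$tau)^(10 * tt)
  reads <- vapply(w, read_current, numeric(1), params = p)
  fit <- stats::nls(reads ~ a * exp(-tt / tau_f) + c0,
                    start = list(a = reads[1], tau_f = 80, c0 = min(reads)),
                    control = stats::nls.control(maxiter = 500,
                                                 scaleOffset = 1))
  expect_equal(unname(stats::coef(fit)["tau_f"]), 100, tolerance = 0.02)
})

test_that("pulse_energy integrates V*I and matches the 50 fJ contract", {
  # constant 100 mV, constant 1 nA, 500 us -> exactly 50 fJ
  wf <- voltage_waveform(0.01, rep(100, 50))
  expect_equal(pulse_energy(wf, rep(1, 50)), 50)
  expect_equal(pulse_energy(voltage_waveform(0.01, rep(0, 50)), rep(1, 50)), 0)
  expect_error(pulse_energy(wf, rep(1, 10)), "lengths differ")
  # calibrated model, 100 mV / 500 us programming pulse -> ~50 fJ
  tr <- simulate_memristor(wf, p)
  expect_equal(pulse_energy(wf, tr), 50, tolerance = 0.02)
})

test_that("calibration script reproduces the committed defaults", {
  pc <- calibrate_memristor()
  for (nm in c("lambda_g", "eta", "tau", "gamma", "delta", "alpha", "beta",
               "w_exp"))
    expect_equal(pc[[nm]], p[[nm]], tolerance = 1e-6)
  expect_identical(p$tau, 100)
  expect_error(memristor_params(1, 1, -1, 1, 1, 1, 1), "positive|>= 0")
  expect_error(memristor_params(1, 1, 1, 1, 1, 1, 1, noise_rel = 1.2),
               "noise_rel")
})

test_that("echo state: recent pulse rate raises the state, old pulses do not", {
  # seven 2-ms pulses ending at t = 0, spacing varied: the state at t = 0
  # increases with the number of pulses delivered within [-120, 0]
  w_end <- vapply(c(60, 40, 20, 10), function(gap)
    state_after_pulses(-(6:0) * gap - 2 + (6 * gap + 2), 6 * gap + 2),
    numeric(1))
  expect_true(all(diff(w_end) > 0))
  # a pulse ending at -150 ms contributes <= 25% of a fresh-pulse increment
  w_fresh <- state_after_pulses(0, 2)
  w_old <- state_after_pulses(0, 152)
  expect_lte(w_old / w_fresh, 0.25)
})

test_that("fading memory: histories differing only before T-300 ms agree at T", {
  suffix <- seq(0, 280, by = 20) + 320
  quiet <- spike_train(suffix, 622, "TONIC")
  dense <- spike_train(c(seq(0, 300, by = 4), suffix), 622, "TONIC")
  i1 <- read_current(simulate_memristor(render_waveform(quiet), p)$final_state,
                     p)
  i2 <- read_current(simulate_memristor(render_waveform(dense), p)$final_state,
                     p)
  expect_lt(abs(i1 - i2), 0.05 * read_current(1, p))
})

test_that("pulse-width response is nonlinear (not charge-additive)", {
  i2 <- tail(simulate_memristor(voltage_waveform(0.1, rep(100, 20)),
                                p)$currents, 1)
  i4 <- tail(simulate_memristor(voltage_waveform(0.1, rep(100, 40)),
                                p)$currents, 1)
  expect_false(isTRUE(all.equal(i4, 2 * i2, tolerance = 1e-3)))
})

test_that("Euler integration is converged at the default step", {
  for (n_ms in c(2, 5)) {
    ia <- tail(simulate_memristor(voltage_waveform(0.1, rep(100, 10 * n_ms)),
                                  p)$currents, 1)
    ib <- tail(simulate_memristor(voltage_waveform(0.05, rep(100, 20 * n_ms)),
                                  p)$currents, 1)
    expect_lt(abs(ia - ib) / ia, 0.005)
  }
})

test_that("state stays in [0, 1] for arbitrary bounded drives", {
  set.seed(99)
  for (i in 1:10) {
    v <- sample(c(-150, -100, 0, 100, 150), 2000, replace = TRUE)
    tr <- simulate_memristor(voltage_waveform(0.1, v), p,
                             memristor_state(runif(1), 0))
    expect_true(all(tr$states >= 0 & tr$states <= 1))
  }
})

test_that("read noise is applied only to flagged measurements", {
  pn <- default_params(noise_rel = 0.05)
  expect_identical(read_current(0.5, pn), read_current(0.5, pn))
  set.seed(1)
  a <- read_current(0.5, pn, measure = TRUE)
  b <- read_current(0.5, pn, measure = TRUE)
  expect_false(a == b)
  expect_equal(a, read_current(0.5, pn), tolerance = 0.25)
})
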