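# Volatile dynamic memristor model.
#
# A single internal state variable w in [0, 1] (degree of conduction-channel
# formation) grows nonlinearly with the applied voltage and relaxes
# spontaneously, giving the device its short-term memory:
#
#   dw/dt = lambda * sinh(eta * V) - w / tau
#
# The device current mixes channel conduction and background leakage, with a
# filament-area exponent p on the state-to-conduction map:
#
#   I = w^p * gamma * sinh(delta * V)
#     + (1 - w^p) * sign(V) * alpha * (1 - exp(-beta * |V|))
#
# Units: ms, mV, nA. The default parameters are calibrated against the
# measured device behaviors (see `calibrate_memristor`).

#' Memristor model parameters
#'
#' @param lambda_g growth-rate prefactor (1/ms).
#' @param eta growth voltage nonlinearity (1/mV).
#' @param tau relaxation time constant (ms), > 0.
#' @param gamma channel-current prefactor (nA).
#' @param delta channel-current voltage nonlinearity (1/mV).
#' @param alpha background-current prefactor (nA).
#' @param beta background-current voltage nonlinearity (1/mV).
#' @param w_exp filament-area exponent mapping state to conduction
#'   (channel weight is `w^w_exp`).
#' @param noise_rel relative Gaussian read-noise SD in \[0, 1); applied only
#'   to flagged measurements, default 0 (off).
#' @return an object of class `memristor_params`.
#' @export
memristor_params <- function(lambda_g, eta, tau, gamma, delta, alpha, beta,
                             w_exp = 1, noise_rel = 0) {
  vals <- c(lambda_g = lambda_g, eta = eta, tau = tau, gamma = gamma,
            delta = delta, alpha = alpha, beta = beta, w_exp = w_exp)
  if (anyNA(vals) || any(vals < 0)) stop("all parameters must be >= 0")
  if (tau <= 0) stop("`tau` must be positive")
  if (noise_rel < 0 || noise_rel >= 1) stop("`noise_rel` must be in [0, 1)")
  structure(c(as.list(vals), list(noise_rel = noise_rel)),
            class = "memristor_params")
}

#' @export
print.memristor_params <- function(x, ...) {
  cat("<memristor_params>\n")
  for (nm in names(x)) cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Committed calibrated default parameters
#'
#' The committed bundle reproduces the measured device contract: HRS
#' ~1e10 ohm and LRS ~1e7 ohm read at 30 mV, ~20 nA at the end of a
#' 100 mV / 5 ms programming pulse, a 100-ms read-current relaxation time,
#' and ~50 fJ delivered by a 100 mV / 500 us pulse. Re-derived by
#' [calibrate_memristor()].
#'
#' @param noise_rel optional relative read-noise SD (default 0).
#' @return a `memristor_params` object.
#' @export
default_params <- function(noise_rel = 0) {
  memristor_params(
    lambda_g = 0.011006329,
    eta      = 0.02,
    tau      = 100,
    gamma    = 1.4089273218,
    delta    = 0.05,
    alpha    = 0.0115748877,
    beta     = 0.01,
    w_exp    = 1.01089258,
    noise_rel = noise_rel
  )
}

#' Re-derive the calibrated parameter bundle from the device contract
#'
#' Solves the model parameters so that, simultaneously: the fully relaxed
#' device (w = 0) reads `i_hrs` nA at `v_read` (HRS ~1e10 ohm at 30 mV);
#' the fully formed channel (w = 1) reads `i_lrs` nA (LRS ~1e7 ohm); a
#' 100 mV / 5 ms pulse from w = 0 ends at `i_program` nA; the state
#' relaxation time is `tau` ms; and the energy delivered by a
#' 100 mV / 500 us pulse is `energy_fj` fJ. The voltage nonlinearities
#' (`eta`, `delta`, `beta`) are fixed structural choices; `alpha`, `gamma`,
#' `lambda_g` and the filament-area exponent are solved.
#'
#' @param tau relaxation time constant (ms).
#' @param i_hrs,i_lrs read currents (nA) at `v_read` for w = 0 / w = 1.
#' @param i_program current (nA) at the end of a 100 mV / 5 ms pulse.
#' @param energy_fj energy (fJ) delivered by a 100 mV / 500 us pulse.
#' @param v_read read voltage (mV).
#' @param eta,delta,beta fixed voltage nonlinearities (1/mV).
#' @return a `memristor_params` object (matches [default_params()]).
#' @export
calibrate_memristor <- function(tau = 100, i_hrs = 0.003, i_lrs = 3,
                                i_program = 20, energy_fj = 50,
                                v_read = 30, eta = 0.02, delta = 0.05,
                                beta = 0.01) {
  alpha <- i_hrs / (1 - exp(-v_read * beta))
  gamma <- i_lrs / sinh(v_read * delta)
  bg100 <- alpha * (1 - exp(-100 * beta))
  ch100 <- gamma * sinh(100 * delta)
  g5 <- (i_program - bg100) / (ch100 - bg100)  # required w^p at end of 5 ms

  build <- function(p) {
    w5 <- g5^(1 / p)
    lambda <- w5 / (sinh(100 * eta) * tau * (1 - exp(-5 / tau)))
    memristor_params(lambda, eta, tau, gamma, delta, alpha, beta, w_exp = p)
  }
  energy_of <- function(p) {
    par <- build(p)
    wf <- voltage_waveform(0.01, rep(100, 50))  # 100 mV, 500 us
    tr <- simulate_memristor(wf, par)
    pulse_energy(wf, tr)
  }
  p <- stats::uniroot(function(p) energy_of(p) - energy_fj, c(1, 1.2),
                      tol = 1e-12)$root
  build(p)
}

#' Memristor state
#'
#' @param w internal state in \[0, 1\] (fraction of channel formation).
#' @param t current simulation time (ms).
#' @return an object of class `memristor_state`.
#' @export
memristor_state <- function(w = 0, t = 0) {
  if (w < 0 || w > 1) stop("`w` must lie in [0, 1]")
  structure(list(w = w, t = t), class = "memristor_state")
}

#' Advance the device state by one Euler step
#'
#' Explicit-Euler update of the state equation under a constant voltage `V`
#' over `dt` ms, with clamping to \[0, 1\].
#'
#' @param state a `memristor_state`.
#' @param V applied voltage (mV).
#' @param dt step (ms); must satisfy the stability bound `dt <= tau / 100`.
#' @param params a `memristor_params`.
#' @return the updated `memristor_state`.
#' @export
step_memristor <- function(state, V, dt, params) {
  if (dt <= 0 || dt > params$tau / 100)
    stop("`dt` must be positive and at most tau / 100")
  w <- state$w + dt * (params$lambda_g * sinh(params$eta * V) -
                         state$w / params$tau)
  memristor_state(min(max(w, 0), 1), state$t + dt)
}

#' Instantaneous device current
#'
#' @param state a `memristor_state`, or a numeric state value w in \[0, 1\].
#' @param V applied voltage (mV).
#' @param params a `memristor_params`.
#' @param measure if `TRUE` and `params$noise_rel > 0`, apply multiplicative
#'   Gaussian read noise (a "measurement"); deterministic otherwise.
#' @return device current (nA).
#' @export
device_current <- function(state, V, params, measure = FALSE) {
  w <- if (inherits(state, "memristor_state")) state$w else state
  g <- w^params$w_exp
  i <- g * params$gamma * sinh(params$delta * V) +
    (1 - g) * sign(V) * params$alpha * (1 - exp(-params$beta * abs(V)))
  if (measure && params$noise_rel > 0)
    i <- i * (1 + stats::rnorm(length(i), 0, params$noise_rel))
  i
}

#' Non-perturbative read of the device current
#'
#' Evaluates the conduction law at the read voltage from the instantaneous
#' state without perturbing it; the physical -30 mV / 0.5 ms read pulses are
#' modeled as instantaneous state queries (read charge is orders of magnitude
#' below programming charge) and the current magnitude at |30 mV| is used.
#'
#' @inheritParams device_current
#' @param v_read read voltage (mV), default 30.
#' @return read current (nA).
#' @export
read_current <- function(state, params, v_read = 30, measure = FALSE) {
  abs(device_current(state, v_read, params, measure = measure))
}

#' Simulate the device along a voltage waveform
#'
#' Integrates the state equation with explicit Euler at the waveform's `dt`
#' and records the current (at each step's end state) and the state
#' trajectory.
#'
#' @param waveform a `voltage_waveform`.
#' @param params a `memristor_params`.
#' @param init initial `memristor_state` (default fully relaxed, w = 0).
#' @return an object of class `current_trace` with fields `dt`, `currents`
#'   (nA), `states` (w trajectory), `i0` (current at the initial state under
#'   the first sample's voltage) and `final_state`.
#' @export
simulate_memristor <- function(waveform, params,
                               init = memristor_state(0, 0)) {
  stopifnot(inherits(waveform, "voltage_waveform"),
            inherits(params, "memristor_params"))
  if (init$w < 0 || init$w > 1) stop("initial state out of [0, 1]")
  if (waveform$dt > params$tau / 100)
    stop("waveform dt violates the Euler stability bound (tau / 100)")
  r <- .euler_sim(waveform$samples, waveform$dt, init$w,
                  params$lambda_g, params$eta, params$tau,
                  params$gamma, params$delta, params$alpha, params$beta,
                  params$w_exp)
  n <- length(waveform$samples)
  i0 <- if (n) device_current(init$w, waveform$samples[1], params) else
    numeric(0)
  structure(list(dt = waveform$dt, currents = r$i, states = r$w, i0 = i0,
                 final_state = memristor_state(
                   if (n) r$w[n] else init$w,
                   init$t + n * waveform$dt)),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples at dt = %g ms, final w = %.4g\n",
              length(x$currents), x$dt, x$final_state$w))
  invisible(x)
}

#' Energy delivered by a pulse
#'
#' Trapezoidal time integral of V(t) * I(t) over the waveform, reported in
#' femtojoules (mV * nA * ms = fJ).
#'
#' @param waveform the driving `voltage_waveform`.
#' @param trace the matching `current_trace` from [simulate_memristor()], or
#'   a numeric current vector aligned with the waveform samples.
#' @return energy in fJ.
#' @export
pulse_energy <- function(waveform, trace) {
  v <- waveform$samples
  if (inherits(trace, "current_trace")) {
    if (length(trace$currents) != length(v))
      stop("waveform and trace lengths differ")
    i <- c(trace$i0, trace$currents)
  } else {
    if (length(trace) != length(v))
      stop("waveform and trace lengths differ")
    i <- c(trace[1], trace)
  }
  p <- v * (utils::head(i, -1) + utils::tail(i, -1)) / 2
  sum(p) * waveform$dt
}
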