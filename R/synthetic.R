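#' Build an alternating potential-step protocol
#'
#' The standard program for probing anaerobic (in)activation kinetics:
#' start at a reducing potential `low_E`, alternate `n_cycles` times to
#' an oxidising potential `high_E` and back, ending at `low_E` — i.e.
#' `2 * n_cycles + 1` steps in total.  Defaults reproduce the
#' inactivation/reactivation stepping experiment between -0.31 and
#' -0.21 V with 50 s holds.
#'
#' @param low_E,high_E the two step potentials (V vs SHE).
#' @param n_cycles number of low->high->low excursions (0 gives a
#'   single hold at `low_E`).
#' @param durations step duration(s) in s, recycled over the steps.
#' @param pH,temperature_K solution conditions.
#' @param rotation_rpm electrode rotation (metadata).
#' @return A [protocol()] object.
#' @export
make_step_protocol <- function(low_E = -0.31, high_E = -0.21, n_cycles = 3,
                               durations = 50, pH = 7,
                               temperature_K = 278.15,
                               rotation_rpm = 3000) {
  if (n_cycles < 0 || n_cycles != round(n_cycles))
    stop_invalid("n_cycles must be a non-negative integer")
  pots <- c(low_E, rep(c(high_E, low_E), n_cycles))
  protocol(pots, durations, pH = pH, temperature_K = temperature_K,
           rotation_rpm = rotation_rpm)
}

#' Noise specification for synthetic traces
#'
#' Additive Gaussian noise with standard deviation
#' `relative_sd * max(|noise-free current|)`.
#'
#' @param relative_sd relative noise level (>= 0); 0.01 emulates a
#'   clean film-electrochemistry trace.
#' @param seed integer RNG seed; generation is bit-reproducible for a
#'   fixed seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(relative_sd = 0.01, seed = 1L) {
  if (relative_sd < 0) stop_invalid("relative_sd must be >= 0")
  structure(list(relative_sd = relative_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Capacitive step-transient specification
#'
#' Non-faradaic electrode-charging transient added after each potential
#' step: `peak_amplitude * sign(dE) * exp(-(t - t_step)/tau)`.  In real
#' experiments this background is recorded in an enzyme-free control and
#' subtracted.
#'
#' @param peak_amplitude spike height (current units).
#' @param tau charging time constant (s), > 0.
#' @return An object of class `capacitive_spec`.
#' @export
capacitive_spec <- function(peak_amplitude = 0.5, tau = 0.5) {
  if (tau <= 0) stop_invalid("tau must be > 0")
  structure(list(peak_amplitude = peak_amplitude, tau = tau),
            class = "capacitive_spec")
}

capacitive_component <- function(protocol, t_grid, capacitive) {
  if (is.null(capacitive)) return(numeric(length(t_grid)))
  starts <- protocol_step_starts(protocol)
  out <- numeric(length(t_grid))
  if (nrow(protocol) < 2) return(out)
  for (i in 2:nrow(protocol)) {
    dE <- protocol$potential[i] - protocol$potential[i - 1]
    if (dE == 0) next
    after <- t_grid >= starts[i]
    out[after] <- out[after] + sign(dE) * capacitive$peak_amplitude *
      exp(-(t_grid[after] - starts[i]) / capacitive$tau)
  }
  out
}

add_noise <- function(current, noise) {
  if (is.null(noise) || noise$relative_sd == 0) return(current)
  sd <- noise$relative_sd * max(abs(current))
  withr::with_seed(noise$seed,
                   current + stats::rnorm(length(current), 0, sd))
}

#' Generate a synthetic chronoamperogram with known ground truth
#'
#' Wraps [simulate_current()] with a capacitive step transient and
#' additive Gaussian noise, and records every generating parameter
#' (including the seed) in a `truth` attribute so that inference can be
#' validated against it.
#'
#' @inheritParams simulate_current
#' @param noise a [noise_spec()] (or `NULL` for noise-free).
#' @param capacitive a [capacitive_spec()] or `NULL` (default: no
#'   capacitive transient).
#' @return A [pfe_trace()] with attribute `truth` (list of all
#'   generating parameters).
#' @export
generate_chronoamperogram <- function(protocol, rates,
                                      weights = activity_weights(),
                                      amplitudes,
                                      noise = noise_spec(),
                                      capacitive = NULL,
                                      film_loss_tau = NULL,
                                      sample_hz = 10) {
  core <- simulate_current(protocol, rates, weights, amplitudes,
                           film_loss_tau = film_loss_tau,
                           sample_hz = sample_hz)
  cap <- capacitive_component(protocol, core$time_s, capacitive)
  noisy <- add_noise(core$current + cap, noise)
  tr <- pfe_trace(core$time_s, core$potential_V, noisy,
                  metadata = trace_metadata(core))
  attr(tr, "truth") <- list(
    protocol = protocol, rates = rates_per_step(rates, protocol),
    weights = weights, amplitudes = as_amplitude_map(amplitudes),
    noise = noise, capacitive = capacitive,
    film_loss_tau = film_loss_tau, sample_hz = sample_hz,
    states = attr(core, "states"), noise_free = core$current + cap,
    enzymatic = core$current
  )
  tr
}

#' Generate an enzyme-free blank trace
#'
#' Capacitive transients plus noise on the same potential program, with
#' zero enzymatic component — the control experiment used for
#' background subtraction.
#'
#' @inheritParams generate_chronoamperogram
#' @return A [pfe_trace()].
#' @export
generate_blank <- function(protocol, capacitive = capacitive_spec(),
                           noise = noise_spec(), sample_hz = 10) {
  t_grid <- seq(0, protocol_total_duration(protocol), by = 1 / sample_hz)
  starts <- protocol_step_starts(protocol)
  step_of <- findInterval(t_grid, starts)
  cap <- capacitive_component(protocol, t_grid, capacitive)
  cur <- add_noise_blank(cap, noise)
  pfe_trace(t_grid, protocol$potential[step_of], cur,
            metadata = list(pH = attr(protocol, "pH"),
                            temperature_K = attr(protocol, "temperature_K"),
                            rotation_rpm = attr(protocol, "rotation_rpm"),
                            units = "normalized"))
}

# blank noise scale: relative to the capacitive peak (the only signal),
# falling back to absolute sd = relative_sd if the blank is all-zero
add_noise_blank <- function(cap, noise) {
  if (is.null(noise) || noise$relative_sd == 0) return(cap)
  scale <- max(abs(cap))
  if (scale == 0) scale <- 1
  withr::with_seed(noise$seed,
                   cap + stats::rnorm(length(cap), 0,
                                      noise$relative_sd * scale))
}

#' Specification of the five-phase O2-exposure experiment
#'
#' Mirrors the residual-activity protocol used to quantify O2
#' resistance: P1 H2-production current at a reducing potential; P2 step
#' to an oxidising potential (a cap-forming enzyme locks itself in
#' Hinact here); P3 injection of dissolved O2; P4 buffer exchange
#' washing O2 out (exponential decay of concentration); P5 step back to
#' the reducing potential to read the residual activity.
#'
#' @param phase_times start times of P1..P5 (s), strictly increasing;
#'   defaults 0, 200, 480, 900, 1300.
#' @param end_time end of the record (s).
#' @param reducing_E,oxidising_E potentials (V vs SHE) applied in
#'   P1/P5 and P2-P4 respectively.
#' @param o2_molar O2 concentration injected at P3 (mol/L); default
#'   50e-6 (50 uM).
#' @param damage_rate second-order rate constant (1/(M s)) of
#'   irreversible O2 damage to the *active* states (Hinact is cap-
#'   protected and immune).
#' @param o2_washout_tau time constant (s) of O2 washout during P4.
#' @return An object of class `o2_experiment_spec`.
#' @export
o2_experiment_spec <- function(phase_times = c(0, 200, 480, 900, 1300),
                               end_time = 1700,
                               reducing_E = -0.8, oxidising_E = 0,
                               o2_molar = 50e-6, damage_rate = 500,
                               o2_washout_tau = 60) {
  if (length(phase_times) != 5 || any(diff(phase_times) <= 0))
    stop_invalid("phase_times must be 5 strictly increasing values")
  if (phase_times[1] != 0)
    stop_invalid("the record starts at P1: phase_times[1] must be 0")
  if (end_time <= phase_times[5])
    stop_invalid("end_time must exceed the start of P5")
  if (o2_molar < 0 || damage_rate < 0)
    stop_invalid("concentrations and rates must be >= 0")
  if (o2_washout_tau <= 0) stop_invalid("o2_washout_tau must be > 0")
  structure(list(phase_times = phase_times, end_time = end_time,
                 reducing_E = reducing_E, oxidising_E = oxidising_E,
                 o2_molar = o2_molar, damage_rate = damage_rate,
                 o2_washout_tau = o2_washout_tau),
            class = "o2_experiment_spec")
}

o2_concentration <- function(spec, t) {
  p3 <- spec$phase_times[3]; p4 <- spec$phase_times[4]
  ifelse(t < p3, 0,
         ifelse(t < p4, spec$o2_molar,
                spec$o2_molar * exp(-(t - p4) / spec$o2_washout_tau)))
}

#' Simulate the five-phase O2-exposure experiment
#'
#' Integrates a four-species extension of the AAI scheme
#' (A1, A2, Hinact, Dead) through the P1-P5 protocol:
#' `d(dead)/dt = damage_rate * [O2](t) * (a1 + a2)`, with [O2] stepping
#' to the injected concentration at P3 and washing out exponentially
#' from P4.  Damage strikes only the active states — the cap-bound
#' Hinact state is protected — and is never repaired.  The current is
#' `amplitude(E_phase) * (alpha1*a1 + alpha2*a2)` plus noise.
#'
#' @param spec an [o2_experiment_spec()].
#' @param rates named list mapping the two phase potentials to
#'   [rate_constants()]; either an `amplitude_map`-style list with
#'   entries `reducing` and `oxidising`, or a list of two
#'   `rate_constants` in that order.
#' @param weights an [activity_weights()] object.
#' @param amplitudes per-potential current scales covering both phase
#'   potentials (reduction currents are negative by convention).
#' @param noise a [noise_spec()] or `NULL`.
#' @param sample_hz sampling rate (Hz).
#' @return A [pfe_trace()] with attributes `truth` (generating
#'   parameters) and `states` (4 x n matrix over A1, A2, Hinact, Dead).
#' @export
generate_o2_experiment <- function(spec, rates,
                                   weights = activity_weights(),
                                   amplitudes =
                                     amplitude_map(c(-0.8, 0), c(-1, 0.3)),
                                   noise = noise_spec(),
                                   sample_hz = 10) {
  stopifnot(inherits(spec, "o2_experiment_spec"))
  rc_red <- as_rate_constants(rates$reducing %||% rates[[1]])
  rc_oxi <- as_rate_constants(rates$oxidising %||% rates[[2]])
  weights <- as_weights(weights)

  bounds <- c(spec$phase_times, spec$end_time)
  phase_E <- c(spec$reducing_E, rep(spec$oxidising_E, 3), spec$reducing_E)
  phase_rc <- list(rc_red, rc_oxi, rc_oxi, rc_oxi, rc_red)
  amp_phase <- amplitude_at(amplitudes, phase_E)

  t_grid <- seq(0, spec$end_time, by = 1 / sample_hz)
  phase_of <- findInterval(t_grid, spec$phase_times)
  states <- matrix(NA_real_, 4, length(t_grid),
                   dimnames = list(c("a1", "a2", "h_inact", "dead"), NULL))
  y <- c(a1 = 1, a2 = 0, h_inact = 0, dead = 0)

  deriv <- function(t, y, parms) {
    G <- parms$G
    flow <- as.numeric(G %*% y[1:3])
    dmg <- spec$damage_rate * o2_concentration(spec, t)
    list(c(flow[1] - dmg * y[1],
           flow[2] - dmg * y[2],
           flow[3],
           dmg * (y[1] + y[2])))
  }

  for (p in 1:5) {
    sel <- phase_of == p
    times <- unique(c(bounds[p], t_grid[sel], bounds[p + 1]))
    sol <- deSolve::lsoda(y, times, deriv,
                          parms = list(G = build_generator(phase_rc[[p]])),
                          rtol = 1e-10, atol = 1e-12)
    if (any(sel)) {
      keep <- match(t_grid[sel], sol[, "time"])
      states[, sel] <- t(sol[keep, c("a1", "a2", "h_inact", "dead")])
    }
    y <- sol[nrow(sol), c("a1", "a2", "h_inact", "dead")]
  }

  activity <- weights[["alpha1"]] * states["a1", ] +
    weights[["alpha2"]] * states["a2", ]
  current <- amp_phase[phase_of] * activity
  noisy <- add_noise(current, noise)
  tr <- pfe_trace(t_grid, phase_E[phase_of], noisy,
                  metadata = list(units = "normalized"))
  attr(tr, "states") <- states
  attr(tr, "truth") <- list(spec = spec, rates = list(reducing = rc_red,
                                                      oxidising = rc_oxi),
                            weights = weights,
                            amplitudes = as_amplitude_map(amplitudes),
                            noise = noise, noise_free = current,
                            sample_hz = sample_hz)
  tr
}

#' Generate a synthetic cyclic voltammogram
#'
#' [simulate_cv()] plus additive Gaussian noise, with the generating
#' parameters kept in a `truth` attribute.
#'
#' @inheritParams simulate_cv
#' @param noise a [noise_spec()] or `NULL`.
#' @return A [pfe_trace()] with a `truth` attribute.
#' @export
generate_cv <- function(sweep, rates, law, weights = activity_weights(),
                        waveshape = list(E_eq = -0.426, steepness = 20,
                                         i_lim = 1),
                        noise = noise_spec(relative_sd = 0.005),
                        sample_hz = 10, pH = 7) {
  core <- simulate_cv(sweep, rates, law, weights, waveshape,
                      sample_hz = sample_hz, pH = pH)
  noisy <- add_noise(core$current, noise)
  tr <- pfe_trace(core$time_s, core$potential_V, noisy,
                  metadata = trace_metadata(core))
  attr(tr, "truth") <- list(sweep = sweep, rates = rates, law = law,
                            weights = weights, waveshape = waveshape,
                            noise = noise, noise_free = core$current,
                            states = attr(core, "states"))
  tr
}
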