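#' Simulate the catalytic current under a potential-step protocol
#'
#' The current model behind potential-step chronoamperometry of a
#' cap-protected hydrogenase: at each sample,
#' `current(t) = amplitude(E_step) * (alpha1*a1(t) + alpha2*a2(t))`,
#' optionally damped by a single-exponential film-loss factor
#' `exp(-t / film_loss_tau)`.  The state fractions evolve by exact
#' propagation of the AAI master equation with the step's rate
#' constants; the state is continuous across step boundaries while the
#' current jumps exactly at step times (the turnover frequency of the
#' active enzyme changes instantly with the potential, the Hinact
#' concentration only slowly afterwards — this is what produces the
#' characteristic peak-then-relax shape).
#'
#' @param protocol a [protocol()] object.
#' @param rates one of: a single [rate_constants()] object (used for
#'   every step), a list of `rate_constants` with one element per step,
#'   or `list(base = rate_constants, law = kreact_law)` in which case
#'   `k_react` is evaluated from the law at each step potential.
#' @param weights an [activity_weights()] object.
#' @param amplitudes per-potential current scales ([amplitude_map()] or
#'   named numeric vector); every distinct protocol potential must be
#'   covered.
#' @param t_grid sample times (s); default a regular grid at
#'   `sample_hz` covering the protocol.
#' @param initial_state state at t = 0; default pure A1 (fully
#'   activated film).
#' @param film_loss_tau optional film-desorption time constant (s);
#'   `NULL` (default) disables film loss.
#' @param sample_hz default sampling rate (Hz) used when `t_grid` is
#'   not given.
#' @return A [pfe_trace()] with an attribute `states` (3 x n matrix of
#'   state fractions at the sample times).
#' @export
simulate_current <- function(protocol, rates, weights = activity_weights(),
                             amplitudes, t_grid = NULL,
                             initial_state = c(1, 0, 0),
                             film_loss_tau = NULL, sample_hz = 10) {
  stopifnot(inherits(protocol, "pfe_protocol"))
  rc_list <- rates_per_step(rates, protocol)
  weights <- as_weights(weights)
  amp <- amplitude_at(amplitudes, protocol$potential)
  total <- protocol_total_duration(protocol)
  if (is.null(t_grid))
    t_grid <- seq(0, total, by = 1 / sample_hz)
  if (any(t_grid < 0) || any(t_grid > total + 1e-9))
    stop_invalid("t_grid must lie within the protocol duration")
  if (!is.null(film_loss_tau) && film_loss_tau <= 0)
    stop_invalid("film_loss_tau must be > 0")

  starts <- protocol_step_starts(protocol)
  step_of <- findInterval(t_grid, starts)
  state <- as.numeric(as_state(initial_state))
  states <- matrix(NA_real_, 3, length(t_grid),
                   dimnames = list(c("a1", "a2", "h_inact"), NULL))
  for (i in seq_len(nrow(protocol))) {
    sel <- step_of == i
    if (any(sel))
      states[, sel] <- propagate_grid(state, rc_list[[i]],
                                      t_grid[sel] - starts[i])
    state <- as.numeric(propagate_grid(state, rc_list[[i]],
                                       protocol$duration[i]))
  }
  activity <- weights[["alpha1"]] * states["a1", ] +
    weights[["alpha2"]] * states["a2", ]
  current <- amp[step_of] * activity
  if (!is.null(film_loss_tau))
    current <- current * exp(-t_grid / film_loss_tau)
  tr <- pfe_trace(t_grid, protocol$potential[step_of], current,
                  metadata = list(pH = attr(protocol, "pH"),
                                  temperature_K = attr(protocol, "temperature_K"),
                                  rotation_rpm = attr(protocol, "rotation_rpm"),
                                  units = "normalized"))
  attr(tr, "states") <- states
  tr
}

as_weights <- function(weights) {
  if (inherits(weights, "activity_weights")) return(weights)
  if (is.numeric(weights) && length(weights) == 1)
    return(activity_weights(weights))
  stop_invalid("weights must be an activity_weights object")
}

# Normalise the `rates` argument of simulate_current into one
# rate_constants object per protocol step.
rates_per_step <- function(rates, protocol) {
  n <- nrow(protocol)
  if (inherits(rates, "rate_constants"))
    return(rep(list(rates), n))
  if (is.list(rates) && !is.null(rates$base) && !is.null(rates$law))
    return(lapply(protocol$potential, function(E)
      rates_at_potential(rates$base, rates$law, E)))
  if (is.list(rates) && all(vapply(rates, inherits, logical(1),
                                   "rate_constants"))) {
    if (length(rates) != n)
      stop_invalid(sprintf("need one rate set per step (%d), got %d",
                           n, length(rates)))
    return(rates)
  }
  stop_invalid("rates must be rate_constants, a per-step list of them, or list(base=, law=)")
}

#' Simulate a cyclic voltammogram with anaerobic inactivation
#'
#' Qualitative simulation of the CV signature of reversible anaerobic
#' inactivation: the AAI state is integrated along the triangular
#' potential ramp `E_start -> E_vertex -> E_start`, with `k_react`
#' evaluated from a potential-dependent law and `(k1, k_neg1, k_inact)`
#' held fixed, and the current is a sigmoidal catalytic waveshape
#' `i_lim * tanh(steepness * (E - E_eq))` scaled by the weighted
#' activity.  Whenever inactivation is non-negligible on the sweep
#' timescale the forward and backward branches separate (hysteresis):
#' the forward current peaks below the vertex and the backward branch
#' recovers only at reducing potentials, where reactivation sets in.
#'
#' The initial state is the A1/A2 conformational equilibrium with no
#' Hinact (a film fully activated at the starting, reducing potential),
#' so a scheme with `k_inact = 0` traces identical branches.
#'
#' @param sweep list with `E_start`, `E_vertex` (V vs SHE) and
#'   `scan_rate` (V/s, > 0).
#' @param rates a [rate_constants()] object; its `k_react` entry is
#'   ignored in favour of `law`.
#' @param law a [kreact_law()] giving `k_react(E)`
#'   (typically [kreact_exponential()]).
#' @param weights an [activity_weights()] object.
#' @param waveshape list with `E_eq` (V), `steepness` (1/V) and `i_lim`
#'   (current units).
#' @param sample_hz sampling rate (Hz).
#' @param pH,temperature_K metadata recorded on the trace.
#' @return A [pfe_trace()] with `scan_rate_V_s` metadata and a `states`
#'   attribute.
#' @export
simulate_cv <- function(sweep, rates, law, weights = activity_weights(),
                        waveshape = list(E_eq = -0.426, steepness = 20,
                                         i_lim = 1),
                        sample_hz = 10, pH = 7, temperature_K = 278.15) {
  stopifnot(is.list(sweep), inherits(law, "kreact_law"))
  rates <- as_rate_constants(rates)
  weights <- as_weights(weights)
  v <- sweep$scan_rate
  if (is.null(v) || !is.finite(v) || v <= 0)
    stop_invalid("scan_rate must be > 0")
  E0 <- sweep$E_start; E1 <- sweep$E_vertex
  span <- abs(E1 - E0)
  t_half <- span / v
  t_grid <- seq(0, 2 * t_half, by = 1 / sample_hz)
  dirn <- sign(E1 - E0)
  E_of_t <- function(t) {
    up <- t <= t_half
    E <- numeric(length(t))
    E[up] <- E0 + dirn * v * t[up]
    E[!up] <- E1 - dirn * v * (t[!up] - t_half)
    E
  }
  E_grid <- E_of_t(t_grid)

  # fully activated, conformationally pre-equilibrated film
  ktot <- rates[["k1"]] + rates[["k_neg1"]]
  state <- if (ktot > 0)
    c(rates[["k_neg1"]], rates[["k1"]], 0) / ktot else c(1, 0, 0)

  n <- length(t_grid)
  states <- matrix(NA_real_, 3, n,
                   dimnames = list(c("a1", "a2", "h_inact"), NULL))
  states[, 1] <- state
  for (i in seq_len(n - 1)) {
    rc_i <- rates_at_potential(rates, law, E_grid[i])
    state <- as.numeric(propagate_grid(state, rc_i,
                                       t_grid[i + 1] - t_grid[i]))
    states[, i + 1] <- state
  }
  activity <- weights[["alpha1"]] * states["a1", ] +
    weights[["alpha2"]] * states["a2", ]
  shape <- waveshape$i_lim * tanh(waveshape$steepness *
                                    (E_grid - waveshape$E_eq))
  tr <- pfe_trace(t_grid, E_grid, shape * activity,
                  metadata = list(pH = pH, temperature_K = temperature_K,
                                  scan_rate_V_s = v, units = "normalized"))
  attr(tr, "states") <- states
  tr
}
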