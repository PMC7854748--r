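#' Potential program for a chronoamperometry experiment
#'
#' A protocol is an ordered sequence of constant-potential holds
#' (`potential` in V vs SHE, `duration` in s) together with the solution
#' conditions.  Rotation rate is carried as metadata only (film
#' experiments are run fast enough that mass transport is not limiting).
#'
#' @param potential numeric vector of step potentials (V vs SHE).
#' @param duration numeric vector of step durations (s), recycled to the
#'   length of `potential`; all > 0.
#' @param pH solution pH, in [0, 14].
#' @param temperature_K temperature in kelvin.
#' @param rotation_rpm electrode rotation rate (metadata only).
#' @return An object of class `pfe_protocol`: a data.frame with columns
#'   `potential`, `duration` and condition attributes.
#' @export
protocol <- function(potential, duration, pH = 7, temperature_K = 278.15,
                     rotation_rpm = 3000) {
  if (length(potential) == 0) stop_invalid("protocol must have >= 1 step")
  duration <- rep_len(duration, length(potential))
  if (any(!is.finite(potential)) || any(!is.finite(duration)))
    stop_invalid("potentials and durations must be finite")
  if (any(duration <= 0)) stop_invalid("step durations must be > 0")
  if (!is.finite(pH) || pH < 0 || pH > 14)
    stop_invalid("pH must lie in [0, 14]")
  structure(
    data.frame(potential = potential, duration = duration),
    pH = pH, temperature_K = temperature_K, rotation_rpm = rotation_rpm,
    class = c("pfe_protocol", "data.frame")
  )
}

#' @export
print.pfe_protocol <- function(x, ...) {
  cat(sprintf("Potential-step protocol: %d step(s), %.1f s total, pH %g, %g K\n",
              nrow(x), sum(x$duration), attr(x, "pH"),
              attr(x, "temperature_K")))
  print(as.data.frame(x), ...)
  invisible(x)
}

protocol_step_starts <- function(protocol) {
  cumsum(c(0, protocol$duration[-nrow(protocol)]))
}

protocol_total_duration <- function(protocol) sum(protocol$duration)

#' Per-potential current amplitudes
#'
#' The current model assigns one amplitude (current scale, the turnover
#' frequency contribution of fully active enzyme) per distinct electrode
#' potential; repeated visits to the same potential share it.
#'
#' @param potential numeric vector of distinct potentials (V vs SHE).
#' @param scale current scale at each potential (arbitrary units).
#' @return A data.frame of class `amplitude_map`.
#' @export
amplitude_map <- function(potential, scale) {
  if (length(potential) != length(scale) || length(potential) == 0)
    stop_invalid("potential and scale must be equal-length, non-empty")
  if (anyDuplicated(round(potential, 9)))
    stop_invalid("duplicate potentials in amplitude map")
  structure(data.frame(potential = potential, scale = scale),
            class = c("amplitude_map", "data.frame"))
}

as_amplitude_map <- function(x) {
  if (inherits(x, "amplitude_map")) return(x)
  if (is.numeric(x) && !is.null(names(x)))
    return(amplitude_map(as.numeric(names(x)), unname(x)))
  if (is.data.frame(x) && all(c("potential", "scale") %in% names(x)))
    return(amplitude_map(x$potential, x$scale))
  stop_invalid("amplitudes must be an amplitude_map, a named numeric vector, or a data.frame with columns potential and scale")
}

amplitude_at <- function(amplitudes, potential, tol = 1e-9) {
  amp <- as_amplitude_map(amplitudes)
  vapply(potential, function(E) {
    i <- which(abs(amp$potential - E) <= tol)
    if (length(i) != 1)
      stop_invalid(sprintf("no amplitude defined for potential %g V", E))
    amp$scale[i]
  }, numeric(1))
}

#' Sampled electrochemical trace
#'
#' Container for a sampled time series of (time, electrode potential,
#' current) with experiment metadata, the common currency between the
#' simulators, the fitting routines and the plain-text I/O.
#'
#' @param time_s strictly increasing sample times (s).
#' @param potential_V electrode potential at each sample (V vs SHE).
#' @param current current at each sample (units given in `metadata`).
#' @param metadata named list; recognised entries are `pH`,
#'   `temperature_K`, `scan_rate_V_s`, `rotation_rpm`, `units`.
#' @return An object of class `pfe_trace` (a data.frame).
#' @export
pfe_trace <- function(time_s, potential_V, current, metadata = list()) {
  n <- length(time_s)
  if (length(potential_V) != n || length(current) != n)
    stop_invalid("time, potential and current must have equal length")
  if (n > 1 && any(diff(time_s) <= 0))
    stop_invalid("time values must be strictly increasing")
  structure(
    data.frame(time_s = time_s, potential_V = potential_V,
               current = current),
    metadata = metadata,
    class = c("pfe_trace", "data.frame")
  )
}

#' @export
print.pfe_trace <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("PFE trace: %d samples, t = [%g, %g] s", nrow(x),
              min(x$time_s), max(x$time_s)))
  if (!is.null(md$pH)) cat(sprintf(", pH %g", md$pH))
  if (!is.null(md$scan_rate_V_s))
    cat(sprintf(", scan rate %g V/s", md$scan_rate_V_s))
  cat("\n")
  invisible(x)
}

#' @export
plot.pfe_trace <- function(x, ..., against = c("time", "potential")) {
  against <- match.arg(against)
  if (against == "time")
    plot(x$time_s, x$current, type = "l", xlab = "time (s)",
         ylab = "current", ...)
  else
    plot(x$potential_V, x$current, type = "l",
         xlab = "potential (V vs SHE)", ylab = "current", ...)
  invisible(x)
}

trace_metadata <- function(trace) attr(trace, "metadata") %||% list()
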