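#' Subtract a background (blank) trace
#'
#' Removes the non-faradaic capacitive background recorded in a control
#' experiment without enzyme: the blank current is interpolated onto
#' the trace's time grid and subtracted pointwise.  The blank must
#' cover the trace's time range.
#'
#' @param trace,blank [pfe_trace()] objects on the same protocol.
#' @return A [pfe_trace()] with the blank removed.
#' @export
subtract_background <- function(trace, blank) {
  stopifnot(inherits(trace, "pfe_trace"), inherits(blank, "pfe_trace"))
  tol <- 1e-9
  if (min(blank$time_s) > min(trace$time_s) + tol ||
      max(blank$time_s) < max(trace$time_s) - tol)
    stop_invalid("blank does not cover the trace's time range")
  bg <- stats::approx(blank$time_s, blank$current, xout = trace$time_s,
                      rule = 2)$y
  pfe_trace(trace$time_s, trace$potential_V, trace$current - bg,
            metadata = trace_metadata(trace))
}

#' Residual activity after the O2-exposure protocol
#'
#' Ratio (in percent) of the reductive plateau current after the
#' five-phase O2-exposure protocol to the plateau before it:
#' `100 * mean(|i|, last plateau_window of P5) /
#'        mean(|i|, last plateau_window of P1)`.
#' 100% means complete protection (the cap locked the enzyme in Hinact
#' before O2 arrived); small values mean the film was irreversibly
#' damaged.
#'
#' @param trace a [pfe_trace()] of the five-phase experiment.
#' @param phases the five phase start times (s), strictly increasing —
#'   a numeric vector or an [o2_experiment_spec()].
#' @param plateau_window averaging window length (s); must be shorter
#'   than both P1 and P5.
#' @return Residual activity in percent.
#' @export
residual_activity <- function(trace, phases, plateau_window = 50) {
  stopifnot(inherits(trace, "pfe_trace"))
  if (inherits(phases, "o2_experiment_spec")) phases <- phases$phase_times
  if (length(phases) != 5 || any(diff(phases) <= 0))
    stop_invalid("phases must be 5 strictly increasing start times")
  t_end <- max(trace$time_s)
  if (phases[5] >= t_end || phases[1] < min(trace$time_s) - 1e-9)
    stop_invalid("phases must lie within the trace")
  if (plateau_window <= 0 ||
      plateau_window > (phases[2] - phases[1]) ||
      plateau_window > (t_end - phases[5]))
    stop_invalid("plateau_window must be positive and shorter than P1 and P5")
  w1 <- trace$time_s >= (phases[2] - plateau_window) &
    trace$time_s < phases[2]
  w5 <- trace$time_s >= (t_end - plateau_window)
  if (!any(w1) || !any(w5)) stop_invalid("empty plateau window")
  100 * mean(abs(trace$current[w5])) / mean(abs(trace$current[w1]))
}

#' Potential of the forward-sweep current maximum of a CV
#'
#' Splits a cyclic voltammogram into forward and backward branches by
#' the sign of dE/dt (median-filtered over 5 points) and returns the
#' electrode potential at which the forward-branch current is maximal.
#' For a catalytic wave without oxidative inactivation this is the
#' vertex potential; anaerobic inactivation pulls the maximum below the
#' vertex (peak-then-decay shape), and the stronger the inactivation
#' the lower the peak potential.
#'
#' @param cv a [pfe_trace()] containing one forward sweep.
#' @param smooth_k odd window length for optional running-median
#'   smoothing of the current before locating the maximum (1 = no
#'   smoothing).
#' @return Potential (V vs SHE) of the forward-branch current maximum.
#' @export
cv_onset <- function(cv, smooth_k = 1) {
  stopifnot(inherits(cv, "pfe_trace"))
  if (nrow(cv) < 7) stop_invalid("trace too short for sweep detection")
  d <- sign(diff(cv$potential_V))
  ds <- stats::runmed(d, 5)
  nz <- which(ds != 0)
  if (length(nz) == 0) stop_invalid("no potential sweep detected")
  dirn <- ds[nz[1]]
  rev_at <- which(ds == -dirn)
  fwd_last <- if (length(rev_at) == 0) length(ds) else rev_at[1] - 1
  fwd <- seq_len(fwd_last + 1)          # diff index i -> samples i, i+1
  if (length(fwd) < 3) stop_invalid("no forward sweep detected")
  cur <- cv$current[fwd]
  if (smooth_k > 1) cur <- stats::runmed(cur, smooth_k)
  cv$potential_V[fwd[which.max(cur)]]
}
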