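#' Rate-generator matrix of the AAI scheme
#'
#' Builds the 3x3 generator `G` of the linear master equation
#' `ds/dt = G s` over the state vector `(a1, a2, h_inact)`.  Columns
#' index the source state, rows the destination, so each column sums to
#' zero and the off-diagonal entries are the scheme's rates
#' (A1 -> A2 = k1, A2 -> A1 = k_neg1, A2 -> Hinact = k_inact,
#' Hinact -> A2 = k_react; there is no direct A1 <-> Hinact path).
#'
#' @param rc a [rate_constants()] object.
#' @return A 3x3 numeric matrix with `dimnames` over
#'   `c("a1", "a2", "h_inact")`.
#' @examples
#' build_generator(rate_constants(0.061, 0.016, 0.42, 0.17))
#' @export
build_generator <- function(rc) {
  rc <- as_rate_constants(rc)
  k1 <- rc[["k1"]]; km1 <- rc[["k_neg1"]]
  ki <- rc[["k_inact"]]; kr <- rc[["k_react"]]
  s <- c("a1", "a2", "h_inact")
  matrix(c(-k1,        km1,         0,
            k1, -(km1 + ki),       kr,
             0,          ki,      -kr),
         nrow = 3, byrow = TRUE, dimnames = list(s, s))
}

as_rate_constants <- function(rc) {
  if (inherits(rc, "rate_constants")) return(rc)
  if (is.numeric(rc) && length(rc) == 4)
    return(rate_constants(rc[[1]], rc[[2]], rc[[3]], rc[[4]]))
  stop_invalid("expected a rate_constants object")
}

# Eigendecomposition of the generator, with a scaling-and-squaring
# matrix-exponential fallback when eigenvalues are (near-)repeated
# (relative gap < 1e-9) or the eigenvector basis is ill-conditioned.
# The chain's generator is similar to a symmetric matrix whenever both
# backward rates are positive, so the spectrum is real; complex parts
# only ever arise as numerical noise and are dropped.
generator_spectral <- function(G) {
  e <- eigen(G, symmetric = FALSE)
  lam <- e$values
  scale <- max(abs(lam), 1)
  if (max(abs(Im(lam))) <= 1e-9 * scale) {
    lam <- Re(lam)
    V <- Re(e$vectors)
  } else {
    V <- e$vectors
  }
  gaps <- abs(outer(lam, lam, "-"))
  diag(gaps) <- Inf
  if (min(gaps) / scale >= 1e-9) {
    Vinv <- tryCatch(solve(V), error = function(e) NULL)
    # cheap conditioning check: the decomposition must reconstruct G
    if (!is.null(Vinv) &&
        max(abs(V %*% (lam * Vinv) - G)) <= 1e-8 * scale)
      return(list(method = "eigen", values = lam, vectors = V,
                  vinv = Vinv))
  }
  list(method = "expm", G = G)
}

# Propagate an initial state over a vector of non-negative lags using a
# precomputed spectral decomposition.  Returns a 3 x length(dt) matrix.
propagate_spectral <- function(sp, s0, dt) {
  if (sp$method == "eigen") {
    coef <- as.vector(sp$vinv %*% s0)
    out <- Re(sp$vectors %*% (exp(outer(sp$values, dt)) * coef))
  } else {
    out <- vapply(dt, function(h) {
      as.numeric(Matrix::expm(sp$G * h) %*% s0)
    }, numeric(3))
    out <- matrix(out, nrow = 3)
  }
  pmin(pmax(out, 0), 1)
}

# As propagate_spectral, building the decomposition from rate constants.
propagate_grid <- function(state, rc, dt) {
  sp <- generator_spectral(build_generator(rc))
  out <- propagate_spectral(sp, as.numeric(state), dt)
  rownames(out) <- c("a1", "a2", "h_inact")
  out
}

#' Propagate AAI state fractions over a time interval
#'
#' Exact solution of the linear master equation `ds/dt = G s` for the
#' three-state AAI scheme under constant conditions, via
#' eigendecomposition of the generator (with a matrix-exponential
#' fallback for degenerate spectra).  The output sums to 1 and each
#' fraction stays in [0, 1].
#'
#' @param state a [state_fractions()] object (or numeric length-3 vector
#'   summing to 1).
#' @param rc a [rate_constants()] object.
#' @param dt time interval in seconds; must be >= 0.
#' @return A [state_fractions()] object.
#' @examples
#' s0 <- state_fractions(1, 0, 0)
#' propagate(s0, rate_constants(0.061, 0.016, 0.42, 0.17), dt = 10)
#' @export
propagate <- function(state, rc, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || is.na(dt) || dt < 0)
    stop_invalid("dt must be a single non-negative number")
  state <- as_state(state)
  if (dt == 0) return(state)
  out <- propagate_grid(state, rc, dt)[, 1]
  state_fractions(out[[1]], out[[2]], out[[3]])
}

as_state <- function(state) {
  if (inherits(state, "state_fractions")) return(state)
  if (is.numeric(state) && length(state) == 3)
    return(state_fractions(state[[1]], state[[2]], state[[3]]))
  stop_invalid("expected state fractions (length-3 numeric summing to 1)")
}

#' Steady state of the AAI scheme
#'
#' Closed-form stationary distribution of the linear chain, proportional
#' to `(1, k1/k_neg1, k1 * k_inact / (k_neg1 * k_react))`.  Degenerate
#' chains with an irreversible step return the corresponding absorbing
#' limit; chains with a fully detached edge (both rates of a step zero,
#' or two absorbing ends) have no unique stationary distribution and
#' raise an error.
#'
#' At oxidising potentials, where the reactivation rate `k_react` drops
#' below `k_inact`, the stationary distribution concentrates in Hinact:
#' the enzyme locks itself behind the safety cap.
#'
#' @param rc a [rate_constants()] object.
#' @return A [state_fractions()] object; also the `dt -> Inf` limit of
#'   [propagate()].
#' @export
steady_state <- function(rc) {
  rc <- as_rate_constants(rc)
  k1 <- rc[["k1"]]; km1 <- rc[["k_neg1"]]
  ki <- rc[["k_inact"]]; kr <- rc[["k_react"]]
  if (all(rc == 0))
    stop_invalid("all rates are zero: no unique steady state")
  if (k1 == 0 && km1 == 0)
    stop_invalid("A1 <-> A2 edge detached: no unique steady state")
  if (ki == 0 && kr == 0)
    stop_invalid("A2 <-> Hinact edge detached: no unique steady state")
  r21 <- if (km1 > 0) k1 / km1 else Inf
  r32 <- if (kr > 0) ki / kr else Inf
  if (is.infinite(r21)) {
    w <- if (is.infinite(r32)) c(0, 0, 1) else c(0, 1, r32)
  } else if (is.infinite(r32)) {
    # Hinact absorbing; reachable only if forward flux exists
    if (k1 == 0)
      stop_invalid("two absorbing states (A1 and Hinact): no unique steady state")
    w <- c(0, 0, 1)
  } else {
    w <- c(1, r21, r21 * r32)
  }
  w <- w / sum(w)
  state_fractions(w[[1]], w[[2]], w[[3]])
}

#' Relaxation rates of the AAI scheme
#'
#' Magnitudes of the non-zero eigenvalues of the generator — the inverse
#' time constants of the (bi-exponential) current relaxations observed
#' after a potential step.  In the decoupled limit these approach
#' `k1 + k_neg1` (slow conformational phase) and `k_inact + k_react`
#' (fast cap-binding phase).
#'
#' @param rc a [rate_constants()] object.
#' @return Numeric vector (length 2, or fewer for degenerate chains) of
#'   relaxation rates in 1/s, sorted increasingly.
#' @export
relaxation_rates <- function(rc) {
  rc <- as_rate_constants(rc)
  G <- build_generator(rc)
  lam <- Re(eigen(G, only.values = TRUE)$values)
  mag <- sort(abs(lam))          # structural zero mode first
  mag <- mag[-1]
  tol <- 1e-12 * max(1, sum(rc))
  sort(mag[mag > tol])
}

#' Propagate the two-state inactivation model
#'
#' Analytic mono-exponential relaxation of the active fraction towards
#' `k_react / (k_inact + k_react)` with rate `k_inact + k_react`.
#'
#' @param active_fraction active fraction in [0, 1] at time zero.
#' @param rc2 a [two_state_rates()] object.
#' @param dt time lag(s) in seconds, all >= 0 (vectorised).
#' @return Active fraction(s) after `dt`.
#' @export
propagate_two_state <- function(active_fraction, rc2, dt) {
  if (!inherits(rc2, "two_state_rates"))
    stop_invalid("rc2 must be a two_state_rates object")
  if (any(dt < 0) || anyNA(dt)) stop_invalid("dt must be non-negative")
  if (any(active_fraction < 0 | active_fraction > 1))
    stop_invalid("active_fraction must lie in [0, 1]")
  ktot <- rc2[["k_inact"]] + rc2[["k_react"]]
  if (ktot == 0) return(rep(active_fraction, length.out = length(dt)))
  a_inf <- rc2[["k_react"]] / ktot
  a_inf + (active_fraction - a_inf) * exp(-ktot * dt)
}
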