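test_that("the generator encodes the linear chain", {
  G <- build_generator(wt_base())
  expect_equal(unname(diag(G)), c(-0.061, -0.436, -0.17))
  expect_equal(G["a2", "a1"], 0.061)   # A1 -> A2
  expect_equal(G["a1", "a2"], 0.016)   # A2 -> A1
  expect_equal(G["h_inact", "a2"], 0.42)
  expect_equal(G["a2", "h_inact"], 0.17)
  expect_equal(G["h_inact", "a1"], 0)  # no direct A1 <-> Hinact path
  expect_equal(G["a1", "h_inact"], 0)

  expect_equal(build_generator(rate_constants(0, 0, 0, 0)),
               matrix(0, 3, 3, dimnames = dimnames(G)))
  expect_error(rate_constants(-0.1, 0, 0, 0),
               class = "capkin_invalid_parameter")
})

test_that("random generators are column-conservative and stable", {
  withr::with_seed(1, {
    for (i in 1:50) {
      rc <- rate_constants(runif(1, 0, 10), runif(1, 0, 10),
                           runif(1, 0, 10), runif(1, 0, 10))
      G <- build_generator(rc)
      expect_equal(unname(colSums(G)), c(0, 0, 0))
      expect_true(all(Re(eigen(G, only.values = TRUE)$values) <= 1e-12))
    }
  })
})

test_that("propagation solves the master equation exactly", {
  s0 <- state_fractions(1, 0, 0)
  expect_equal(propagate(s0, wt_base(), 0), s0)
  expect_error(propagate(s0, wt_base(), -1),
               class = "capkin_invalid_parameter")

  # symmetric chain equilibrates to equipartition
  sym <- rate_constants(1, 1, 1, 1)
  expect_equal(as.numeric(propagate(s0, sym, 100)), rep(1 / 3, 3),
               tolerance = 1e-6)

  # against an independent fixed-step RK4 integration (deSolve)
  G <- build_generator(wt_base())
  sol <- deSolve::rk4(c(1, 0, 0), times = seq(0, 10, by = 1e-3),
                      func = function(t, y, p) list(as.numeric(G %*% y)),
                      parms = NULL)
  oracle <- sol[nrow(sol), 2:4]
  got <- as.numeric(propagate(s0, wt_base(), 10))
  expect_lt(max(abs(got - oracle)), 1e-8)
})

test_that("propagation conserves total enzyme for random rates and times", {
  withr::with_seed(42, {
    for (i in 1:60) {
      rc <- rate_constants(runif(1, 0, 10), runif(1, 0, 10),
                           runif(1, 0, 10), runif(1, 0, 10))
      s0 <- as.numeric(stats::rgamma(3, 1)); s0 <- s0 / sum(s0)
      dt <- runif(1, 0, 100)
      out <- propagate(state_fractions(s0[1], s0[2], s0[3]), rc, dt)
      expect_lt(abs(sum(out) - 1), 1e-9)
      expect_true(all(out >= 0 & out <= 1))
    }
  })
})

test_that("degenerate spectra fall back to the matrix exponential", {
  # equal eigenvalue pair: k1 = k_neg1 = 0 detaches A1 and leaves a
  # repeated zero eigenvalue
  rc <- rate_constants(0, 0, 0.3, 0.1)
  out <- propagate(state_fractions(0.2, 0.5, 0.3), rc, 5)
  expect_equal(out[["a1"]], 0.2)     # detached state holds its mass
  expect_lt(abs(sum(out) - 1), 1e-9)
  # agreement with deSolve on the same degenerate chain
  G <- build_generator(rc)
  sol <- deSolve::rk4(c(0.2, 0.5, 0.3), times = seq(0, 5, by = 1e-3),
                      func = function(t, y, p) list(as.numeric(G %*% y)),
                      parms = NULL)
  expect_lt(max(abs(as.numeric(out) - sol[nrow(sol), 2:4])), 1e-8)
})

test_that("steady state matches the closed-form chain ratio", {
  expect_equal(as.numeric(steady_state(rate_constants(1, 1, 1, 1))),
               rep(1 / 3, 3))

  # detached third state
  st <- steady_state(rate_constants(0.3, 0.6, 0, 0.5))
  expect_equal(st[["h_inact"]], 0)
  expect_equal(st[["a1"]] / st[["a2"]], 0.6 / 0.3)

  # wild-type: detailed-balance ratios 1 : k1/k-1 : k1*ki/(k-1*kr)
  rc <- wt_base()
  w <- c(1, 0.061 / 0.016, (0.061 * 0.42) / (0.016 * 0.17))
  expect_equal(w[2], 3.8125)
  expect_equal(w[3], 9.419118, tolerance = 1e-6)
  expect_equal(as.numeric(steady_state(rc)), w / sum(w), tolerance = 1e-12)

  # equals the long-time limit of propagation
  long <- propagate(state_fractions(1, 0, 0), rc, 1e4)
  expect_lt(max(abs(as.numeric(long) - as.numeric(steady_state(rc)))), 1e-6)

  expect_error(steady_state(rate_constants(0, 0, 0, 0)),
               class = "capkin_invalid_parameter")
  # two absorbing ends: no unique stationary distribution
  expect_error(steady_state(rate_constants(0, 0.5, 0.4, 0)),
               class = "capkin_invalid_parameter")
})

test_that("absorbing limits of the steady state", {
  # irreversible inactivation locks everything in Hinact
  st <- steady_state(rate_constants(0.1, 0.2, 0.3, 0))
  expect_equal(as.numeric(st), c(0, 0, 1))
  # irreversible A1 depletion leaves the A2 <-> Hinact balance
  st2 <- steady_state(rate_constants(0.5, 0, 0.3, 0.1))
  expect_equal(as.numeric(st2), c(0, 0.1, 0.3) / 0.4)
})

test_that("steady-state Hinact is monotone in the cap-binding rates", {
  base <- wt_base()
  h_of <- function(ki, kr)
    steady_state(rate_constants(base[["k1"]], base[["k_neg1"]],
                                ki, kr))[["h_inact"]]
  ki_grid <- seq(0.05, 2, length.out = 8)
  expect_true(all(diff(vapply(ki_grid, h_of, numeric(1),
                              kr = 0.17)) >= 0))
  kr_grid <- seq(0.02, 2, length.out = 8)
  expect_true(all(diff(vapply(kr_grid, function(kr) h_of(0.42, kr),
                              numeric(1))) <= 0))
})

test_that("relaxation rates reduce to the decoupled limits", {
  # detached cap step: single non-zero rate k1 + k_neg1
  r <- relaxation_rates(rate_constants(0.3, 0.5, 0, 0))
  expect_equal(r, 0.8)

  # linearity: scaling all rates scales the spectrum
  rc <- wt_base()
  r1 <- relaxation_rates(rc)
  r2 <- relaxation_rates(rate_constants(3 * rc[["k1"]], 3 * rc[["k_neg1"]],
                                        3 * rc[["k_inact"]],
                                        3 * rc[["k_react"]]))
  expect_equal(r2, 3 * r1, tolerance = 1e-12)

  # against the characteristic polynomial of the generator
  G <- build_generator(rc)
  tr <- sum(diag(G))
  m2 <- sum(vapply(1:3, function(i) det(G[-i, -i, drop = FALSE]),
                   numeric(1)))
  roots <- polyroot(c(0, m2, -tr, 1))
  mag <- sort(Mod(roots))[-1]
  expect_equal(r1, mag, tolerance = 1e-10)
})

test_that("two-state relaxation is the analytic mono-exponential", {
  rc2 <- two_state_rates(0.42, 0.17)
  expect_equal(propagate_two_state(0.7, rc2, 0), 0.7)
  expect_error(propagate_two_state(0.7, rc2, -1),
               class = "capkin_invalid_parameter")
  expect_equal(propagate_two_state(1, two_state_rates(0.3, 0.3), 1e4), 0.5)

  # against numerical integration
  sol <- deSolve::rk4(c(a = 1), times = seq(0, 1, by = 1e-4),
                      func = function(t, y, p)
                        list(-0.42 * y + 0.17 * (1 - y)), parms = NULL)
  expect_lt(abs(propagate_two_state(1, rc2, 1) - sol[nrow(sol), 2]), 1e-10)
})

test_that("fast conformational pre-equilibrium pools to the two-state model", {
  # k1 = k_neg1 = 1000/s: A1 and A2 stay equimolar, so the pooled
  # active fraction obeys the two-state model with k_inact halved
  rc3 <- rate_constants(1000, 1000, 0.42, 0.17)
  rc2 <- two_state_rates(0.42 / 2, 0.17)
  w <- activity_weights(0.5)
  t_grid <- seq(0.1, 60, by = 0.5)
  st <- propagate_grid(state_fractions(0.5, 0.5, 0), rc3, t_grid)
  act3 <- w[["alpha1"]] * st["a1", ] + w[["alpha2"]] * st["a2", ]
  act2 <- propagate_two_state(1, rc2, t_grid) * (1 + 0.5) / 2
  expect_lt(max(abs(act3 - act2) / act2), 0.01)
})

test_that("the current model scales activity by per-potential amplitudes", {
  prot <- protocol(c(-0.31), 50)
  tr <- simulate_current(prot, wt_base(), activity_weights(0.5),
                         amplitude_map(-0.31, 1))
  expect_equal(tr$current[1], 1)   # pure A1, alpha1 = 1, amplitude 1

  # long hold approaches amplitude x weighted steady activity
  lock <- rate_constants(0.061, 0.016, 0.42, 0.002) # k_react << k_inact
  prot2 <- protocol(-0.21, 5000)
  tr2 <- simulate_current(prot2, lock, activity_weights(0.5),
                          amplitude_map(-0.21, 2))
  st <- steady_state(lock)
  expect_equal(tr2$current[nrow(tr2)],
               2 * (st[["a1"]] + 0.5 * st[["a2"]]), tolerance = 1e-4)

  expect_error(
    simulate_current(std_protocol(), wt_base(), activity_weights(),
                     amplitude_map(-0.31, 1)),
    class = "capkin_invalid_parameter") # missing amplitude at -0.21
})

test_that("state is continuous but current jumps at step boundaries", {
  prot <- std_protocol()
  tr <- simulate_current(prot, list(base = wt_base(), law = wt_law()),
                         activity_weights(), std_amps())
  st <- attr(tr, "states")
  expect_true(all(abs(colSums(st) - 1) < 1e-9))
  # boundary at t = 50 s: potential changes, current jumps with it
  i50 <- which(tr$time_s == 50)
  expect_equal(tr$potential_V[i50], -0.21)
  expect_equal(tr$potential_V[i50 - 1], -0.31)
  jump <- abs(tr$current[i50] - tr$current[i50 - 1])
  typical <- stats::median(abs(diff(tr$current[2:i50 - 1])))
  expect_gt(jump, 50 * typical)
})

test_that("step relaxations are genuinely bi-exponential", {
  prot <- protocol(c(-0.31, -0.21), c(50, 120))
  tr <- simulate_current(prot, list(base = wt_base(), law = wt_law()),
                         activity_weights(), std_amps())
  sel <- tr$time_s >= 50
  t <- tr$time_s[sel] - 50
  y <- tr$current[sel]
  ssr_exp_fit <- function(n_exp) {
    par0 <- if (n_exp == 1) c(log(0.3), 0.1, 0.3) else
      c(log(0.06), log(0.6), 0.1, 0.2, 0.2)
    fn <- function(p) {
      if (n_exp == 1) p[3] + p[2] * exp(-exp(p[1]) * t) - y
      else p[5] + p[3] * exp(-exp(p[1]) * t) + p[4] * exp(-exp(p[2]) * t) - y
    }
    minpack.lm::nls.lm(par0, fn = fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500))$deviance
  }
  expect_gt(ssr_exp_fit(1) / ssr_exp_fit(2), 10)
})

test_that("CV hysteresis appears exactly when inactivation is active", {
  sweep <- list(E_start = -0.56, E_vertex = -0.05, scan_rate = 0.003)
  # no inactivation: forward and backward branches coincide
  no_inact <- rate_constants(0.061, 0.016, 0, 0)
  cv0 <- simulate_cv(sweep, no_inact, wt_law(), sample_hz = 10)
  n <- nrow(cv0)
  half <- (n + 1) / 2
  fwd <- 1:(half - 1); bwd <- n:(half + 1)
  expect_equal(cv0$potential_V[fwd], cv0$potential_V[bwd], tolerance = 1e-12)
  expect_lt(max(abs(cv0$current[fwd] - cv0$current[bwd])), 1e-9)

  # wild-type-like: forward maximum below the vertex, branches split
  cv1 <- simulate_cv(sweep, wt_base(), wt_law(), sample_hz = 10)
  imax <- which.max(cv1$current[fwd])
  expect_lt(cv1$potential_V[fwd][imax], sweep$E_vertex - 0.02)
  expect_gt(max(abs(cv1$current[fwd] - cv1$current[bwd])), 0.05)

  # faster sweep reaches the vertex with less inactive enzyme
  cv_fast <- simulate_cv(list(E_start = -0.56, E_vertex = -0.05,
                              scan_rate = 0.006),
                         wt_base(), wt_law(), sample_hz = 10)
  h_at_vertex <- function(cv) {
    iv <- which.max(cv$potential_V)
    attr(cv, "states")["h_inact", iv]
  }
  expect_lt(h_at_vertex(cv_fast), h_at_vertex(cv1))
})
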