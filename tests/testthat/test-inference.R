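test_that("background subtraction removes the capacitive component", {
  prot <- small_protocol()
  cap <- capacitive_spec(peak_amplitude = 0.4, tau = 0.8)
  tr <- generate_chronoamperogram(prot, wt_truth(), activity_weights(),
                                  std_amps(), noise = noise_spec(0, 1),
                                  capacitive = cap)
  blank0 <- generate_blank(prot, cap, noise = noise_spec(0, 2))

  # blank identical to trace -> zero current
  zero <- subtract_background(tr, tr)
  expect_equal(zero$current, rep(0, nrow(tr)))

  # blank of zeros -> unchanged
  null_blank <- pfe_trace(tr$time_s, tr$potential_V, rep(0, nrow(tr)))
  expect_equal(subtract_background(tr, null_blank)$current, tr$current)

  # noise-free capacitive blank recovers the enzymatic core exactly
  clean <- subtract_background(tr, blank0)
  expect_equal(clean$current, attr(tr, "truth")$enzymatic,
               tolerance = 1e-12)

  # with noise on both, recovery is within the combined noise scale
  sd_rel <- 0.01
  trn <- generate_chronoamperogram(prot, wt_truth(), activity_weights(),
                                   std_amps(),
                                   noise = noise_spec(sd_rel, 3),
                                   capacitive = cap)
  blankn <- generate_blank(prot, cap, noise = noise_spec(sd_rel, 4))
  cleann <- subtract_background(trn, blankn)
  resid <- cleann$current - attr(trn, "truth")$enzymatic
  noise_sd <- sd_rel * max(abs(attr(trn, "truth")$noise_free))
  expect_lt(stats::sd(resid), 2.5 * noise_sd)

  # non-overlapping time ranges are refused
  short <- pfe_trace(tr$time_s[1:10], tr$potential_V[1:10],
                     tr$current[1:10])
  expect_error(subtract_background(tr, short),
               class = "capkin_invalid_parameter")
})

test_that("noiseless AAI data are recovered essentially exactly", {
  res <- noiseless_aai_fit()
  fit <- res$fit
  truth <- wt_base()
  expect_lt(abs(fit$shared[["k1"]] - truth[["k1"]]) / truth[["k1"]], 1e-3)
  expect_lt(abs(fit$shared[["k_neg1"]] - truth[["k_neg1"]]) /
              truth[["k_neg1"]], 1e-3)
  expect_lt(abs(fit$shared[["k_inact"]] - truth[["k_inact"]]) /
              truth[["k_inact"]], 1e-3)
  kr <- fit$kreact_table
  truth_kr <- evaluate_kreact(wt_law(), kr$potential)
  expect_lt(max(abs(kr$k_react - truth_kr) / truth_kr), 1e-3)
  # amplitudes are recovered too
  expect_equal(fit$amplitudes$scale[match(c(-0.31, -0.21),
                                          fit$amplitudes$potential)],
               c(0.7, 1), tolerance = 1e-3)
  expect_true(all(fit$kreact_table$se >= 0))
})

test_that("the AAI fit is never worse than the nested two-state fit", {
  res <- noiseless_aai_fit()
  prot <- std_protocol()
  fit2 <- fit_model(res$trace, prot, "two_state", fast_fit_options())
  expect_gt(fit2$ssr, res$fit$ssr)
  cmp <- compare_models(fit2, res$fit)
  expect_equal(cmp$preferred, "aai")
  expect_gt(cmp$aic_delta, 0)
})

test_that("fitting is invariant to current rescaling up to amplitudes", {
  res <- noiseless_aai_fit()
  prot <- std_protocol()
  tr <- res$trace
  scaled <- pfe_trace(tr$time_s, tr$potential_V, 3.7 * tr$current,
                      metadata = trace_metadata(tr))
  fit_s <- fit_model(scaled, prot, "aai", fast_fit_options())
  expect_equal(fit_s$shared, res$fit$shared, tolerance = 1e-6)
  expect_equal(fit_s$amplitudes$scale, 3.7 * res$fit$amplitudes$scale,
               tolerance = 1e-6)
})

test_that("insufficient points per step are refused", {
  prot <- std_protocol()
  res <- noiseless_aai_fit()
  expect_error(
    fit_model(res$trace, prot, "aai",
              fast_fit_options(mask_after_step = 49.5)),
    class = "capkin_fit_error")
})

test_that("model comparison statistics follow the nested F/AIC forms", {
  mk <- function(kind, ssr, n, p)
    structure(list(model_kind = kind, ssr = ssr, n_points = n,
                   n_params = p), class = "capkin_fit")
  # identical fits: F = 0, aic_delta equals the parameter penalty
  cmp <- compare_models(mk("two_state", 1.0, 500, 5), mk("aai", 1.0, 500, 7))
  expect_equal(cmp$f_statistic, 0)
  expect_equal(cmp$aic_delta, 2 * (5 - 7))
  expect_equal(cmp$preferred, "two_state")

  # a decisive improvement prefers the AAI model
  cmp2 <- compare_models(mk("two_state", 2.0, 500, 5), mk("aai", 1.0, 500, 7))
  expect_equal(cmp2$f_statistic,
               ((2 - 1) / 2) / (1 / (500 - 7)))
  expect_equal(cmp2$aic_delta, 500 * log(2) - 4)
  expect_equal(cmp2$preferred, "aai")

  # argument order does not matter
  cmp3 <- compare_models(mk("aai", 1.0, 500, 7), mk("two_state", 2.0, 500, 5))
  expect_equal(cmp3$f_statistic, cmp2$f_statistic)

  expect_error(compare_models(mk("two_state", 1, 400, 5),
                              mk("aai", 1, 500, 7)),
               class = "capkin_invalid_parameter")
  expect_error(compare_models(mk("aai", 1, 500, 7), mk("aai", 1, 500, 7)),
               class = "capkin_invalid_parameter")
})

test_that("k_react profiling recovers the exponential potential law", {
  res <- noiseless_aai_fit()
  prof <- estimate_kreact_profile(list(res$fit), fit_law = TRUE,
                                  E_ref = -0.21)
  expect_equal(nrow(prof$table), 2)
  expect_equal(prof$law$slope, 15, tolerance = 0.05)
  expect_equal(prof$law$k0, 0.17, tolerance = 0.05)

  # constant k_react across potential -> slope ~ 0 (table assembled
  # from synthetic fits)
  mkfit <- function(pots, kr, pH)
    structure(list(kreact_table = data.frame(potential = pots,
                                             k_react = kr, se = NA_real_),
                   pH = pH), class = "capkin_fit")
  flat <- estimate_kreact_profile(
    list(mkfit(c(-0.31, -0.21, -0.11), c(0.2, 0.2, 0.2), 7)),
    fit_law = TRUE)
  expect_lt(abs(flat$law$slope), 1e-8)

  # pH ordering is preserved in the assembled table
  prof3 <- estimate_kreact_profile(list(
    mkfit(-0.196, 0.015, 10), mkfit(-0.196, 0.069, 8.5),
    mkfit(-0.196, 0.17, 7)))
  ord <- order(prof3$table$pH)
  expect_true(all(diff(prof3$table$k_react[ord]) < 0))

  expect_error(estimate_kreact_profile(list(mkfit(-0.2, 0.1, 7)),
                                       fit_law = TRUE),
               class = "capkin_invalid_parameter")
})

test_that("recovery study is unbiased without noise and seed-stable", {
  prot <- small_protocol()
  rs <- recovery_study(wt_truth(), prot, noise_sd = 0, n_reps = 2,
                       seed = 5, amplitudes = std_amps(),
                       fit_options = fast_fit_options())
  expect_true(all(abs(rs$rel_bias) < 1e-3))
  expect_true(all(abs(rs$rel_rmse) < 1e-3))

  rs2 <- recovery_study(wt_truth(), prot, noise_sd = 0, n_reps = 2,
                        seed = 5, amplitudes = std_amps(),
                        fit_options = fast_fit_options())
  expect_identical(attr(rs, "estimates"), attr(rs2, "estimates"))
})

test_that("more noise never improves recovery error", {
  prot <- small_protocol()
  lo <- recovery_study(wt_truth(), prot, noise_sd = 0.005, n_reps = 3,
                       seed = 8, amplitudes = std_amps(),
                       fit_options = fast_fit_options())
  hi <- recovery_study(wt_truth(), prot, noise_sd = 0.01, n_reps = 3,
                       seed = 8, amplitudes = std_amps(),
                       fit_options = fast_fit_options())
  expect_gte(sum(hi$rel_rmse), sum(lo$rel_rmse))
})

test_that("residual activity is the plateau ratio and scale-invariant", {
  phases <- c(0, 200, 480, 900, 1300)
  t <- seq(0, 1700, by = 0.5)
  cur <- ifelse(t < 200, -1, ifelse(t < 1300, 0.05, -0.62))
  tr <- pfe_trace(t, ifelse(t >= 200 & t < 1300, 0, -0.8), cur)
  expect_equal(residual_activity(tr, phases, 50), 62)

  tr_eq <- pfe_trace(t, tr$potential_V, ifelse(t < 200, -1,
                                               ifelse(t < 1300, 0, -1)))
  expect_equal(residual_activity(tr_eq, phases, 50), 100)
  tr_half <- pfe_trace(t, tr$potential_V, ifelse(t < 200, -1,
                                                 ifelse(t < 1300, 0, -0.5)))
  expect_equal(residual_activity(tr_half, phases, 50), 50)

  scaled <- pfe_trace(t, tr$potential_V, 17 * cur)
  expect_equal(residual_activity(scaled, phases, 50),
               residual_activity(tr, phases, 50))

  expect_error(residual_activity(tr, phases, plateau_window = 300),
               class = "capkin_invalid_parameter")
  expect_error(residual_activity(tr, c(0, 10, 5, 900, 1300), 50),
               class = "capkin_invalid_parameter")
})

test_that("cv onset tracks the strength of oxidative inactivation", {
  sweep <- list(E_start = -0.56, E_vertex = -0.05, scan_rate = 0.005)
  no_inact <- rate_constants(0.061, 0.016, 0, 0)
  cv0 <- simulate_cv(sweep, no_inact, wt_law(), sample_hz = 5)
  expect_equal(cv_onset(cv0), sweep$E_vertex, tolerance = 2e-3)

  cv1 <- simulate_cv(sweep, wt_base(), wt_law(), sample_hz = 5)
  on1 <- cv_onset(cv1)
  expect_lt(on1, sweep$E_vertex - 0.02)

  strong <- rate_constants(0.061, 0.016, 4.2, 0.17)
  cv2 <- simulate_cv(sweep, strong, wt_law(), sample_hz = 5)
  expect_lt(cv_onset(cv2), on1)

  flat <- pfe_trace(0:19, rep(-0.3, 20), rnorm(20))
  expect_error(cv_onset(flat), class = "capkin_invalid_parameter")
})
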