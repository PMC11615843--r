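test_that("cumulative distribution counts dwells at or above each time", {
  cd <- cumulative_distribution(dwell_sample(c(1, 2, 3)))
  expect_equal(cd$t, c(1, 2, 3))
  expect_equal(cd$count, c(3, 2, 1))
  # ties share a point
  cd <- cumulative_distribution(dwell_sample(c(2, 2)))
  expect_equal(cd$t, 2)
  expect_equal(cd$count, 2)
  expect_error(cumulative_distribution(numeric(0)))
})

test_that("empirical cumulative curve stays inside the DKW band", {
  set.seed(12)
  n <- 1e4
  dw <- stats::rexp(n, 8)
  cd <- cumulative_distribution(dwell_sample(dw))
  band <- sqrt(log(2 / 0.01) / (2 * n))  # alpha = 0.01
  expect_true(all(abs(cd$count / n - exp(-8 * cd$t)) <= band))
})

test_that("half-frame correction subtracts frame_interval / 2", {
  s <- dwell_sample(c(0.156, 0.052), frame_interval = 0.052,
                    provenance = "detected")
  cs <- half_frame_correct(s)
  expect_equal(cs$dwells, c(0.130, 0.026))
  expect_true(cs$half_frame_corrected)
  expect_error(half_frame_correct(cs))  # no double correction
  # dwells at or below half a frame are dropped with a warning
  s2 <- dwell_sample(c(0.156, 0.020), frame_interval = 0.052,
                     provenance = "detected")
  expect_warning(c2 <- half_frame_correct(s2), "dropped")
  expect_length(c2$dwells, 1)
})

test_that("single-exponential rate is recovered within its CI", {
  set.seed(21)
  dw <- dwell_sample(stats::rexp(1e4, 2))
  fit <- fit_multiexp(cumulative_distribution(dw), 1)
  expect_true(fit$converged)
  expect_equal(fit$phases$rate, 2, tolerance = 0.05)
  # the asymptotic CI is finite, positive and brackets the estimate; it is
  # optimistic on correlated cumulative points, so allow a 2% slack on truth
  expect_true(fit$phases$rate_lo < fit$phases$rate &&
                fit$phases$rate < fit$phases$rate_hi)
  expect_lt(fit$phases$rate_lo, 2 * 1.02)
  expect_gt(fit$phases$rate_hi, 2 * 0.98)
  expect_equal(fit$phases$amplitude, 1)
})

test_that("two-phase parameters are recovered from mixture draws", {
  set.seed(22)
  dw <- dwell_sample(rmix_dwells(2e4, c(0.7, 0.3), c(8, 0.05)))
  fit <- fit_multiexp(cumulative_distribution(dw), 2)
  expect_equal(fit$phases$rate, c(8, 0.05), tolerance = 0.05)
  expect_equal(fit$phases$amplitude, c(0.7, 0.3), tolerance = 0.05)
  expect_equal(sum(fit$phases$amplitude), 1, tolerance = 1e-9)
  # maximum-likelihood cross-check on the raw dwells agrees
  ml <- fit_multiexp_ml(dw, 2)
  expect_equal(ml$rates, fit$phases$rate, tolerance = 0.05)
  expect_equal(ml$amplitudes, fit$phases$amplitude, tolerance = 0.05)
})

test_that("fits are asymptotically unbiased across replicates", {
  set.seed(23)
  reps <- 20
  est <- t(replicate(reps, {
    dw <- dwell_sample(rmix_dwells(1e4, c(0.714, 0.286), c(8, 0.05)))
    f <- fit_multiexp(cumulative_distribution(dw), 2)
    f$phases$rate
  }))
  expect_lt(abs(stats::median(est[, 1]) - 8) / 8, 0.05)
  expect_lt(abs(stats::median(est[, 2]) - 0.05) / 0.05, 0.05)
})

test_that("adding phases never increases the residual sum of squares", {
  set.seed(24)
  cd <- cumulative_distribution(
    dwell_sample(rmix_dwells(2000, c(0.8, 0.18, 0.02), c(7, 0.3, 0.03))))
  fits <- lapply(1:3, function(m) fit_multiexp(cd, m))
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  expect_true(all(diff(rss) <= 1e-6 * rss[1]))
})

test_that("AICc model comparison selects the generating model", {
  set.seed(25)
  # three phases with a rare slow component, detectable at N = 1000
  cd3 <- cumulative_distribution(
    dwell_sample(rmix_dwells(1000, c(0.82, 0.16, 0.02), c(7, 0.3, 0.03))))
  cmp3 <- compare_models(lapply(1:3, function(m) fit_multiexp(cd3, m)))
  expect_equal(cmp3$n_phases[cmp3$selected], 3L)
  # a single phase must not spawn spurious extra phases
  cd1 <- cumulative_distribution(dwell_sample(stats::rexp(1000, 2)))
  cmp1 <- compare_models(lapply(1:3, function(m) fit_multiexp(cd1, m)))
  expect_equal(cmp1$n_phases[cmp1$selected], 1L)
  # identical fits tie at delta AICc zero
  f <- fit_multiexp(cd1, 1)
  expect_equal(compare_models(list(f, f))$delta_aicc, c(0, 0))
  expect_error(compare_models(list(f, fit_multiexp(cd3, 1))))
})

test_that("dwell-time amplitude correction follows its defining arithmetic", {
  # equal rates: the correction is the identity
  ca <- correct_amplitudes_eq1(NULL, amplitudes = c(0.6, 0.4), rates = c(2, 2))
  expect_equal(ca$corrected, ca$observed)
  # two-phase example: (0.85/5) / (0.85/5 + 0.15/0.2)
  ca <- correct_amplitudes_eq1(NULL, amplitudes = c(0.85, 0.15),
                               rates = c(5, 0.2))
  expect_equal(ca$corrected[1], 0.17 / (0.17 + 0.75), tolerance = 1e-12)
  expect_equal(ca$corrected[1], 0.1848, tolerance = 1e-3)
  # corrected amplitudes always renormalize exactly
  expect_equal(sum(ca$corrected), 1, tolerance = 1e-12)
  # bounds bracket observed and corrected values
  expect_true(all(ca$lower <= pmin(ca$observed, ca$corrected) + 1e-12))
  expect_error(correct_amplitudes_eq1(NULL, c(0.5, 0.5), c(1, 0)))
})

test_that("triple-phase correction approximates the published percentages", {
  ca <- correct_amplitudes_eq1(NULL, amplitudes = c(0.822, 0.160, 0.018),
                               rates = c(6.88, 0.30, 0.03))
  # frozen from direct arithmetic: w = A/k = (.11948, .53333, .60000)
  expect_equal(ca$corrected, c(0.09536700, 0.42570964, 0.47892335),
               tolerance = 1e-6)
  # within 4 percentage points of the printed 9.3% / 43% / 47%
  expect_true(all(abs(ca$corrected - c(0.093, 0.43, 0.47)) < 0.04))
})

test_that("cycle-time correction inverts the analytic event fractions", {
  r_fast <- expected_event_rate(fast_motor(), 5)
  r_slow <- expected_event_rate(slow_motor(), 5)
  A_obs <- c(r_fast, r_slow) / (r_fast + r_slow)
  cc <- cycle_corrected_fractions(NULL, amplitudes = A_obs,
                                  rates = c(8, 0.05),
                                  k_on = c(0.005, 0.0025), hot_conc = 5)
  # the model holds one molecule of each class
  expect_equal(cc$molecule_fraction, c(0.5, 0.5), tolerance = 1e-12)
  # the dwell-time-only correction instead underestimates the fast class
  eq1 <- correct_amplitudes_eq1(NULL, amplitudes = A_obs, rates = c(8, 0.05))
  expect_equal(eq1$corrected[1], 0.0154, tolerance = 0.01)
  # dwell-limited regime: cycle correction converges to the dwell-time one
  cc_lim <- cycle_corrected_fractions(NULL, amplitudes = c(0.7, 0.3),
                                      rates = c(8, 0.05),
                                      k_on = c(100, 100), hot_conc = 1e4)
  eq1_lim <- correct_amplitudes_eq1(NULL, amplitudes = c(0.7, 0.3),
                                    rates = c(8, 0.05))
  expect_equal(cc_lim$molecule_fraction, eq1_lim$corrected, tolerance = 1e-4)
})

test_that("a pooled fit reproduces sub-sampled data sets within their bands", {
  set.seed(26)
  pooled <- rmix_dwells(1000, c(0.83, 0.17), c(5.3, 0.26))
  fit <- fit_multiexp(cumulative_distribution(dwell_sample(pooled)), 2)
  for (n_sub in c(166, 236, 598)) {
    sub <- sample(pooled, n_sub)
    cd <- cumulative_distribution(dwell_sample(sub))
    pred <- n_sub * as.vector(
      exp(-outer(cd$t, fit$phases$rate)) %*% fit$phases$amplitude)
    band <- sqrt(log(2 / 0.001) / (2 * n_sub)) + 0.03
    expect_true(all(abs(cd$count - pred) / n_sub <= band))
  }
})
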