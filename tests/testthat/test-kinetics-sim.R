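test_that("closed-form event rates match their defining arithmetic", {
  expect_equal(expected_event_rate(fast_motor(), 5), 1 / (40 + 0.125),
               tolerance = 1e-12)
  expect_equal(expected_event_rate(fast_motor(), 5), 0.024922, tolerance = 1e-4)
  expect_equal(expected_event_rate(slow_motor(), 5), 0.01, tolerance = 1e-12)
  # binding-limited limit: with instantaneous turnover the event rate is
  # just the pseudo-first-order binding rate
  fast_turnover <- motor_spec(0.005, 1e9)
  expect_equal(expected_event_rate(fast_turnover, 5), 0.005 * 5,
               tolerance = 1e-6)
})

test_that("an ROI without motors produces no events", {
  m <- roi_kinetic_model(list(), hot_conc = 5)
  ev <- simulate_binding_events(m, 100, seed = 1)
  expect_s3_class(ev, "binding_events")
  expect_identical(nrow(ev), 0L)
})

test_that("simulated event statistics match the two-motor model's analytics", {
  m <- ref_model()
  ev <- simulate_binding_events(m, 2e5, seed = 101)
  ev_ok <- ev[!ev$censored, ]
  # mean fast dwell = 1 / k_cat = 0.125 s
  fast <- ev_ok$duration[ev_ok$motor_index == 1]
  expect_lt(abs(mean(fast) - 0.125), 3 * 0.125 / sqrt(length(fast)))
  # event-share of the fast motor = r_fast / (r_fast + r_slow) = 0.714
  p <- 0.024922 / (0.024922 + 0.01)
  se <- sqrt(p * (1 - p) / nrow(ev))
  expect_lt(abs(mean(ev$motor_index == 1) - p), 3 * se)
})

test_that("single-motor dwell times are exponential with rate k_cat", {
  m1 <- roi_kinetic_model(fast_motor(), hot_conc = 5)
  dw <- simulate_dwells(m1, 1e4, seed = 7)
  ks <- suppressWarnings(stats::ks.test(dw$dwells, "pexp", 8))
  expect_gt(ks$p.value, 0.01)
})

test_that("a fixed seed reproduces events bit-identically", {
  m <- ref_model()
  e1 <- simulate_binding_events(m, 5000, seed = 42)
  e2 <- simulate_binding_events(m, 5000, seed = 42)
  expect_identical(e1, e2)
  t1 <- digitize_trace(e1, camera_spec(read_noise_sd = 0.1), 5000, seed = 9)
  t2 <- digitize_trace(e2, camera_spec(read_noise_sd = 0.1), 5000, seed = 9)
  expect_identical(t1$values, t2$values)
})

test_that("photobleaching shortens visible dwells as a competing rate", {
  pb <- 2  # strong, to make the effect measurable
  m <- roi_kinetic_model(fast_motor(), hot_conc = 5, photobleach_rate = pb)
  dw <- simulate_dwells(m, 5000, seed = 3)
  expect_equal(mean(dw$dwells), 1 / (8 + pb),
               tolerance = 3 / sqrt(5000) / (8 + pb) + 1e-3)
})

test_that("cold ATP competition thins visible events to the analytic rate", {
  m_cold <- roi_kinetic_model(fast_motor(), hot_conc = 5, cold_conc = 500)
  dur <- 5e4
  n_mix <- nrow(simulate_binding_events(m_cold, dur, seed = 5))
  # closed form: bindings occur at r_h + r_c, a fraction r_h/(r_h+r_c) is
  # visible, and every binding occupies the site for 1/k_cat on average
  r_h <- 0.005 * 5; r_c <- 0.005 * 500
  rate_vis <- (r_h / (r_h + r_c)) / (1 / (r_h + r_c) + 1 / 8)
  expect_lt(abs(n_mix - dur * rate_vis), 3 * sqrt(dur * rate_vis))
  # visible events are rarer than without cold ATP
  expect_lt(rate_vis, expected_event_rate(fast_motor(), 5))
})

test_that("digitization integrates occupancy over exposure windows", {
  cam <- camera_spec(frame_interval = 0.05, exposure = 0.05)
  # one event exactly covering frames 2-4
  tr <- digitize_trace(make_events(0.10, 0.15), cam, 0.5)
  expect_equal(tr$values, c(0, 0, 1, 1, 1, rep(0, 5)))
  # 10 ms wholly inside one 50 ms exposure -> fractional occupancy 0.2
  tr <- digitize_trace(make_events(0.120, 0.010), cam, 0.5)
  expect_equal(tr$values[3], 0.2)
  expect_equal(sum(tr$values), 0.2)
  # 25 ms in each of two consecutive exposures -> two frames at 0.5
  tr <- digitize_trace(make_events(0.075, 0.050), cam, 0.5)
  expect_equal(tr$values[2:3], c(0.5, 0.5))
})

test_that("bound time in camera dead time is invisible", {
  cam <- camera_spec(frame_interval = 0.052, exposure = 0.050)
  # event entirely inside the 2 ms gap after the first exposure
  tr <- digitize_trace(make_events(0.0505, 0.001), cam, 0.5)
  expect_true(all(tr$values == 0))
})

test_that("noise-free digitization conserves in-exposure bound time", {
  cam <- camera_spec(frame_interval = 0.052, exposure = 0.050)
  set.seed(31)
  for (rep in 1:5) {
    ev <- simulate_binding_events(ref_model(), 500)
    tr <- digitize_trace(ev, cam, 500)
    # independent oracle: accumulate overlap on a fine time grid
    grid <- seq(0, 500, by = 5e-4)
    in_exposure <- (grid %% cam$frame_interval) < cam$exposure &
      grid < floor(500 / cam$frame_interval) * cam$frame_interval
    occupied <- rep(0, length(grid))
    for (j in seq_len(nrow(ev)))
      occupied <- occupied + (grid >= ev$start[j] &
                              grid < ev$start[j] + ev$duration[j])
    oracle <- sum(occupied[in_exposure]) * 5e-4
    expect_equal(sum(tr$values) * cam$exposure, oracle, tolerance = 0.02)
  }
})

test_that("threshold dwell measurement counts frames per candidate event", {
  cam <- camera_spec(frame_interval = 0.052, exposure = 0.052)
  tr <- intensity_trace(c(0, 0, 1, 1, 1, 0), cam)
  expect_equal(measure_dwells(tr, 0.5)$dwells, 3 * 0.052)
  # shoulders at 0.4 are below half the maximum but above a 0.1 threshold
  tr <- intensity_trace(c(0, 0.4, 1, 1, 0.4, 0), cam)
  expect_equal(measure_dwells(tr, 0.5)$dwells, 0.104)
  expect_equal(measure_dwells(tr, 0.1)$dwells, 0.208)
  # a sub-frame event normalized by its own maximum still yields one frame
  tr <- intensity_trace(c(0, 0.2, 0, 0, 0, 0), cam)
  expect_equal(measure_dwells(tr, 0.5)$dwells, 0.052)
  # empty trace
  expect_length(measure_dwells(intensity_trace(numeric(0), cam))$dwells, 0)
  # one sub-floor frame splits candidate events
  tr <- intensity_trace(c(1, 1, 0.01, 1, 1), cam)
  expect_length(measure_dwells(tr, 0.5)$dwells, 2)
})

test_that("measured dwells converge to true durations as frames shrink", {
  ev <- make_events(c(1.003, 5.217, 9.004), c(0.831, 1.119, 0.497))
  fi <- 1e-3
  cam <- camera_spec(frame_interval = fi, exposure = fi)
  tr <- digitize_trace(ev, cam, 12)
  dw <- sort(measure_dwells(tr, 0.5)$dwells)
  expect_equal(length(dw), 3L)
  expect_true(all(abs(dw - sort(ev$duration)) <= fi + 1e-9))
})

test_that("invalid inputs are rejected", {
  expect_error(motor_spec(-1, 8))
  expect_error(motor_spec(0.005, 0))
  expect_error(camera_spec(frame_interval = 0.05, exposure = 0.06))
  expect_error(simulate_binding_events(ref_model(), -5))
  expect_error(expected_event_rate(fast_motor(), 0))
  expect_error(measure_dwells(intensity_trace(0:3, camera_spec()), 1.2))
})
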