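test_that("z-projections compute per-pixel mean and standard deviation", {
  stack <- array(0, c(4, 4, 2))
  stack[, , 2] <- 2
  expect_equal(z_projection(stack, "mean")$image, matrix(1, 4, 4))
  expect_equal(z_projection(stack, "std")$image,
               matrix(stats::sd(c(0, 2)), 4, 4))
  expect_equal(z_projection(array(5, c(3, 3, 7)), "std")$image,
               matrix(0, 3, 3))
  expect_error(z_projection(array(1, c(3, 3, 1)), "std"))
})

test_that("colocalization requires a hot spot in both channels", {
  set.seed(41)
  base_a <- matrix(stats::rnorm(900, 10, 1), 30, 30)
  base_g <- matrix(stats::rnorm(900, 10, 1), 30, 30)
  spot <- function(m, r, c) { m[r + (-1:1), c + (-1:1)] <- 40; m }
  # emitter at (10,10) in both; (20,20) eGFP-only; (25,8) blinking-only
  alexa <- spot(spot(base_a, 10, 10), 25, 8)
  egfp <- spot(spot(base_g, 10, 10), 20, 20)
  pa <- structure(list(image = alexa, mode = "std", n_frames = 100),
                  class = "projection")
  pg <- structure(list(image = egfp, mode = "mean", n_frames = 100),
                  class = "projection")
  rois <- colocalize(pa, pg)
  expect_length(rois, 1)
  expect_equal(c(rois[[1]]$row, rois[[1]]$col), c(10, 10))
  expect_true(rois[[1]]$colocalized)
})

test_that("ROI traces are pixel sums (or means) and respect image bounds", {
  stack <- array(0, c(5, 5, 3))
  stack[2:4, 2:4, 2] <- 1
  roi <- roi_selection(3, 3)
  tr <- extract_roi_trace(stack, roi, camera_spec())
  expect_equal(tr$values, c(0, 9, 0))
  tr_mean <- extract_roi_trace(stack, roi, camera_spec(), stat = "mean")
  expect_equal(tr_mean$values, c(0, 1, 0))
  expect_error(extract_roi_trace(array(0, c(2, 2, 3)), roi, camera_spec()))
  expect_equal(extract_roi_trace(array(0, c(5, 5, 4)), roi,
                                 camera_spec())$values, rep(0, 4))
})

test_that("background estimation is robust to sparse events", {
  set.seed(42)
  v <- stats::rnorm(2000, 10, 1)
  tr <- intensity_trace(v, camera_spec())
  bg <- estimate_background(tr)
  expect_equal(bg$level, 10, tolerance = 0.05)
  expect_equal(bg$noise_sd, 1, tolerance = 0.05)
  # constant trace: zero noise
  bgc <- estimate_background(intensity_trace(rep(3, 200), camera_spec()))
  expect_equal(bgc$noise_sd, 0)
  # 5% of frames in bright events barely move the level
  v2 <- v
  v2[sample(2000, 100)] <- 50
  bg2 <- estimate_background(intensity_trace(v2, camera_spec()))
  expect_lt(abs(bg2$level - bg$level) / bg$level, 0.02)
  expect_error(estimate_background(intensity_trace(rnorm(50), camera_spec())))
})

test_that("event detection applies the two-sigma rule on constructed bursts", {
  set.seed(43)
  cam <- camera_spec()
  # quiet baseline so that the nominal noise level drives the threshold
  v <- stats::rnorm(1200, 10, 0.1)
  # three clear bursts of 4, 2 and 6 frames, and one sub-threshold bump
  v[101:104] <- 20
  v[301:302] <- 20
  v[501:506] <- 20
  v[701] <- 10 + 1.9   # peak at 1.9 x noise sd: below "at least twice"
  tr <- intensity_trace(v, cam)
  det <- detect_events(tr, background = list(level = 10, noise_sd = 1))
  expect_equal(nrow(det$events), 3)
  expect_equal(sort(det$dwells$dwells), sort(c(4, 2, 6) * cam$frame_interval))
  # two bursts separated by one sub-threshold frame stay two events
  v2 <- rep(0, 300); v2[100:104] <- 10; v2[105] <- 0.5; v2[106:109] <- 10
  det2 <- detect_events(intensity_trace(v2, cam),
                        background = list(level = 0, noise_sd = 1))
  expect_equal(det2$events$n_frames, c(5, 4))
})

test_that("multi-step events are flagged by the plateau-CV check", {
  cam <- camera_spec()
  v <- rep(0, 300)
  v[100:105] <- c(10, 10, 10, 30, 30, 30)  # double step up
  det <- detect_events(intensity_trace(v, cam),
                       background = list(level = 0, noise_sd = 1))
  expect_false(det$events$accepted[1])
  expect_match(det$events$reason[1], "single-step")
  expect_length(det$dwells$dwells, 0)
})

test_that("selection excludes sparse ROIs and noisy recordings, idempotently", {
  mk_roi <- function(n_events, duration = 600, fi = 0.052) {
    starts <- round(seq(30, duration - 30, length.out = n_events) / fi)
    list(roi = roi_selection(5, 5, colocalized = TRUE),
         events = data.frame(start_frame = starts, n_frames = 2,
                             mean_intensity = 10, plateau_cv = 0.1,
                             accepted = TRUE, reason = ""),
         dwells = dwell_sample(rep(2 * fi, n_events), frame_interval = fi,
                               provenance = "detected"))
  }
  rois <- list(good = mk_roi(40), boundary = mk_roi(15), sparse = mk_roi(3))
  sel <- apply_selection(rois, background_event_count = 2, duration = 600)
  expect_false(sel$recording_excluded)
  expect_named(sel$accepted, "good")
  expect_equal(sum(sel$audit$accepted), 1)
  # exactly 15 events fails the strictly-more-than-15 rule
  expect_match(sel$audit$reason[2], "more than 15")
  # idempotent on the accepted subset
  sel2 <- apply_selection(sel$accepted, 2, 600)
  expect_named(sel2$accepted, "good")
  # a recording with 11 background events per 10 min goes out wholesale
  selx <- apply_selection(rois, background_event_count = 11, duration = 600)
  expect_true(selx$recording_excluded)
  expect_length(selx$accepted, 0)
  # clustered events fail the throughout-the-recording rule
  cl <- mk_roi(40, duration = 100)
  cl$events$start_frame <- cl$events$start_frame %/% 40  # all near t = 0
  selc <- apply_selection(list(clustered = cl), 0, duration = 600)
  expect_false(selc$audit$accepted[1])
})

test_that("non-colocalized ROIs are excluded when colocalization is required", {
  roi <- list(roi = roi_selection(5, 5, colocalized = FALSE),
              events = data.frame(start_frame = seq(10, 11000, by = 300),
                                  n_frames = 2, mean_intensity = 10,
                                  plateau_cv = 0.1, accepted = TRUE,
                                  reason = ""),
              dwells = dwell_sample(rep(0.104, 37), frame_interval = 0.052,
                                    provenance = "detected"))
  sel <- apply_selection(list(surface = roi), 0, 600)
  expect_false(sel$audit$accepted[1])
  sel_off <- apply_selection(list(surface = roi), 0, 600,
                             selection_criteria(require_colocalization = FALSE))
  expect_true(sel_off$audit$accepted[1])
})
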