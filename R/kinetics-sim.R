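#' Kinetic specification of a single myosin motor domain
#'
#' A motor is characterised by a second-order fluorescent-ATP binding rate
#' constant `k_on` (per nM per s) and a first-order turnover rate constant
#' `k_cat` (per s) that terminates the bound (fluorescent) dwell.  The mean
#' on-dwell time of the fluorescent nucleotide is `1 / k_cat`.
#'
#' @param k_on Binding rate constant (nM^-1 s^-1); must be positive.
#' @param k_cat Turnover rate constant (s^-1); must be positive.
#' @param label Free-text label, e.g. `"fast"`, `"slow"`, `"nonspecific"`.
#' @return An object of class `motor_spec`.
#' @examples
#' motor_spec(k_on = 0.005, k_cat = 8, label = "fast")
#' @export
motor_spec <- function(k_on, k_cat, label = "motor") {
  stopifnot(is.numeric(k_on), length(k_on) == 1L, is.finite(k_on), k_on > 0,
            is.numeric(k_cat), length(k_cat) == 1L, is.finite(k_cat), k_cat > 0)
  structure(list(k_on = k_on, k_cat = k_cat, label = as.character(label)[1L]),
            class = "motor_spec")
}

#' @export
print.motor_spec <- function(x, ...) {
  cat(sprintf("<motor_spec '%s'> k_on = %g nM^-1 s^-1, k_cat = %g s^-1 (mean dwell %.4g s)\n",
              x$label, x$k_on, x$k_cat, 1 / x$k_cat))
  invisible(x)
}

#' Kinetic model of one region of interest
#'
#' Collects the motors assumed present in one ROI together with the
#' fluorescent ("hot") and non-fluorescent ("cold") ATP concentrations and an
#' optional photobleaching rate.  Cold ATP competes for the nucleotide site
#' and produces invisible dwells; photobleaching terminates the *visible*
#' part of a hot dwell without freeing the site.
#'
#' @param motors A list of [motor_spec()] objects (possibly empty).
#' @param hot_conc Fluorescent-ATP concentration (nM), >= 0.
#' @param cold_conc Non-fluorescent ATP concentration (nM), >= 0 (default 0).
#' @param cold_k_on Binding rate constant for cold ATP (nM^-1 s^-1).  Default
#'   `NULL` means each motor uses its own `k_on` for cold ATP too.
#' @param photobleach_rate Photobleaching rate constant (s^-1, default 0).
#' @return An object of class `roi_kinetic_model`.
#' @export
roi_kinetic_model <- function(motors, hot_conc, cold_conc = 0,
                              cold_k_on = NULL, photobleach_rate = 0) {
  if (inherits(motors, "motor_spec")) motors <- list(motors)
  stopifnot(is.list(motors), all(vapply(motors, inherits, logical(1), "motor_spec")),
            is.numeric(hot_conc), length(hot_conc) == 1L, hot_conc >= 0,
            is.numeric(cold_conc), length(cold_conc) == 1L, cold_conc >= 0,
            is.numeric(photobleach_rate), photobleach_rate >= 0)
  if (!is.null(cold_k_on))
    stopifnot(is.numeric(cold_k_on), all(cold_k_on > 0),
              length(cold_k_on) %in% c(1L, length(motors)))
  structure(list(motors = motors, hot_conc = hot_conc, cold_conc = cold_conc,
                 cold_k_on = cold_k_on, photobleach_rate = photobleach_rate),
            class = "roi_kinetic_model")
}

#' Reference two-motor model used throughout the simulation studies
#'
#' One motor with fast fluorescent-ATP binding (0.005 nM^-1 s^-1) and fast
#' turnover (8 s^-1, actin-activated), and one motor with slow binding
#' (default 0.0025 nM^-1 s^-1) and slow turnover (0.05 s^-1, basal-like), at
#' 5 nM fluorescent ATP.  `slow_k_on = 0.002` selects the alternative slow
#' binding constant that is also quoted for this model.
#'
#' @param slow_k_on Slow-motor binding rate constant (nM^-1 s^-1).
#' @param hot_conc Fluorescent-ATP concentration (nM).
#' @return A [roi_kinetic_model()].
#' @export
reference_two_motor_model <- function(slow_k_on = 0.0025, hot_conc = 5) {
  roi_kinetic_model(
    motors = list(motor_spec(0.005, 8, "fast"),
                  motor_spec(slow_k_on, 0.05, "slow")),
    hot_conc = hot_conc)
}

#' Closed-form mean event rate of one motor
#'
#' In steady state a motor alternates between a free state (mean waiting time
#' `1 / (k_on * hot_conc)`) and a bound state (mean dwell `1 / k_cat`), so
#' visible events occur at rate `1 / (1/(k_on*hot_conc) + 1/k_cat)`.  This is
#' the analytic oracle for the stochastic simulator and the quantity behind
#' event-frequency weighting of amplitudes: faster motors generate more
#' events per molecule per unit time.
#'
#' @param motor A [motor_spec()].
#' @param hot_conc Fluorescent-ATP concentration (nM), > 0.
#' @return Events per second (numeric scalar).
#' @examples
#' expected_event_rate(motor_spec(0.005, 8), 5)    # 0.02492 s^-1
#' expected_event_rate(motor_spec(0.0025, 0.05), 5) # 0.01 s^-1
#' @export
expected_event_rate <- function(motor, hot_conc) {
  stopifnot(inherits(motor, "motor_spec"),
            is.numeric(hot_conc), length(hot_conc) == 1L, hot_conc > 0)
  1 / (1 / (motor$k_on * hot_conc) + 1 / motor$k_cat)
}

#' Camera acquisition parameters
#'
#' Frames are spaced `frame_interval` apart; each frame integrates light over
#' an exposure window of length `exposure` at the start of the interval.  The
#' gap `frame_interval - exposure` is dead time: fluorophore presence there
#' is invisible.  Defaults mirror a 52 ms frame-to-frame interval with 50 ms
#' individual exposures.
#'
#' @param frame_interval Frame-to-frame interval (s), default 0.052.
#' @param exposure Exposure time (s), default 0.050; `0 < exposure <=
#'   frame_interval`.
#' @param unit_intensity Intensity of one fluorophore bound for a full
#'   exposure (arbitrary units, default 1).
#' @param read_noise_sd Gaussian read noise per frame (intensity units,
#'   default 0).
#' @return An object of class `camera_spec`.
#' @export
camera_spec <- function(frame_interval = 0.052, exposure = 0.050,
                        unit_intensity = 1, read_noise_sd = 0) {
  stopifnot(is.numeric(frame_interval), frame_interval > 0,
            is.numeric(exposure), exposure > 0, exposure <= frame_interval,
            is.numeric(unit_intensity), unit_intensity > 0,
            is.numeric(read_noise_sd), read_noise_sd >= 0)
  structure(list(frame_interval = frame_interval, exposure = exposure,
                 unit_intensity = unit_intensity, read_noise_sd = read_noise_sd),
            class = "camera_spec")
}

# Simulate one motor's alternating free/bound renewal process on [0, duration).
# Returns start, duration (visible), site_end (true unbinding time), species,
# censored.  Vectorised in blocks; exact continuous-time (Gillespie) sampling.
sim_one_motor <- function(rate_hot, rate_cold, k_cat, pb_rate, duration) {
  rate_bind <- rate_hot + rate_cold
  empty <- data.frame(start = numeric(0), duration = numeric(0),
                      species = character(0), censored = logical(0))
  if (rate_bind <= 0) return(empty)
  p_hot <- rate_hot / rate_bind
  mean_cycle <- 1 / rate_bind + 1 / k_cat
  starts <- durs <- numeric(0); spec <- character(0)
  t0 <- 0
  repeat {
    n <- max(16L, ceiling(1.3 * (duration - t0) / mean_cycle))
    waits <- stats::rexp(n, rate_bind)
    dwells <- stats::rexp(n, k_cat)
    hot <- stats::runif(n) < p_hot
    vis <- dwells
    if (pb_rate > 0) {
      bleach <- stats::rexp(n, pb_rate)
      vis <- pmin(dwells, bleach)
    }
    ends <- t0 + cumsum(waits + dwells)
    st <- ends - dwells
    keep <- st < duration
    starts <- c(starts, st[keep])
    durs <- c(durs, ifelse(hot[keep], vis[keep], dwells[keep]))
    spec <- c(spec, ifelse(hot[keep], "hot", "cold"))
    t0 <- ends[n]
    if (t0 >= duration) break
  }
  cens <- starts + durs > duration
  durs[cens] <- duration - starts[cens]
  data.frame(start = starts, duration = durs, species = spec, censored = cens)
}

#' Simulate fluorescent-nucleotide binding events in one ROI
#'
#' Exact continuous-time stochastic simulation (Gillespie algorithm) of the
#' two-state free/bound cycle of each motor in the model.  Each motor binds
#' ATP after an exponential wait with rate `k_on * hot_conc + cold_k_on *
#' cold_conc` (the bound species is hot with probability proportional to the
#' hot term) and unbinds after an exponential dwell with rate `k_cat`.  Only
#' hot (fluorescent) dwells are emitted; photobleaching, when enabled,
#' shortens the visible part of a hot dwell.  Events that straddle the end of
#' the recording are truncated and flagged `censored`.
#'
#' @param model A [roi_kinetic_model()].
#' @param duration Recording duration (s), > 0.
#' @param seed Optional integer seed (`set.seed`) for reproducibility.
#' @return A `binding_events` data frame with columns `start`, `duration`,
#'   `motor_index`, `species` (always `"hot"`) and `censored`, ordered by
#'   start time.
#' @examples
#' ev <- simulate_binding_events(reference_two_motor_model(), 500, seed = 1)
#' head(ev)
#' @export
simulate_binding_events <- function(model, duration, seed = NULL) {
  stopifnot(inherits(model, "roi_kinetic_model"),
            is.numeric(duration), length(duration) == 1L, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (i in seq_along(model$motors)) {
    m <- model$motors[[i]]
    cko <- if (is.null(model$cold_k_on)) m$k_on
           else if (length(model$cold_k_on) == 1L) model$cold_k_on
           else model$cold_k_on[i]
    ev <- sim_one_motor(rate_hot = m$k_on * model$hot_conc,
                        rate_cold = cko * model$cold_conc,
                        k_cat = m$k_cat,
                        pb_rate = model$photobleach_rate,
                        duration = duration)
    ev <- ev[ev$species == "hot" & ev$duration > 0, , drop = FALSE]
    if (nrow(ev)) ev$motor_index <- i
    out[[i]] <- ev
  }
  out <- out[vapply(out, nrow, integer(1)) > 0L]
  if (!length(out)) {
    ev <- data.frame(start = numeric(0), duration = numeric(0),
                     motor_index = integer(0), species = character(0),
                     censored = logical(0))
  } else {
    ev <- do.call(rbind, out)
    ev <- ev[order(ev$start), c("start", "duration", "motor_index", "species",
                                "censored")]
    rownames(ev) <- NULL
  }
  class(ev) <- c("binding_events", "data.frame")
  attr(ev, "duration") <- duration
  ev
}

#' Draw a fixed number of idealized on-dwell times from a model
#'
#' Runs the stochastic simulator until at least `n` completed (uncensored)
#' visible events have occurred and returns the first `n` dwell durations in
#' chronological order.  These are idealized dwells: no camera digitization
#' or threshold measurement is applied.
#'
#' @inheritParams simulate_binding_events
#' @param n Number of dwells required.
#' @return A [dwell_sample()] with `provenance = "simulated"`.
#' @export
simulate_dwells <- function(model, n, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  total_rate <- sum(vapply(model$motors, expected_event_rate, numeric(1),
                           hot_conc = model$hot_conc))
  if (total_rate <= 0) stop("model generates no visible events")
  duration <- (n + 10 * sqrt(n)) / total_rate
  repeat {
    ev <- simulate_binding_events(model, duration)
    ev <- ev[!ev$censored, , drop = FALSE]
    if (nrow(ev) >= n) break
    duration <- duration * 1.5
  }
  dwell_sample(ev$duration[seq_len(n)], provenance = "simulated")
}

#' A sample of measured or simulated on-dwell times
#'
#' @param dwells Numeric vector of dwell durations (s), all > 0.
#' @param threshold Threshold rule used to measure the dwells (fraction of
#'   per-event maximum), or `NA` for idealized dwells.
#' @param frame_interval Camera frame interval (s) the dwells derive from, or
#'   `NA`.
#' @param half_frame_corrected Has [half_frame_correct()] been applied?
#' @param provenance `"simulated"` (ground truth) or `"detected"` (measured
#'   from a trace).
#' @return An object of class `dwell_sample`.
#' @export
dwell_sample <- function(dwells, threshold = NA_real_,
                         frame_interval = NA_real_,
                         half_frame_corrected = FALSE,
                         provenance = c("simulated", "detected")) {
  provenance <- match.arg(provenance)
  dwells <- as.numeric(dwells)
  stopifnot(all(dwells > 0))
  structure(list(dwells = dwells, threshold = threshold,
                 frame_interval = frame_interval,
                 half_frame_corrected = half_frame_corrected,
                 provenance = provenance),
            class = "dwell_sample")
}

#' @export
print.dwell_sample <- function(x, ...) {
  cat(sprintf("<dwell_sample> n = %d, mean = %.4g s, provenance = %s%s\n",
              length(x$dwells), mean(x$dwells), x$provenance,
              if (isTRUE(x$half_frame_corrected)) ", half-frame corrected" else ""))
  invisible(x)
}

#' Convert events into a camera-digitized intensity trace
#'
#' Frame `i` (0-based) integrates fluorophore presence over its exposure
#' window `[i * frame_interval, i * frame_interval + exposure)`; the
#' remaining `frame_interval - exposure` is dead time.  The noise-free frame
#' intensity is `unit_intensity *` (bound time within the exposure window) `/
#' exposure`, so simultaneous events sum.  Gaussian read noise is added when
#' `read_noise_sd > 0`.
#'
#' @param events A `binding_events` data frame (only `species == "hot"` rows
#'   contribute).
#' @param camera A [camera_spec()].
#' @param duration Trace duration (s); the trace has
#'   `floor(duration / frame_interval)` frames.
#' @param seed Optional integer seed for the read noise.
#' @return An object of class `intensity_trace`: list with `values`, `camera`
#'   and `duration`.
#' @export
digitize_trace <- function(events, camera, duration, seed = NULL) {
  stopifnot(inherits(camera, "camera_spec"),
            is.numeric(duration), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  fi <- camera$frame_interval; ex <- camera$exposure
  n_frames <- floor(duration / fi)
  values <- numeric(n_frames)
  if (nrow(events)) {
    ev <- events[events$species == "hot", , drop = FALSE]
    if (any(ev$start < 0 | ev$start + ev$duration > duration + 1e-9))
      stop("events must lie within [0, duration]")
    for (j in seq_len(nrow(ev))) {
      s <- ev$start[j]; e <- s + ev$duration[j]
      k0 <- max(0L, floor(s / fi)); k1 <- min(n_frames - 1L, floor(e / fi))
      if (k1 < k0) next
      k <- k0:k1
      win_start <- k * fi
      overlap <- pmin(e, win_start + ex) - pmax(s, win_start)
      overlap[overlap < 0] <- 0
      values[k + 1L] <- values[k + 1L] + camera$unit_intensity * overlap / ex
    }
  }
  if (camera$read_noise_sd > 0)
    values <- values + stats::rnorm(n_frames, 0, camera$read_noise_sd)
  intensity_trace(values, camera, duration)
}

#' @rdname digitize_trace
#' @param values Per-frame intensities.
#' @export
intensity_trace <- function(values, camera, duration = NULL) {
  stopifnot(inherits(camera, "camera_spec"))
  if (is.null(duration)) duration <- length(values) * camera$frame_interval
  structure(list(values = as.numeric(values), camera = camera,
                 duration = duration),
            class = "intensity_trace")
}

#' Measure on-dwell times from a digitized trace by per-event thresholding
#'
#' Contiguous runs of frames above an absolute detection floor
#' (`floor_frac * unit_intensity`) form candidate events; one sub-floor frame
#' splits events (no gap closing).  Within each candidate event, frames with
#' intensity >= `threshold` times the event's maximum frame intensity are
#' counted and the measured dwell is that count times the frame interval.
#' Because the per-event maximum of a sub-frame event is itself small, even a
#' very short binding is measured as at least one full frame — the mechanism
#' that inflates short dwells and biases fast rate estimates downward.
#'
#' @param trace An [intensity_trace()].
#' @param threshold Fraction of the per-event maximum (0 < threshold < 1),
#'   default 0.5.
#' @param floor_frac Detection floor as a fraction of `unit_intensity`
#'   (default 0.05).
#' @return A [dwell_sample()] with `provenance = "detected"`.
#' @export
measure_dwells <- function(trace, threshold = 0.5, floor_frac = 0.05) {
  stopifnot(inherits(trace, "intensity_trace"),
            is.numeric(threshold), threshold > 0, threshold < 1)
  fi <- trace$camera$frame_interval
  v <- trace$values
  if (!length(v))
    return(dwell_sample(numeric(0), threshold, fi, provenance = "detected"))
  above <- v > floor_frac * trace$camera$unit_intensity
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dwells <- numeric(0)
  for (i in which(r$values)) {
    seg <- v[starts[i]:ends[i]]
    cnt <- sum(seg >= threshold * max(seg))
    if (cnt > 0) dwells <- c(dwells, cnt * fi)
  }
  dwell_sample(dwells, threshold = threshold, frame_interval = fi,
               provenance = "detected")
}
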