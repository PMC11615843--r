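#' Specification of a synthetic two-channel TIRF movie
#'
#' Describes the field of view, camera, optics, noise, filament geometry and
#' motor densities for the synthetic movie generator.  The eGFP channel is a
#' single static image (every motor carries one eGFP); the fluorescent-ATP
#' channel is a stack of `n_frames` images in which each motor blinks
#' according to its simulated binding events.  Coordinates are in micrometres
#' with x to the right, y down, and pixel (row i, col j) centred at
#' `((j - 0.5) * pixel_size, (i - 0.5) * pixel_size)` (1-based indices).
#'
#' @param width,height Image size in pixels.
#' @param pixel_size Pixel pitch (um), default 0.8/3 so a 3x3-pixel ROI spans
#'   0.8 x 0.8 um^2.
#' @param n_frames Number of frames in the blinking channel.
#' @param camera A [camera_spec()].
#' @param psf_sigma Gaussian PSF standard deviation (um); default 0.13,
#'   roughly lambda/(2 NA) for 660 nm at NA 1.49.
#' @param background_level Mean background (intensity units per pixel).
#' @param background_sd Gaussian background fluctuation used when
#'   `shot_noise = FALSE`.
#' @param filaments List of polylines; each an n x 2 matrix of (x, y) in um.
#' @param motor_density Motors per actin monomer (e.g. 1/50 to 1/333).
#' @param monomers_per_um Actin monomers per um of filament (default 362).
#' @param off_filament_motor_rate Surface-adsorbed motors per um^2.
#' @param shot_noise Apply Poisson shot noise to signal + background?
#' @return An object of class `movie_spec`.
#' @export
movie_spec <- function(width, height, pixel_size = 0.8 / 3, n_frames = 100,
                       camera = camera_spec(), psf_sigma = 0.13,
                       background_level = 0, background_sd = 0,
                       filaments = list(), motor_density = 0,
                       monomers_per_um = 362, off_filament_motor_rate = 0,
                       shot_noise = FALSE) {
  stopifnot(width >= 1, height >= 1, pixel_size > 0, n_frames >= 1,
            inherits(camera, "camera_spec"), psf_sigma > 0,
            background_level >= 0, background_sd >= 0, motor_density >= 0,
            monomers_per_um > 0, off_filament_motor_rate >= 0)
  filaments <- lapply(filaments, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2, nrow(p) >= 2)
    if (any(p[, 1] < 0 | p[, 1] > width * pixel_size |
            p[, 2] < 0 | p[, 2] > height * pixel_size))
      stop("filament polylines must lie inside the field")
    p
  })
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, n_frames = as.integer(n_frames),
                 camera = camera, psf_sigma = psf_sigma,
                 background_level = background_level,
                 background_sd = background_sd, filaments = filaments,
                 motor_density = motor_density,
                 monomers_per_um = monomers_per_um,
                 off_filament_motor_rate = off_filament_motor_rate,
                 shot_noise = shot_noise),
            class = "movie_spec")
}

#' Arc length of a polyline
#'
#' @param p n x 2 matrix of vertices (um).
#' @return Total length (um).
#' @export
polyline_length <- function(p) {
  sum(sqrt(rowSums(diff(as.matrix(p))^2)))
}

# sample a point at arc-length s along polyline p
polyline_point <- function(p, s) {
  seg <- sqrt(rowSums(diff(p)^2))
  cs <- cumsum(seg)
  i <- findInterval(s, c(0, cs), rightmost.closed = TRUE, all.inside = TRUE)
  s0 <- if (i == 1) 0 else cs[i - 1]
  f <- (s - s0) / seg[i]
  p[i, ] + f * (p[i + 1, ] - p[i, ])
}

#' Place motors on filaments and on the background surface
#'
#' On-filament motors form a Poisson point process along each polyline with
#' linear density `motor_density * monomers_per_um` per um (at a 1:50
#' motor:monomer ratio and 362 monomers/um the mean spacing is 138 nm).
#' Surface-adsorbed motors form a spatial Poisson process at
#' `off_filament_motor_rate` per um^2.  By default on-filament motors carry
#' eGFP and fast actin-activated kinetics while off-filament motors carry
#' eGFP and slow basal kinetics; both can be overridden before rendering.
#'
#' @param spec A [movie_spec()].
#' @param seed Optional integer seed.
#' @param on_motor,off_motor [motor_spec()] kinetics assigned to on- and
#'   off-filament motors.
#' @param hot_conc Fluorescent-ATP concentration (nM) used when simulating
#'   events at render time.
#' @return An object of class `ground_truth`: list with `emitters` (data
#'   frame `x`, `y`, `on_filament`, `filament`, `has_egfp`, `k_on`, `k_cat`)
#'   and the generating `spec`/`hot_conc`.
#' @export
place_motors <- function(spec, seed = NULL,
                         on_motor = motor_spec(0.005, 8, "fast"),
                         off_motor = motor_spec(0.0025, 0.05, "slow"),
                         hot_conc = 5) {
  stopifnot(inherits(spec, "movie_spec"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  lin_density <- spec$motor_density * spec$monomers_per_um  # per um
  for (fi in seq_along(spec$filaments)) {
    p <- spec$filaments[[fi]]
    L <- polyline_length(p)
    n <- stats::rpois(1, lin_density * L)
    if (n > 0) {
      s <- sort(stats::runif(n, 0, L))
      xy <- t(vapply(s, function(si) polyline_point(p, si), numeric(2)))
      rows[[length(rows) + 1L]] <- data.frame(
        x = xy[, 1], y = xy[, 2], on_filament = TRUE, filament = fi,
        has_egfp = TRUE, k_on = on_motor$k_on, k_cat = on_motor$k_cat)
    }
  }
  area <- spec$width * spec$height * spec$pixel_size^2
  n_off <- stats::rpois(1, spec$off_filament_motor_rate * area)
  if (n_off > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      x = stats::runif(n_off, 0, spec$width * spec$pixel_size),
      y = stats::runif(n_off, 0, spec$height * spec$pixel_size),
      on_filament = FALSE, filament = NA_integer_,
      has_egfp = TRUE, k_on = off_motor$k_on, k_cat = off_motor$k_cat)
  }
  emitters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), on_filament = logical(0),
               filament = integer(0), has_egfp = logical(0),
               k_on = numeric(0), k_cat = numeric(0))
  rownames(emitters) <- NULL
  structure(list(emitters = emitters, spec = spec, hot_conc = hot_conc,
                 events = NULL),
            class = "ground_truth")
}

# integrated 2-D Gaussian PSF of unit total intensity at (x0, y0) um,
# evaluated over the whole pixel grid (h x w matrix)
render_psf <- function(x0, y0, sigma, width, height, pixel_size) {
  xe <- (0:width) * pixel_size   # pixel edges
  ye <- (0:height) * pixel_size
  px <- diff(stats::pnorm(xe, mean = x0, sd = sigma))
  py <- diff(stats::pnorm(ye, mean = y0, sd = sigma))
  outer(py, px)
}

#' Render a two-channel synthetic TIRF movie with ground truth
#'
#' The eGFP channel is one static image with an integrated-Gaussian PSF of
#' total intensity `egfp_intensity` per eGFP-carrying motor.  The
#' fluorescent-ATP channel is a stack where every motor contributes its PSF
#' scaled by its camera-digitized per-frame occupancy (binding events are
#' simulated per motor via [simulate_binding_events()] and digitized via
#' [digitize_trace()]), so the pixel sum of a fully bound, noise-free frame
#' equals the camera's `unit_intensity`.  Noise: Poisson shot noise on
#' signal + background when `spec$shot_noise`, plus Gaussian read noise from
#' the camera; otherwise Gaussian background fluctuation only.
#'
#' @param spec A [movie_spec()].
#' @param truth A [place_motors()] result consistent with `spec`.
#' @param seed Optional integer seed.
#' @param egfp_intensity Integrated intensity of one eGFP molecule (a.u.).
#' @return An object of class `tirf_movie`: list with `egfp` (h x w matrix),
#'   `alexa` (h x w x n_frames array) and `truth` (the input, with per-motor
#'   `events` and per-motor true `dwells` filled in).
#' @export
render_movie <- function(spec, truth, seed = NULL, egfp_intensity = 1) {
  stopifnot(inherits(spec, "movie_spec"), inherits(truth, "ground_truth"))
  if (!is.null(seed)) set.seed(seed)
  em <- truth$emitters
  W <- spec$width; H <- spec$height; px <- spec$pixel_size
  duration <- spec$n_frames * spec$camera$frame_interval
  field_w <- W * px; field_h <- H * px
  inside <- em$x >= 0 & em$x <= field_w & em$y >= 0 & em$y <= field_h
  if (any(!inside)) {
    warning(sprintf("%d emitter(s) outside the field clipped", sum(!inside)))
    em <- em[inside, , drop = FALSE]
  }

  egfp <- matrix(0, H, W)
  alexa <- array(0, dim = c(H, W, spec$n_frames))
  events <- vector("list", nrow(em))
  for (i in seq_len(nrow(em))) {
    psf <- render_psf(em$x[i], em$y[i], spec$psf_sigma, W, H, px)
    if (em$has_egfp[i]) egfp <- egfp + egfp_intensity * psf
    model_i <- roi_kinetic_model(motor_spec(em$k_on[i], em$k_cat[i]),
                                 hot_conc = truth$hot_conc)
    ev <- simulate_binding_events(model_i, duration)
    events[[i]] <- ev
    if (nrow(ev)) {
      occ <- digitize_trace(ev, spec$camera, duration)$values
      hot_frames <- which(occ > 0)
      for (f in hot_frames) alexa[, , f] <- alexa[, , f] + occ[f] * psf
    }
  }

  egfp <- egfp + spec$background_level
  alexa <- alexa + spec$background_level
  if (spec$shot_noise) {
    egfp <- matrix(stats::rpois(length(egfp), pmax(egfp, 0)), H, W)
    alexa <- array(stats::rpois(length(alexa), pmax(alexa, 0)), dim = dim(alexa))
  } else if (spec$background_sd > 0) {
    egfp <- egfp + stats::rnorm(length(egfp), 0, spec$background_sd)
    alexa <- alexa + array(stats::rnorm(length(alexa), 0, spec$background_sd),
                           dim = dim(alexa))
  }
  if (spec$camera$read_noise_sd > 0) {
    egfp <- egfp + stats::rnorm(length(egfp), 0, spec$camera$read_noise_sd)
    alexa <- alexa + array(
      stats::rnorm(length(alexa), 0, spec$camera$read_noise_sd),
      dim = dim(alexa))
  }

  truth$events <- events
  truth$dwells <- lapply(events, function(ev)
    if (nrow(ev)) ev$duration[!ev$censored] else numeric(0))
  structure(list(egfp = egfp, alexa = alexa, truth = truth, spec = spec),
            class = "tirf_movie")
}
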