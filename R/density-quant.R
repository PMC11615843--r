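#' Intensity of a single fluorescent molecule
#'
#' Mean background-corrected integrated intensity of at least five isolated
#' surface-adsorbed molecules: for each dot, the pixel sum over a small
#' square patch minus the background level times the patch area.  Dots
#' closer together than `min_separation` pixels are rejected as overlapping.
#'
#' @param image An h x w matrix (e.g. the eGFP mean projection).
#' @param dot_positions n x 2 matrix of (row, col) dot centres, n >= 5.
#' @param dot_size Patch side length in pixels (odd, default 3).
#' @param background `"min"` (minimum gray value, the classical choice) or
#'   `"robust"` (median; insensitive to the noise floor).
#' @param min_separation Minimum centre-to-centre distance (pixels).
#' @return Mean single-molecule intensity (a.u.).
#' @export
single_molecule_intensity <- function(image, dot_positions, dot_size = 3,
                                      background = c("robust", "min"),
                                      min_separation = dot_size) {
  background <- match.arg(background)
  dot_positions <- as.matrix(dot_positions)
  if (nrow(dot_positions) < 5)
    stop("at least five isolated molecules are required")
  if (nrow(dot_positions) > 1) {
    d <- as.matrix(stats::dist(dot_positions))
    diag(d) <- Inf
    if (min(d) < min_separation) stop("overlapping dots rejected")
  }
  bg <- if (background == "min") min(image) else stats::median(image)
  half <- (dot_size - 1L) %/% 2L
  ints <- apply(dot_positions, 1, function(rc) {
    rows <- (rc[1] - half):(rc[1] + half)
    cols <- (rc[2] - half):(rc[2] + half)
    if (min(rows) < 1 || max(rows) > nrow(image) ||
        min(cols) < 1 || max(cols) > ncol(image))
      stop("dot patch extends outside the image")
    sum(image[rows, cols]) - bg * dot_size^2
  })
  mean(ints)
}

# pixels (centres) within width/2 of the polyline, as a logical mask
polyline_mask <- function(image, polyline, pixel_size, width_px = 3) {
  h <- nrow(image); w <- ncol(image)
  cx <- (col(image) - 0.5) * pixel_size
  cy <- (row(image) - 0.5) * pixel_size
  dmin <- matrix(Inf, h, w)
  for (i in seq_len(nrow(polyline) - 1)) {
    a <- polyline[i, ]; b <- polyline[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- if (len2 == 0) 0 else
      pmin(1, pmax(0, ((cx - a[1]) * ab[1] + (cy - a[2]) * ab[2]) / len2))
    dx <- cx - (a[1] + tt * ab[1]); dy <- cy - (a[2] + tt * ab[2])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin <= width_px * pixel_size / 2
}

#' Motor density along one actin filament from its fluorescence intensity
#'
#' The filament's net integrated intensity (pixel sum over a mask of
#' configurable width around the polyline, minus background times the mask
#' area) is divided by the single-molecule intensity to give the number of
#' motors; the filament length times `monomers_per_um` gives the monomer
#' count, whence the motor:monomer ratio and the mean inter-motor spacing.
#'
#' @param image h x w matrix (static-channel image).
#' @param polyline n x 2 matrix of (x, y) in um tracing the filament.
#' @param sm_intensity Single-molecule intensity (a.u.), > 0.
#' @param pixel_size Pixel pitch (um).
#' @param width_px Mask width in pixels (default 3).
#' @param background `"robust"` (median) or `"min"`.
#' @param monomers_per_um Actin monomers per um (default 362).
#' @return An object of class `density_estimate`: list with
#'   `single_molecule_intensity`, `n_molecules`, `filament_length`,
#'   `monomers`, `ratio` (motors per monomer), `mean_spacing` (um).
#' @export
filament_density <- function(image, polyline, sm_intensity,
                             pixel_size, width_px = 3,
                             background = c("robust", "min"),
                             monomers_per_um = 362) {
  background <- match.arg(background)
  stopifnot(sm_intensity > 0)
  polyline <- as.matrix(polyline)
  L <- polyline_length(polyline)
  stopifnot(L > 0)
  mask <- polyline_mask(image, polyline, pixel_size, width_px)
  bg <- if (background == "min") min(image) else stats::median(image)
  net <- sum(image[mask]) - bg * sum(mask)
  if (net < 0) {
    warning("negative net filament intensity; reporting 0 molecules")
    net <- 0
  }
  n_mol <- net / sm_intensity
  density_estimate(n_mol, L, sm_intensity = sm_intensity,
                   monomers_per_um = monomers_per_um)
}

#' Density bookkeeping from a molecule count and filament length
#'
#' @param n_molecules Number of motors on the filament (may be fractional).
#' @param filament_length Filament length (um), > 0.
#' @param sm_intensity Single-molecule intensity used (a.u.), or `NA`.
#' @param monomers_per_um Actin monomers per um (default 362).
#' @return An object of class `density_estimate`.
#' @examples
#' # a 1:50 motor:monomer ratio corresponds to 138 nm mean spacing
#' d <- density_estimate(362 / 50 * 10, 10)
#' d$mean_spacing * 1000
#' @export
density_estimate <- function(n_molecules, filament_length,
                             sm_intensity = NA_real_, monomers_per_um = 362) {
  stopifnot(n_molecules >= 0, filament_length > 0)
  monomers <- filament_length * monomers_per_um
  structure(list(single_molecule_intensity = sm_intensity,
                 n_molecules = n_molecules,
                 filament_length = filament_length,
                 monomers = monomers,
                 ratio = n_molecules / monomers,
                 mean_spacing = if (n_molecules > 0)
                   filament_length / n_molecules else Inf),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf(paste0("<density_estimate> %.4g molecules on %.4g um ",
                     "(1:%.3g motor:monomer, spacing %.4g nm)\n"),
              x$n_molecules, x$filament_length,
              if (x$ratio > 0) 1 / x$ratio else Inf, x$mean_spacing * 1000))
  invisible(x)
}

#' Expected range of motors per region of interest
#'
#' Given the observed range of inter-motor spacings, a square ROI of side
#' `roi_width` and diagonal `roi_diagonal` contains between
#' `max(1, floor(roi_width / spacing_max))` and
#' `round(roi_diagonal / spacing_min)` motors (at least the one local motor
#' under study is assumed present).
#'
#' @param spacing_min,spacing_max Inter-motor spacing range (um), or a
#'   `density_estimate` for `spacing_min` with `spacing_max` omitted.
#' @param roi_width ROI side (um), default 0.8 (3 pixels).
#' @param roi_diagonal ROI diagonal (um), default 1.13.
#' @return Integer vector `c(lower, upper)`.
#' @examples
#' motors_per_roi(0.138, 0.837)  # 1 to 8
#' @export
motors_per_roi <- function(spacing_min, spacing_max = spacing_min,
                           roi_width = 0.8, roi_diagonal = 1.13) {
  if (inherits(spacing_min, "density_estimate"))
    spacing_min <- spacing_min$mean_spacing
  if (inherits(spacing_max, "density_estimate"))
    spacing_max <- spacing_max$mean_spacing
  stopifnot(spacing_min > 0, spacing_max >= spacing_min,
            roi_width > 0, roi_diagonal >= roi_width)
  lower <- max(1L, as.integer(floor(roi_width / spacing_max)))
  c(lower = lower,
    upper = max(lower, as.integer(round(roi_diagonal / spacing_min))))
}
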