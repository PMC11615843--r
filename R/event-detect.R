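#' Z-projection of an image stack
#'
#' Per-pixel mean or standard deviation across frames.  The standard
#' deviation projection highlights blinking emitters; the mean projection
#' highlights static ones.
#'
#' @param stack An h x w x n array (or a `tirf_movie` channel).
#' @param mode `"mean"` or `"std"`.
#' @return An object of class `projection`: list with `image`, `mode`,
#'   `n_frames`.
#' @export
z_projection <- function(stack, mode = c("mean", "std")) {
  mode <- match.arg(mode)
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  n <- dim(stack)[3]
  if (mode == "std" && n < 2) stop("std projection needs at least 2 frames")
  mat <- matrix(stack, ncol = n)
  mu <- rowMeans(mat)
  img <- if (mode == "mean") mu else {
    v <- (rowSums(mat^2) - n * mu^2) / (n - 1)
    sqrt(pmax(v, 0))
  }
  structure(list(image = matrix(img, dim(stack)[1], dim(stack)[2]),
                 mode = mode, n_frames = n),
            class = "projection")
}

#' Event- and ROI-selection criteria
#'
#' Operationalises the recording- and event-level selection rules: exclude
#' recordings whose background ROIs show more than
#' `max_background_events_per_10min` events per 10 minutes; require events to
#' exceed the background level by `intensity_factor` times the background
#' noise; require a single-step intensity change at event start and end
#' (quantified as a plateau coefficient of variation at most
#' `max_plateau_cv`); keep only ROIs with strictly more than
#' `min_events_per_roi` events that occur throughout the recording (largest
#' gap at most `max_gap_fraction` of the recording).
#'
#' @param min_events_per_roi Minimum event count; ROIs with `<=` this many
#'   events are excluded (default 15, i.e. "more than 15" is strict).
#' @param max_background_events_per_10min Default 10.
#' @param intensity_factor Multiple of the background noise SD (default 2).
#' @param require_single_step,require_colocalization Logical switches.
#' @param max_plateau_cv Plateau coefficient-of-variation cap (default 0.5).
#' @param max_gap_fraction Largest allowed gap between consecutive events as
#'   a fraction of the recording (default 0.5).
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(min_events_per_roi = 15,
                               max_background_events_per_10min = 10,
                               intensity_factor = 2,
                               require_single_step = TRUE,
                               require_colocalization = TRUE,
                               max_plateau_cv = 0.5,
                               max_gap_fraction = 0.5) {
  stopifnot(min_events_per_roi > 0, max_background_events_per_10min > 0,
            intensity_factor > 0, max_plateau_cv > 0, max_gap_fraction > 0)
  structure(list(min_events_per_roi = min_events_per_roi,
                 max_background_events_per_10min = max_background_events_per_10min,
                 intensity_factor = intensity_factor,
                 require_single_step = require_single_step,
                 require_colocalization = require_colocalization,
                 max_plateau_cv = max_plateau_cv,
                 max_gap_fraction = max_gap_fraction),
            class = "selection_criteria")
}

#' A square region of interest on the image
#'
#' @param row,col Centre pixel (1-based).
#' @param size Side length in pixels (odd; default 3).
#' @param colocalized Was the ROI found in both channels?
#' @param background_roi Is this a background (off-filament) ROI?
#' @return An object of class `roi_selection`.
#' @export
roi_selection <- function(row, col, size = 3, colocalized = FALSE,
                          background_roi = FALSE) {
  stopifnot(size %% 2 == 1, size >= 1)
  structure(list(row = as.integer(row), col = as.integer(col),
                 size = as.integer(size), colocalized = colocalized,
                 background_roi = background_roi),
            class = "roi_selection")
}

proj_mask <- function(proj, intensity_factor) {
  img <- proj$image
  level <- stats::median(img)
  noise <- stats::mad(img)
  img > level + intensity_factor * max(noise, .Machine$double.eps)
}

#' Co-localize blinking-channel and static-channel projections
#'
#' Candidate ROIs are connected components of pixels that exceed, in *both*
#' the fluorescent-ATP standard-deviation projection and the eGFP mean
#' projection, their own image's robust background (median) by
#' `intensity_factor` times the robust noise SD (MAD).  Component centroids
#' become ROI centres; components touching the border such that the ROI
#' would leave the image are shifted inward.
#'
#' @param alexa_std `projection` of the blinking channel (mode `"std"`).
#' @param egfp_mean `projection` of the static channel (mode `"mean"`).
#' @param criteria A [selection_criteria()].
#' @param roi_size ROI side length in pixels (odd, default 3).
#' @return A list of [roi_selection()] objects (possibly empty), all flagged
#'   `colocalized`.
#' @export
colocalize <- function(alexa_std, egfp_mean, criteria = selection_criteria(),
                       roi_size = 3) {
  stopifnot(inherits(alexa_std, "projection"), inherits(egfp_mean, "projection"),
            identical(dim(alexa_std$image), dim(egfp_mean$image)))
  both <- proj_mask(alexa_std, criteria$intensity_factor) &
    proj_mask(egfp_mean, criteria$intensity_factor)
  if (!any(both)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(both * 1))
  labm <- as.matrix(EBImage::imageData(lab))
  h <- nrow(labm); w <- ncol(labm); half <- (roi_size - 1L) %/% 2L
  out <- list()
  for (id in seq_len(max(labm))) {
    idx <- which(labm == id, arr.ind = TRUE)
    r <- min(max(round(mean(idx[, 1])), 1L + half), h - half)
    cl <- min(max(round(mean(idx[, 2])), 1L + half), w - half)
    out[[length(out) + 1L]] <- roi_selection(r, cl, roi_size,
                                             colocalized = TRUE)
  }
  out
}

#' Extract the per-frame intensity trace of one ROI
#'
#' @param stack An h x w x n array.
#' @param roi A [roi_selection()], fully inside the image.
#' @param camera A [camera_spec()] attached to the resulting trace.
#' @param stat Pixel statistic per frame: `"sum"` (default; keeps Poisson
#'   statistics interpretable) or `"mean"`.
#' @return An [intensity_trace()].
#' @export
extract_roi_trace <- function(stack, roi, camera = camera_spec(),
                              stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  stopifnot(is.array(stack), length(dim(stack)) == 3,
            inherits(roi, "roi_selection"))
  half <- (roi$size - 1L) %/% 2L
  rows <- (roi$row - half):(roi$row + half)
  cols <- (roi$col - half):(roi$col + half)
  if (min(rows) < 1 || max(rows) > dim(stack)[1] ||
      min(cols) < 1 || max(cols) > dim(stack)[2])
    stop("ROI extends outside the image")
  sub <- stack[rows, cols, , drop = FALSE]
  v <- apply(sub, 3, if (stat == "sum") sum else mean)
  intensity_trace(v, camera)
}

#' Robust background level and noise of an intensity trace
#'
#' Level is the median, noise the MAD scaled to the SD of a Gaussian
#' (1.4826 x), both insensitive to sparse binding events.
#'
#' @param trace An [intensity_trace()] of at least 100 frames.
#' @return List with `level` and `noise_sd`.
#' @export
estimate_background <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (length(trace$values) < 100)
    stop("background estimation needs at least 100 frames")
  list(level = stats::median(trace$values),
       noise_sd = stats::mad(trace$values))
}

#' Detect binding events in an ROI intensity trace
#'
#' Events are maximal runs of consecutive frames with intensity at least
#' `level + intensity_factor * noise_sd` above background (no gap closing:
#' one sub-threshold frame ends an event).  Each event is checked for a
#' single-step appearance: the coefficient of variation of its
#' background-subtracted plateau (interior frames; the first and last frame
#' of an event are partial exposures) must not exceed `max_plateau_cv`.  Events
#' failing the check are recorded but flagged and excluded from the dwell
#' sample when `require_single_step` is set.
#'
#' @param trace An [intensity_trace()].
#' @param criteria A [selection_criteria()].
#' @param camera A [camera_spec()]; defaults to the trace's own camera.
#' @param background Optional list `(level, noise_sd)`; estimated from the
#'   trace when `NULL`.
#' @return List with `events` (data frame `start_frame`, `n_frames`,
#'   `mean_intensity`, `plateau_cv`, `accepted`, `reason`) and `dwells`
#'   (a [dwell_sample()] of accepted events).
#' @export
detect_events <- function(trace, criteria = selection_criteria(),
                          camera = NULL, background = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (is.null(camera)) camera <- trace$camera
  if (is.null(background)) background <- estimate_background(trace)
  thr <- background$level + criteria$intensity_factor * background$noise_sd
  v <- trace$values
  above <- v >= thr & v > background$level  # guard for zero-noise traces
  events <- data.frame(start_frame = integer(0), n_frames = integer(0),
                       mean_intensity = numeric(0), plateau_cv = numeric(0),
                       accepted = logical(0), reason = character(0))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ii <- which(r$values)
    events <- do.call(rbind, lapply(ii, function(i) {
      seg <- v[starts[i]:ends[i]] - background$level
      # the plateau excludes the first and last frame (partial exposures)
      plateau <- if (length(seg) >= 3) seg[-c(1, length(seg))] else seg
      cv <- if (length(plateau) > 1 && mean(plateau) > 0)
        stats::sd(plateau) / mean(plateau) else 0
      ok <- !(criteria$require_single_step && cv > criteria$max_plateau_cv)
      data.frame(start_frame = starts[i], n_frames = ends[i] - starts[i] + 1L,
                 mean_intensity = mean(v[starts[i]:ends[i]]), plateau_cv = cv,
                 accepted = ok,
                 reason = if (ok) "" else "plateau CV above single-step cap")
    }))
    rownames(events) <- NULL
  }
  dw <- events$n_frames[events$accepted] * camera$frame_interval
  list(events = events,
       dwells = dwell_sample(dw, threshold = NA_real_,
                             frame_interval = camera$frame_interval,
                             provenance = "detected"))
}

#' Apply recording- and ROI-level selection criteria
#'
#' Recordings whose background ROIs show more than the allowed number of
#' events per 10 minutes are excluded wholesale.  Within an accepted
#' recording, ROIs are kept only if they have strictly more than
#' `min_events_per_roi` events, events occur throughout the recording
#' (largest gap between consecutive event starts at most `max_gap_fraction`
#' of the recording), and — when required — the ROI was co-localized.  Every
#' exclusion is logged with its reason.  The operation is idempotent.
#'
#' @param roi_results Named list, one element per ROI: list with `roi`
#'   (a [roi_selection()]), `events` and `dwells` as from [detect_events()].
#' @param background_event_count Total event count over the recording's
#'   background ROIs.
#' @param duration Recording duration (s).
#' @param criteria A [selection_criteria()].
#' @return List with `accepted` (filtered subset of `roi_results`),
#'   `recording_excluded` (logical) and `audit` (data frame `roi_id`,
#'   `accepted`, `reason`).
#' @export
apply_selection <- function(roi_results, background_event_count, duration,
                            criteria = selection_criteria()) {
  stopifnot(is.list(roi_results), duration > 0)
  bg_per_10min <- background_event_count * 600 / duration
  if (bg_per_10min > criteria$max_background_events_per_10min) {
    audit <- data.frame(
      roi_id = names2(roi_results), accepted = FALSE,
      reason = sprintf("recording excluded: %.3g background events per 10 min",
                       bg_per_10min))
    return(list(accepted = list(), recording_excluded = TRUE, audit = audit))
  }
  ids <- names2(roi_results)
  audit <- data.frame(roi_id = ids, accepted = TRUE, reason = "")
  for (i in seq_along(roi_results)) {
    rr <- roi_results[[i]]
    n_ev <- nrow(rr$events[rr$events$accepted, , drop = FALSE])
    reason <- NULL
    if (criteria$require_colocalization &&
        !isTRUE(rr$roi$colocalized))
      reason <- "not colocalized with the static channel"
    else if (n_ev <= criteria$min_events_per_roi)
      reason <- sprintf("only %d events (more than %d required)",
                        n_ev, criteria$min_events_per_roi)
    else {
      starts_s <- rr$events$start_frame[rr$events$accepted] *
        rr$dwells$frame_interval
      gaps <- diff(c(0, sort(starts_s), duration))
      if (max(gaps) > criteria$max_gap_fraction * duration)
        reason <- "events not spread throughout the recording"
    }
    if (!is.null(reason)) {
      audit$accepted[i] <- FALSE
      audit$reason[i] <- reason
    }
  }
  list(accepted = roi_results[audit$accepted],
       recording_excluded = FALSE, audit = audit)
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- rep("", length(x))
  ifelse(nm == "", sprintf("roi_%d", seq_along(x)), nm)
}
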