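#' Read and write dwell-time lists, traces, events and image stacks
#'
#' Plain-CSV interchange: dwell lists have a single `dwell_s` column; traces
#' have `frame_index` (0-based), `time_s`, `intensity`; event lists have
#' `start_s`, `duration_s`, `motor_index`, `species`.  Image stacks are
#' multi-page TIFF, one file per channel, written as 16-bit unsigned with a
#' recorded intensity scale.
#'
#' @param sample A [dwell_sample()].
#' @param path File path.
#' @name smatpase-io
NULL

#' @rdname smatpase-io
#' @export
write_dwells_csv <- function(sample, path) {
  stopifnot(inherits(sample, "dwell_sample"))
  utils::write.csv(data.frame(dwell_s = sample$dwells), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname smatpase-io
#' @param provenance Provenance recorded in the reconstructed sample.
#' @export
read_dwells_csv <- function(path, provenance = "detected") {
  df <- utils::read.csv(path)
  stopifnot("dwell_s" %in% names(df))
  dwell_sample(df$dwell_s, provenance = provenance)
}

#' @rdname smatpase-io
#' @param events A `binding_events` data frame.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(
    data.frame(start_s = events$start, duration_s = events$duration,
               motor_index = events$motor_index, species = events$species),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname smatpase-io
#' @param trace An [intensity_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$values)
  utils::write.csv(
    data.frame(frame_index = seq_len(n) - 1L,
               time_s = (seq_len(n) - 1L) * trace$camera$frame_interval,
               intensity = trace$values),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname smatpase-io
#' @param camera A [camera_spec()] attached to the trace on reading.
#' @export
read_trace_csv <- function(path, camera = camera_spec()) {
  df <- utils::read.csv(path)
  stopifnot("intensity" %in% names(df))
  intensity_trace(df$intensity, camera)
}

#' @rdname smatpase-io
#' @param stack h x w x n array (or h x w matrix for a single image).
#' @param scale Intensity corresponding to the 16-bit maximum; defaults to
#'   the stack maximum.
#' @export
write_stack_tiff <- function(stack, path, scale = NULL) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  if (is.null(scale)) scale <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[3]), function(i)
    pmin(pmax(stack[, , i] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(scale)
}

#' @rdname smatpase-io
#' @export
read_stack_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , i] <- p
  }
  arr * scale
}

#' Read and write run configuration as YAML
#'
#' Serializes a kinetic model plus camera (and free extra fields) so a
#' simulation run is fully described by one file together with its seed.
#'
#' @param model A [roi_kinetic_model()].
#' @param camera A [camera_spec()].
#' @param path File path.
#' @param extra Named list of additional fields (duration, seed, ...).
#' @return `read_run_config` returns a list with `model`, `camera`, `extra`.
#' @export
write_run_config <- function(model, camera, path, extra = list()) {
  cfg <- list(
    motors = lapply(model$motors, function(m)
      list(k_on = m$k_on, k_cat = m$k_cat, label = m$label)),
    hot_conc = model$hot_conc, cold_conc = model$cold_conc,
    cold_k_on = model$cold_k_on, photobleach_rate = model$photobleach_rate,
    camera = unclass(camera), extra = extra)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  motors <- lapply(cfg$motors, function(m)
    motor_spec(m$k_on, m$k_cat, m$label %||% "motor"))
  model <- roi_kinetic_model(
    motors, hot_conc = cfg$hot_conc,
    cold_conc = cfg$cold_conc %||% 0,
    cold_k_on = cfg$cold_k_on,
    photobleach_rate = cfg$photobleach_rate %||% 0)
  cam <- do.call(camera_spec, cfg$camera)
  list(model = model, camera = cam, extra = cfg$extra %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a fit report as JSON
#'
#' @param fit A [fit_multiexp()] result.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "multiexp_fit"))
  jsonlite::write_json(
    list(n_phases = nrow(fit$phases), phases = fit$phases, scale = fit$scale,
         rss = fit$rss, r_squared = fit$r_squared, aicc = fit$aicc,
         n = fit$n, converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
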