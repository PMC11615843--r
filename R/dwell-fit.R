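#' Complementary cumulative distribution of dwell times
#'
#' For each distinct observed dwell value `t_j`, the curve records the number
#' of dwells with duration >= `t_j`.  Tied dwells share a point.  This is the
#' form in which dwell data are fitted by sums of exponentials: for an
#' m-phase mixture the expectation is `N * sum_i A_i * exp(-k_i * t)`.
#'
#' @param sample A [dwell_sample()] (or bare numeric vector) with >= 1 dwell.
#' @return An object of class `cumulative_distribution`: list with sorted
#'   unique times `t`, counts `count`, total `n` and the raw `dwells`.
#' @examples
#' cumulative_distribution(dwell_sample(c(1, 2, 3)))
#' @export
cumulative_distribution <- function(sample) {
  dw <- if (inherits(sample, "dwell_sample")) sample$dwells else as.numeric(sample)
  if (!length(dw)) stop("empty dwell sample")
  t <- sort(unique(dw))
  n <- length(dw)
  # count of dwells >= t_j
  count <- n - findInterval(t, sort(dw), left.open = TRUE)
  structure(list(t = t, count = count, n = n, dwells = dw),
            class = "cumulative_distribution")
}

#' Subtract half a frame interval from measured dwell times
#'
#' Threshold-based dwell measurement on digitized traces systematically
#' lengthens events (most severely, in relative terms, for short events and
#' low thresholds).  Subtracting half the frame time from every dwell before
#' fitting largely eliminates the resulting underestimation of fast rate
#' constants for thresholds below 0.5.
#'
#' @param sample A [dwell_sample()].
#' @param camera A [camera_spec()], or `NULL` to use the sample's own
#'   `frame_interval`.
#' @return A corrected [dwell_sample()] with `half_frame_corrected = TRUE`.
#'   Dwells not exceeding half a frame are dropped with a warning.
#' @export
half_frame_correct <- function(sample, camera = NULL) {
  stopifnot(inherits(sample, "dwell_sample"))
  fi <- if (!is.null(camera)) camera$frame_interval else sample$frame_interval
  if (!is.finite(fi)) stop("no frame interval available")
  if (isTRUE(sample$half_frame_corrected))
    stop("sample is already half-frame corrected")
  keep <- sample$dwells > fi / 2
  if (!all(keep))
    warning(sprintf("%d dwell(s) <= frame_interval/2 dropped", sum(!keep)))
  dwell_sample(sample$dwells[keep] - fi / 2, threshold = sample$threshold,
               frame_interval = fi, half_frame_corrected = TRUE,
               provenance = sample$provenance)
}

multiexp_value <- function(t, k, B) {
  as.vector(exp(-outer(t, k)) %*% B)
}

# Initial amplitudes for fixed rates by linear least squares, clamped positive.
init_amplitudes <- function(t, y, k) {
  X <- exp(-outer(t, k))
  B <- tryCatch(stats::coef(stats::lm.fit(X, y)), error = function(e) NULL)
  if (is.null(B) || anyNA(B)) B <- rep(max(y) / length(k), length(k))
  pmax(B, 1e-6 * max(y))
}

# parameter vector layout: (k_1..k_m, log w_1..log w_{m-1}), w_m = 1;
# amplitudes A = w / sum(w) so they sum to one by construction
par_to_amp <- function(p, m) {
  w <- c(exp(p[seq_len(m - 1L) + m]), 1)
  w / sum(w)
}

#' Fit a multi-exponential decay to a cumulative dwell-time distribution
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt, multi-start) of
#' `y(t) = N * sum_i A_i * exp(-k_i * t)` to the complementary cumulative
#' counts, with the plateau fixed at zero and the scale fixed at the total
#' event count `N` (a complementary cumulative curve equals `N` at `t = 0`),
#' so the amplitudes `A_i` are fractions summing to one.  Anchoring the
#' scale is what makes the fit sensitive to digitization: measured dwells
#' are systematically lengthened by frame quantization, and a fit whose
#' value at zero is pinned to `N` must lower the fast rate to reach the
#' data — the origin of the fast-rate underestimation that the half-frame
#' correction repairs.  Phases are sorted fast to slow.  Starting rate sets
#' are log-spaced over the span of the data and quantile-derived from the
#' raw dwells; starting amplitudes come from a linear solve at fixed rates.
#' Asymptotic 95% confidence intervals are derived from the least-squares
#' covariance; the small-sample-corrected Akaike criterion is
#' `AICc = n*ln(RSS/n) + 2K + 2K(K+1)/(n-K-1)` with `K` = number of fitted
#' parameters plus one (for the error variance).
#'
#' Note the points of a cumulative curve are serially correlated, so the CIs
#' are approximate; see [fit_multiexp_ml()] for a maximum-likelihood
#' cross-check on the raw dwells.
#'
#' @param cd A [cumulative_distribution()].
#' @param n_phases Number of exponential phases (1-3).
#' @param camera Optional [camera_spec()]; recorded in the result only.
#' @return An object of class `multiexp_fit`: list with `phases` (data frame
#'   of `rate`, `rate_lo`, `rate_hi`, `amplitude`, `amp_lo`, `amp_hi`),
#'   `scale` (= N), `rss`, `r_squared`, `aicc`, `n_points`, `n`, `converged`.
#' @export
fit_multiexp <- function(cd, n_phases, camera = NULL) {
  stopifnot(inherits(cd, "cumulative_distribution"),
            n_phases %in% 1:3)
  m <- as.integer(n_phases)
  t <- cd$t; y <- cd$count; N <- cd$n
  if (N < 5 * 2 * m)
    stop(sprintf("need at least %d dwells to fit %d phases", 10 * m, m))

  starts <- list()
  t_min <- max(min(t), 1e-6); t_max <- max(t)
  # geometric ladder spanning the observable rate range
  for (shift in c(1, 0.3, 3)) {
    k0 <- shift * exp(seq(log(2 / t_max), log(2 / t_min), length.out = m + 2L))[
      seq(2L, m + 1L)]
    starts[[length(starts) + 1L]] <- sort(k0, decreasing = TRUE)
  }
  # quantile-derived rates from the raw dwells
  qs <- stats::quantile(cd$dwells, probs = seq(0.15, 0.9, length.out = m))
  qs[qs <= 0] <- t_min
  starts[[length(starts) + 1L]] <- sort(unname(1 / qs), decreasing = TRUE)

  # sequential start: the (m-1)-phase solution plus one slower phase, so a
  # low-amplitude slow tail is not missed
  start_amps <- vector("list", length(starts))
  if (m > 1) {
    sub <- tryCatch(fit_multiexp(cd, m - 1L), error = function(e) NULL)
    if (!is.null(sub)) {
      k_extra <- min(sub$phases$rate) / 10
      starts[[length(starts) + 1L]] <- c(sub$phases$rate, k_extra)
      start_amps[[length(starts)]] <- c(sub$phases$amplitude * 0.98, 0.02)
    }
  }

  resid_fn <- function(p) {
    y - N * multiexp_value(t, p[1:m], par_to_amp(p, m))
  }
  lower <- c(rep(1e-9, m), rep(-30, m - 1L))
  upper <- c(rep(Inf, m), rep(30, m - 1L))
  best <- NULL
  for (s in seq_along(starts)) {
    k0 <- starts[[s]]
    if (anyDuplicated(k0)) k0 <- k0 * (1 + 0.01 * seq_along(k0))
    ord0 <- order(k0, decreasing = TRUE)
    k0 <- k0[ord0]
    A0 <- if (s <= length(start_amps) && !is.null(start_amps[[s]]))
      start_amps[[s]][ord0] else init_amplitudes(t, y, k0)
    A0 <- pmax(A0 / sum(A0), 1e-6)
    par0 <- c(k0, log(A0[-m] / A0[m]))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("multi-exponential fit failed from every start")

  p <- best$par
  k <- p[1:m]
  A <- par_to_amp(p, m)
  ord <- order(k, -A, decreasing = TRUE)
  rss <- best$deviance
  n_pts <- length(t)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  n_par <- 2 * m - 1L
  K <- n_par + 1L
  aicc <- n_pts * log(rss / n_pts) + 2 * K +
    if (n_pts - K - 1 > 0) 2 * K * (K + 1) / (n_pts - K - 1) else Inf

  # asymptotic covariance of (k, log w) from the Gauss-Newton hessian
  dof <- n_pts - n_par
  vc <- tryCatch({
    sigma2 <- rss / dof
    sigma2 * solve(best$hessian)
  }, error = function(e) matrix(NA_real_, n_par, n_par))
  tq <- if (dof > 0) stats::qt(0.975, dof) else NA_real_
  k_se <- sqrt(pmax(diag(vc)[1:m], 0))
  # delta method for A = w / sum(w) with respect to log w_1..log w_{m-1}
  amp_se <- rep(0, m)
  if (m > 1) {
    vcw <- vc[(m + 1):n_par, (m + 1):n_par, drop = FALSE]
    if (!anyNA(vcw)) {
      for (i in 1:m) {
        g <- vapply(seq_len(m - 1L), function(j)
          A[j] * ((i == j) - A[i]), numeric(1))
        amp_se[i] <- sqrt(max(0, drop(crossprod(g, vcw %*% g))))
      }
    } else amp_se <- rep(NA_real_, m)
  }
  phases <- data.frame(
    rate = k[ord],
    rate_lo = (k - tq * k_se)[ord], rate_hi = (k + tq * k_se)[ord],
    amplitude = A[ord],
    amp_lo = (A - tq * amp_se)[ord], amp_hi = (A + tq * amp_se)[ord])
  rownames(phases) <- NULL

  structure(list(phases = phases, scale = N, rss = rss, r_squared = r2,
                 aicc = aicc, n_points = n_pts, n = N,
                 converged = best$info %in% 1:3, camera = camera,
                 dwells = cd$dwells),
            class = "multiexp_fit")
}

#' @export
print.multiexp_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<multiexp_fit> %d phase(s), N = %d (%d curve points)\n",
              nrow(x$phases), x$n, x$n_points))
  print(format(x$phases, digits = digits), ...)
  cat(sprintf("R^2 = %.5g  AICc = %.6g  converged = %s\n",
              x$r_squared, x$aicc, x$converged))
  invisible(x)
}

#' Maximum-likelihood exponential-mixture fit (cross-check mode)
#'
#' Fits the same m-phase model to the raw dwell times by direct maximum
#' likelihood (EM algorithm for an exponential mixture).  Used as an
#' independent cross-check on the least-squares cumulative-curve fit.
#'
#' @param sample A [dwell_sample()] or numeric vector of dwells.
#' @param n_phases Number of phases (1-3).
#' @param max_iter,tol EM iteration controls.
#' @return List with `rates`, `amplitudes` (fast to slow), `loglik`,
#'   `n_iter`.
#' @export
fit_multiexp_ml <- function(sample, n_phases, max_iter = 2000, tol = 1e-10) {
  dw <- if (inherits(sample, "dwell_sample")) sample$dwells else as.numeric(sample)
  m <- as.integer(n_phases)
  stopifnot(m >= 1, length(dw) >= 5 * m)
  qs <- stats::quantile(dw, probs = seq(0.15, 0.9, length.out = m))
  k <- sort(unname(1 / pmax(qs, 1e-9)), decreasing = TRUE)
  if (anyDuplicated(k)) k <- k * (1 + 0.01 * seq_along(k))
  A <- rep(1 / m, m)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:m, function(i) A[i] * k[i] * exp(-k[i] * dw),
                   numeric(length(dw)))
    dens <- pmax(dens, 1e-300)
    tot <- rowSums(dens)
    resp <- dens / tot
    A <- colMeans(resp)
    k <- colSums(resp) / colSums(resp * dw)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(k, decreasing = TRUE)
  list(rates = k[ord], amplitudes = A[ord], loglik = ll, n_iter = it)
}

#' Compare multi-exponential fits by small-sample Akaike criterion
#'
#' The default comparison computes AICc from the exponential-mixture
#' log-likelihood of the raw dwell times (`AICc = -2*lnL + 2K +
#' 2K(K+1)/(N-K-1)`, with `K = 2m - 1` free parameters refit by EM for each
#' phase count).  The points of a cumulative curve are strongly serially
#' correlated, so an AICc built from the curve's residual sum of squares
#' treats one sample fluctuation as hundreds of independent observations and
#' routinely manufactures spurious phases; the likelihood of the independent
#' dwells does not.  `method = "ls"` gives the residual-sum-of-squares AICc
#' of the curve fits instead, for comparison with curve-fitting software.
#'
#' The selected model has the lowest AICc, except that a model with fewer
#' phases is preferred whenever its AICc lies within `margin` of the
#' minimum — an extra exponential phase must improve AICc by more than the
#' margin to be accepted.
#'
#' @param fits A list of [fit_multiexp()] results on identical data.
#' @param margin AICc improvement an additional phase must exceed
#'   (default 2).
#' @param method `"ml"` (mixture-likelihood AICc on the raw dwells, default)
#'   or `"ls"` (least-squares AICc of the cumulative-curve fits).
#' @return A data frame (`n_phases`, `aicc`, `delta_aicc`, `r_squared`,
#'   `selected`).
#' @export
compare_models <- function(fits, margin = 2, method = c("ml", "ls")) {
  method <- match.arg(method)
  stopifnot(is.list(fits), length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "multiexp_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  np <- vapply(fits, `[[`, numeric(1), "n_points")
  same_data <- length(unique(ns)) == 1L && length(unique(np)) == 1L &&
    all(vapply(fits, function(f) identical(sort(f$dwells), sort(fits[[1]]$dwells)),
               logical(1)))
  if (!same_data) stop("fits must be on identical data")
  m_all <- vapply(fits, function(f) nrow(f$phases), integer(1))
  aicc <- if (method == "ls") {
    vapply(fits, `[[`, numeric(1), "aicc")
  } else {
    N <- ns[1]
    vapply(seq_along(fits), function(i) {
      m <- m_all[i]
      ll <- if (m == 1)
        sum(stats::dexp(fits[[i]]$dwells, 1 / mean(fits[[i]]$dwells),
                        log = TRUE))
      else fit_multiexp_ml(fits[[i]]$dwells, m)$loglik
      K <- 2 * m - 1
      -2 * ll + 2 * K + 2 * K * (K + 1) / (N - K - 1)
    }, numeric(1))
  }
  out <- data.frame(
    n_phases = m_all,
    aicc = aicc,
    delta_aicc = aicc - min(aicc),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"))
  candidates <- which(out$delta_aicc <= margin)
  sel <- candidates[which.min(out$n_phases[candidates])]
  out$selected <- seq_len(nrow(out)) == sel
  out
}

as_amp_rate <- function(fit, amplitudes, rates) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "multiexp_fit"))
    list(A = fit$phases$amplitude, k = fit$phases$rate)
  } else {
    stopifnot(length(amplitudes) == length(rates), all(rates > 0),
              all(amplitudes >= 0))
    list(A = amplitudes / sum(amplitudes), k = rates)
  }
}

#' Dwell-time-weighted amplitude correction (and its bounds)
#'
#' Observed exponential amplitudes count *events*, and fast motors produce
#' more events per molecule, so the observed fast amplitude overestimates the
#' fraction of fast molecules.  Rescaling each amplitude by the mean dwell
#' time of its phase, `A_i^corr = (A_i / k_i) / sum_j (A_j / k_j)`, converts
#' event fractions to time-weighted molecule fractions; for two phases this
#' is the familiar `A_corr_fast = A_obs_fast * k_slow / k_fast` (normalized).
#' Because this correction itself *under*-weights fast molecules whenever
#' binding (not turnover) limits the event rate, the corrected and observed
#' amplitudes bracket the true molecule fraction: the corrected value is the
#' lower bound for fast phases, the observed value the upper bound.
#'
#' @param fit A [fit_multiexp()] result, or `NULL` if `amplitudes`/`rates`
#'   are given directly.
#' @param amplitudes,rates Optional explicit observed amplitudes (fractions)
#'   and rate constants (s^-1), fast to slow.
#' @return Object of class `corrected_amplitudes`: data frame with columns
#'   `rate`, `observed`, `corrected`, `lower`, `upper`.
#' @examples
#' correct_amplitudes_eq1(NULL, amplitudes = c(0.85, 0.15), rates = c(5, 0.2))
#' @export
correct_amplitudes_eq1 <- function(fit = NULL, amplitudes = NULL, rates = NULL) {
  ar <- as_amp_rate(fit, amplitudes, rates)
  if (any(ar$k == 0)) stop("all rate constants must be nonzero")
  w <- ar$A / ar$k
  corr <- w / sum(w)
  out <- data.frame(rate = ar$k, observed = ar$A, corrected = corr,
                    lower = pmin(corr, ar$A), upper = pmax(corr, ar$A))
  class(out) <- c("corrected_amplitudes", "data.frame")
  out
}

#' Cycle-time (event-frequency) corrected molecule fractions
#'
#' When the waiting time for ATP binding is not negligible, the number of
#' events a molecule produces per unit time is `r_i = 1 / (1/(k_on_i * C) +
#' 1/k_i)`, not `k_i`.  Dividing each observed amplitude by its event rate
#' and renormalizing, `n_i = (A_i / r_i) / sum_j (A_j / r_j)`, recovers the
#' fraction of *molecules* in each kinetic class.  In the dwell-limited
#' regime (`k_on * C >> k_i`) this reduces to the dwell-time-weighted
#' correction of [correct_amplitudes_eq1()].
#'
#' @inheritParams correct_amplitudes_eq1
#' @param k_on Binding rate constants per phase (nM^-1 s^-1), fast to slow.
#' @param hot_conc Fluorescent-ATP concentration (nM).
#' @return Data frame with `rate`, `k_on`, `event_rate`, `observed`,
#'   `molecule_fraction`.
#' @examples
#' cycle_corrected_fractions(NULL, amplitudes = c(0.714, 0.286),
#'   rates = c(8, 0.05), k_on = c(0.005, 0.0025), hot_conc = 5)
#' @export
cycle_corrected_fractions <- function(fit = NULL, amplitudes = NULL,
                                      rates = NULL, k_on, hot_conc) {
  ar <- as_amp_rate(fit, amplitudes, rates)
  stopifnot(length(k_on) == length(ar$k), all(k_on > 0), hot_conc > 0)
  r <- 1 / (1 / (k_on * hot_conc) + 1 / ar$k)
  w <- ar$A / r
  data.frame(rate = ar$k, k_on = k_on, event_rate = r, observed = ar$A,
             molecule_fraction = w / sum(w))
}
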