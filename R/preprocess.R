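#' @importFrom rlang %||%
#' @importFrom Rcpp sourceCpp
#' @useDynLib eoripen, .registration = TRUE
NULL

#' Logarithmic transform of a chromatogram
#'
#' Compresses the dynamic range of a trace whose peak heights span several
#' orders of magnitude: `intensity' = log10(intensity + offset)`. The
#' transform is monotone, so peak apex positions are preserved while minor
#' peaks become visible next to a dominant one.
#'
#' @param trace A chromatogram tibble (stage `"raw"`).
#' @param offset Additive offset in raw intensity units (default 1), so
#'   that zero-intensity grid points stay finite.
#' @return The trace with transformed intensities, stage `"logged"`.
#' @export
log_transform <- function(trace, offset = 1) {
  x <- trace$intensity + offset
  bad <- which(x <= 0)
  if (length(bad) > 0)
    stop("non-positive intensity + offset at index ", bad[1], call. = FALSE)
  out <- trace
  out$intensity <- log10(x)
  attr(out, "stage") <- "logged"
  attr(out, "log_offset") <- offset
  out
}

#' Parameters of the adaptive asymmetric least squares baseline
#'
#' The baseline estimator minimizes
#' `sum_i w_i (y_i - z_i)^2 + lambda * sum_i (d2 z_i)^2`
#' (second differences on the index grid), iterating the peaked-signal
#' weight rule: points below the current baseline get weight `1 - p`;
#' points above it get the adaptive weight `p * exp(-(y_i - z_i)/k)`, so
#' that tall peaks are ignored almost entirely while small positive
#' residuals still pull the baseline up. `k` sets the intensity scale (in
#' logged units) beyond which a residual counts as "peak".
#'
#' @param lam Smoothness penalty `lambda` (>= 0). Larger values give a
#'   stiffer baseline. Default 1e5.
#' @param p Asymmetry weight in (0, 0.5): weight budget of above-baseline
#'   points. Default 0.001.
#' @param k Peak-scale parameter (> 0), same units as the logged
#'   intensity, or `NULL` to use 0.1 * range(y) at fit time.
#' @param max_iter Maximum weight-update iterations. Default 50.
#' @param tol Convergence tolerance: relative change of the weight vector
#'   (sum of absolute weight changes over sum of weights). Default 1e-3.
#' @return A list of class `psalsa_params`.
#' @export
psalsa_params <- function(lam = 1e5, p = 0.001, k = NULL,
                          max_iter = 50L, tol = 1e-3) {
  if (lam < 0) stop("`lam` must be >= 0", call. = FALSE)
  if (p <= 0 || p >= 0.5)
    stop("`p` must be in (0, 0.5)", call. = FALSE)
  if (!is.null(k) && k <= 0) stop("`k` must be > 0", call. = FALSE)
  if (max_iter < 1 || tol <= 0)
    stop("`max_iter` and `tol` must be positive", call. = FALSE)
  structure(list(lam = lam, p = p, k = k,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "psalsa_params")
}

# Bands of W + lambda * D2'D2 for diagonal weights w (pentadiagonal SPD).
als_system_bands <- function(w, lam) {
  n <- length(w)
  d0 <- w + lam * c(1, 5, rep(6, n - 4), 5, 1)
  d1 <- lam * c(-2, rep(-4, n - 3), -2)
  d2 <- lam * rep(1, n - 2)
  list(d0 = d0, d1 = d1, d2 = d2)
}

# One penalized weighted least-squares solve: z = (W + lam D'D)^{-1} W y
als_solve <- function(y, w, lam) {
  b <- als_system_bands(w, lam)
  penta_chol_solve(b$d0, b$d1, b$d2, w * y)
}

#' Adaptive asymmetric least squares baseline estimation
#'
#' Estimates the slowly varying baseline under a peaky signal by iterating
#' penalized weighted least squares with the adaptive asymmetric weight
#' rule described in [psalsa_params()]. Intended to run on the logged
#' trace (see [preprocess_trace()] for the full chain).
#'
#' @param y Numeric vector of (logged) intensities, length >= 5. A
#'   chromatogram tibble is also accepted (its `intensity` column is used).
#' @param params A [psalsa_params()] object.
#' @return Numeric baseline vector of the same length, with attributes
#'   `converged` (logical) and `iterations`.
#' @export
psalsa_baseline <- function(y, params = psalsa_params()) {
  if (is.data.frame(y)) y <- y$intensity
  n <- length(y)
  if (n < 5) stop("need at least 5 points", call. = FALSE)
  k <- params$k %||% (0.1 * diff(range(y)))
  if (k <= 0) k <- 1e-12 # constant signal: scale degenerates

  w <- rep(1, n)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(params$max_iter)) {
    z <- als_solve(y, w, params$lam)
    r <- y - z
    w_new <- ifelse(r > 0, params$p * exp(-r / k), 1 - params$p)
    delta <- sum(abs(w_new - w)) / sum(w)
    w <- w_new
    if (delta < params$tol) {
      converged <- TRUE
      break
    }
  }
  z <- als_solve(y, w, params$lam)
  attr(z, "converged") <- converged
  attr(z, "iterations") <- it
  z
}

#' Subtract an estimated baseline from a logged trace
#'
#' @param trace A chromatogram tibble at stage `"logged"`.
#' @param baseline Numeric baseline vector of the same length, typically
#'   from [psalsa_baseline()].
#' @return The trace with `intensity - baseline`, stage
#'   `"baseline_corrected"`.
#' @export
subtract_baseline <- function(trace, baseline) {
  if (trace_stage(trace) != "logged")
    stop("baseline subtraction expects a logged trace (see log_transform)",
         call. = FALSE)
  if (length(baseline) != nrow(trace))
    stop("baseline length does not match the trace", call. = FALSE)
  out <- trace
  out$intensity <- trace$intensity - as.numeric(baseline)
  attr(out, "stage") <- "baseline_corrected"
  out
}

#' Noise statistics and detection threshold of a corrected trace
#'
#' Estimates the noise level from the quiet part of a baseline-corrected
#' trace — the fraction of grid points with the smallest absolute
#' intensity — and derives the peak-detection threshold as the noise mean
#' plus three times its standard deviation.
#'
#' @param trace A chromatogram tibble at stage `"baseline_corrected"`.
#' @param quiet_fraction Fraction (0, 1] of lowest-|intensity| points
#'   treated as noise. Default 0.2.
#' @return A list of class `noise_stats` with `mean`, `sd`, `threshold`.
#' @export
estimate_noise <- function(trace, quiet_fraction = 0.2) {
  if (trace_stage(trace) != "baseline_corrected")
    stop("noise estimation expects a baseline-corrected trace",
         call. = FALSE)
  if (quiet_fraction <= 0 || quiet_fraction > 1)
    stop("`quiet_fraction` must be in (0, 1]", call. = FALSE)
  y <- trace$intensity
  m <- max(1L, floor(quiet_fraction * length(y)))
  quiet <- y[order(abs(y))[seq_len(m)]]
  if (length(quiet) == 0) stop("empty quiet selection", call. = FALSE)
  mu <- mean(quiet)
  raw_sd <- if (length(quiet) > 1) stats::sd(quiet) else 0
  # Selecting the lowest-|y| fraction truncates the noise distribution to
  # its centre; under a normal noise model the truncated sd understates
  # the full sd by a known factor, which we invert so the threshold is
  # mean + 3 sd of the *full* noise distribution.
  noise_stats(mu, raw_sd / truncated_normal_sd(quiet_fraction))
}

# sd of a standard normal truncated to its central probability mass q
truncated_normal_sd <- function(q) {
  c_ <- stats::qnorm(0.5 + q / 2)
  sqrt(1 - 2 * c_ * stats::dnorm(c_) / (2 * stats::pnorm(c_) - 1))
}

#' Construct noise statistics directly
#'
#' @param mean,sd Noise mean and standard deviation (logged-intensity
#'   units, `sd >= 0`).
#' @return A `noise_stats` object with `threshold = mean + 3 * sd`.
#' @export
noise_stats <- function(mean, sd) {
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  structure(list(mean = mean, sd = sd, threshold = mean + 3 * sd),
            class = "noise_stats")
}

#' Full chromatogram enhancement chain
#'
#' Log transform, baseline estimation and subtraction, and noise
#' statistics, in that order.
#'
#' @param trace A raw chromatogram tibble.
#' @param params A [psalsa_params()] object.
#' @param offset Log-transform offset (raw intensity units).
#' @param quiet_fraction Passed to [estimate_noise()].
#' @return The corrected trace with a `noise_stats` attribute.
#' @export
preprocess_trace <- function(trace, params = psalsa_params(), offset = 1,
                             quiet_fraction = 0.2) {
  logged <- log_transform(trace, offset)
  z <- psalsa_baseline(logged$intensity, params)
  corrected <- subtract_baseline(logged, z)
  attr(corrected, "noise_stats") <- estimate_noise(corrected, quiet_fraction)
  corrected
}

#' Preprocess every trace of a study
#'
#' @param study A study tibble from [simulate_study()] or [read_study()].
#' @inheritParams preprocess_trace
#' @return The study tibble with its `trace` list-column replaced by
#'   baseline-corrected traces (each carrying its `noise_stats`).
#' @export
preprocess_study <- function(study, params = psalsa_params(), offset = 1,
                             quiet_fraction = 0.2) {
  study$trace <- purrr::map(study$trace, preprocess_trace,
                            params = params, offset = offset,
                            quiet_fraction = quiet_fraction)
  study
}
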