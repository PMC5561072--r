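# Per-curve processing: rupture detection on the retraction trace,
# worm-like-chain fitting of the final rupture event, and the numerical
# loading rate dF/dt just before rupture.

max_drop_within <- function(f, max_lag = 3) {
  # largest forward decrease of f within max_lag samples, per index
  n <- length(f)
  drop <- rep(-Inf, n)
  for (lag in seq_len(max_lag)) {
    idx <- seq_len(n - lag)
    drop[idx] <- pmax(drop[idx], f[idx] - f[idx + lag])
  }
  drop
}

#' Detect the last rupture event on a force curve
#'
#' Scans the retraction trace for the final discontinuous force drop: a
#' decrease of at least `5 * noise_sigma` within at most 3 samples with no
#' later drop of that size. The baseline and noise level are estimated from
#' the post-rupture tail (median, and 1.4826 x MAD); the reported rupture
#' force `f_r` is the pre-drop force minus the baseline.
#'
#' The drop criterion is evaluated on a width-3 running median of the
#' trace, which leaves a genuine (few-sample) rupture step intact while
#' making isolated noise excursions in a long baseline unable to mimic a
#' 5-sigma drop.
#'
#' Curves without a qualifying drop are returned with `detected = FALSE`
#' and a reason (`"no_rupture"`, or `"unstable_baseline"` when the
#' post-rupture tail disagrees with the final 10% of samples); the
#' processing pipeline counts these in its QC report rather than erroring.
#'
#' @param curve A [force_curve()].
#' @param noise_sigma Force noise SD in pN, or `NULL` (default) to estimate
#'   it from the trailing baseline.
#' @return A list: `detected`, `index` (last pre-drop sample), `f_r` (pN,
#'   baseline-corrected), `baseline` (pN), `noise_sigma` (pN), `reason`.
#' @export
detect_last_rupture <- function(curve, noise_sigma = NULL) {
  f <- curve$f
  n <- length(f)
  tail_idx <- seq.int(max(1, n - max(8, ceiling(0.1 * n)) + 1), n)
  sigma0 <- if (is.null(noise_sigma)) {
    max(mad(f[tail_idx]), 1e-3)
  } else {
    noise_sigma
  }
  baseline0 <- median(f[tail_idx])
  fs <- stats::runmed(f, 3)
  drop <- max_drop_within(fs)
  hits <- which(drop >= 5 * sigma0)
  if (length(hits) == 0) {
    return(list(detected = FALSE, index = NA_integer_, f_r = NA_real_,
                baseline = baseline0, noise_sigma = sigma0,
                reason = "no_rupture"))
  }
  k <- max(hits)
  post <- seq.int(min(k + 4, n), n)
  baseline <- median(f[post])
  sigma <- if (is.null(noise_sigma)) max(mad(f[post]), 1e-3) else noise_sigma
  if (abs(baseline - baseline0) > 5 * max(sigma, sigma0)) {
    return(list(detected = FALSE, index = k, f_r = NA_real_,
                baseline = baseline, noise_sigma = sigma,
                reason = "unstable_baseline"))
  }
  list(detected = TRUE, index = k, f_r = fs[k] - baseline,
       baseline = baseline, noise_sigma = sigma, reason = NA_character_)
}

wlc_dimensionless <- function(s) s + 0.25 / (1 - s)^2 - 0.25

#' Fit the worm-like chain to the last rupture event
#'
#' Least-squares fit of the WLC force law over the final loading segment:
#' from the previous rupture (or the force onset) up to the rupture index.
#' Free parameters are the apparent persistence length `l_app` (bounds
#' 0.01-100 nm) and contour length `L` (bounds: just above the largest
#' extension in the window, up to `1e4` times it). The fit is multi-started
#' over a grid of trial contour lengths; a poor fit returns
#' `converged = FALSE` rather than erroring.
#'
#' @param curve A [force_curve()].
#' @param rupture_index Last pre-drop sample, from [detect_last_rupture()].
#' @param baseline Baseline force (pN) subtracted before fitting.
#' @param noise_sigma Noise SD used to locate the force onset.
#' @param min_window Minimum number of samples in the fit window (default 8).
#' @return A list: `l_app` (nm), `L` (nm), `residual_rms` (pN), `window`
#'   (first and last sample index), `converged`.
#' @export
fit_last_event_wlc <- function(curve, rupture_index, baseline = 0,
                               noise_sigma = NULL, min_window = 8) {
  k <- rupture_index
  f <- curve$f - baseline
  if (is.null(noise_sigma)) {
    det <- detect_last_rupture(curve)
    noise_sigma <- det$noise_sigma
  }
  pre <- seq_len(max(k - 4, 0))
  prev_rupture <- if (length(pre) > 3) {
    hits <- which(max_drop_within(f[pre]) >= 5 * noise_sigma)
    if (length(hits)) max(hits) + 3L else 0L
  } else 0L
  low <- which(f[seq_len(k)] <= 2 * noise_sigma)
  onset <- if (length(low)) max(low) else 1L
  start <- max(prev_rupture + 1L, onset, 1L)
  window <- seq.int(start, k)
  if (length(window) < min_window) {
    abort(sprintf("WLC fit window too short: %d samples (need >= %d).",
                  length(window), min_window))
  }
  xw <- curve$x[window]
  fw <- f[window]
  temperature <- curve_temperature(curve)
  kT <- kBT(temperature)
  x_max <- max(xw)
  if (x_max <= 0 || max(fw) <= 0) {
    return(list(l_app = NA_real_, L = NA_real_, residual_rms = NA_real_,
                window = range(window), converged = FALSE))
  }
  lo <- c(0.01, x_max * (1 + 1e-6))
  hi <- c(100, 1e4 * x_max)
  resid_fn <- function(p) {
    s <- pmin(xw / p[2], 1 - 1e-9)
    fw - (kT / p[1]) * wlc_dimensionless(s)
  }
  f_end <- max(mean(fw[max(1, length(fw) - 4):length(fw)]), noise_sigma)
  best <- NULL
  for (L0 in x_max * c(1.02, 1.1, 1.4, 2.5)) {
    l0 <- kT * wlc_dimensionless(min(x_max / L0, 1 - 1e-9)) / f_end
    p0 <- pmin(pmax(c(l0, L0), lo * 1.01), hi * 0.99)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(list(l_app = NA_real_, L = NA_real_, residual_rms = NA_real_,
                window = range(window), converged = FALSE))
  }
  converged <- best$info %in% 1:4 && best$par[2] > x_max
  list(
    l_app = best$par[1], L = best$par[2],
    residual_rms = sqrt(best$deviance / length(window)),
    window = range(window),
    converged = converged
  )
}

#' Numerical loading rate at rupture
#'
#' Slope of a straight-line fit to force vs time over the final pre-rupture
#' window (by default the last 5% of samples before rupture, at least 8):
#' the operational `dF/dt` taken directly from the force-time trajectory.
#' The window length trades chord bias (the WLC stiffens toward rupture, so
#' a long window underestimates the end slope) against noise on the slope;
#' 5% balances the two on ground-truthed synthetic curves at typical
#' sampling rates, and the fraction is exposed for data sampled differently.
#' A non-positive slope (no adhesive load) returns `NA` so the event can be
#' excluded with a reason.
#'
#' @param curve A [force_curve()].
#' @param rupture_index Last pre-rupture sample index.
#' @param window_fraction Fraction of the pre-rupture samples used.
#' @return Loading rate in pN/s, or `NA_real_` when the slope is not
#'   positive.
#' @export
numerical_loading_rate <- function(curve, rupture_index,
                                   window_fraction = 0.05) {
  k <- rupture_index
  if (k < 8) abort("need at least 8 samples before rupture for dF/dt.")
  m <- max(8L, floor(window_fraction * k))
  idx <- seq.int(k - m + 1L, k)
  slope <- unname(coef(lm(curve$f[idx] ~ curve$t[idx]))[2])
  # slopes below 1e-6 pN/s are numerically zero (flat trace), not a load
  if (!is.finite(slope) || slope < 1e-6) {
    return(NA_real_)
  }
  slope
}
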