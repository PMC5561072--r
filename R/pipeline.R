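# The analysis pipeline from a set of force curves to the fitted bond:
#   process_curves()  - detect + WLC-fit + dF/dt per curve -> event table
#   filter_events()   - keep single-molecule events by apparent persistence length
#   build_spectrum()  - velocity-grouped mean force vs mean loading rate
# then fit_single_bond_model() and summarize_landscape().

#' Extract rupture events from force curves
#'
#' Runs, per curve: last-rupture detection, WLC fitting of the final
#' loading segment, and the numerical loading rate `dF/dt` just before
#' rupture. Curves without a detectable rupture, with an unstable baseline,
#' with a too-short fit window, or with a non-positive loading rate are
#' dropped and tallied in the QC report attached to the result.
#'
#' @param curves A list of [force_curve()] objects, or a directory path
#'   containing curve CSV files.
#' @param rate_method `"numeric"` (default; `dF/dt` from the trajectory) or
#'   `"wlc"` (analytic tether stiffness at the rupture force, using the
#'   fitted WLC). Both are recorded when available; this chooses which one
#'   fills the `r` column used downstream.
#' @param noise_sigma Optional fixed noise SD (pN); default auto-estimate.
#' @param window_fraction Pre-rupture window for the numerical loading
#'   rate, as a fraction of the samples before rupture (see
#'   [numerical_loading_rate()]).
#' @return A tibble with one row per usable rupture event: `curve_id`,
#'   `velocity`, `f_r`, `r`, `r_numeric`, `r_wlc`, `l_app`, `L`,
#'   `fit_rms`, `converged`. QC counts are in `attr(, "qc")`:
#'   `n_curves`, `n_ruptures`, `n_converged_fits`, `n_events`, `reasons`.
#' @export
process_curves <- function(curves, rate_method = c("numeric", "wlc"),
                           noise_sigma = NULL, window_fraction = 0.05) {
  rate_method <- match.arg(rate_method)
  if (is.character(curves) && length(curves) == 1) {
    curves <- read_curve_dataset(curves)
  }
  reasons <- character(0)
  rows <- purrr::map(curves, function(curve) {
    det <- detect_last_rupture(curve, noise_sigma)
    if (!det$detected) {
      reasons <<- c(reasons, det$reason)
      return(NULL)
    }
    fit <- tryCatch(
      fit_last_event_wlc(curve, det$index, baseline = det$baseline,
                         noise_sigma = det$noise_sigma),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      reasons <<- c(reasons, "short_window")
      return(NULL)
    }
    r_num <- tryCatch(
      numerical_loading_rate(curve, det$index, window_fraction),
      error = function(e) NA_real_
    )
    r_wlc <- if (isTRUE(fit$converged) && det$f_r > 0) {
      tryCatch(
        loading_rate(det$f_r, curve_velocity(curve), fit$l_app, fit$L,
                     curve_temperature(curve)),
        error = function(e) NA_real_
      )
    } else {
      NA_real_
    }
    r <- if (rate_method == "numeric") r_num else r_wlc
    if (!is.finite(r) || r <= 0) {
      reasons <<- c(reasons, "nonpositive_rate")
      return(NULL)
    }
    tibble(
      curve_id = curve_id(curve),
      velocity = curve_velocity(curve),
      f_r = det$f_r,
      r = r, r_numeric = r_num, r_wlc = r_wlc,
      l_app = fit$l_app, L = fit$L,
      fit_rms = fit$residual_rms,
      converged = fit$converged
    )
  })
  events <- bind_rows(rows)
  qc <- list(
    n_curves = length(curves),
    n_ruptures = length(curves) - sum(reasons %in% c("no_rupture", "unstable_baseline")),
    n_converged_fits = if (nrow(events)) sum(events$converged) else 0L,
    n_events = nrow(events),
    reasons = as.list(table(reasons))
  )
  attr(events, "qc") <- qc
  events
}

#' Keep single-molecule rupture events by apparent persistence length
#'
#' A cluster of N chains loaded in parallel has apparent persistence length
#' `l_p / N`, so events fitted with `l_app` well below the single-polymer
#' persistence length involve multiple chains. The filter keeps events with
#' `threshold_fraction * l_p <= l_app <= max_fraction * l_p` (and a
#' converged WLC fit); the lower cut isolates single molecules, the upper
#' cut removes nonphysically steep fits.
#'
#' @param events Event tibble from [process_curves()] (or any data frame
#'   with `l_app` and, optionally, `converged`).
#' @param l_p Single-polymer persistence length, nm.
#' @param threshold_fraction Lower cut as a fraction of `l_p`; in
#'   `(0, 1]`, default 0.7.
#' @param max_fraction Upper cut as a multiple of `l_p`; `>= 1`, default 2.
#' @return The filtered tibble, with `attr(, "filter_report")`: counts in,
#'   kept and removed, and a histogram of the implied chain count
#'   `N = l_p / l_app` (rounded) among the incoming events.
#' @export
filter_events <- function(events, l_p, threshold_fraction = 0.7,
                          max_fraction = 2.0) {
  if (!(threshold_fraction > 0 && threshold_fraction <= 1)) {
    abort("`threshold_fraction` must be in (0, 1].")
  }
  if (!(max_fraction >= 1)) abort("`max_fraction` must be >= 1.")
  if (l_p <= 0) abort("`l_p` must be positive (nm).")
  events <- as_tibble(events)
  ok <- is.finite(events$l_app) & events$l_app > 0
  if ("converged" %in% names(events)) ok <- ok & events$converged
  keep <- ok &
    events$l_app >= threshold_fraction * l_p &
    events$l_app <= max_fraction * l_p
  out <- events[keep, , drop = FALSE]
  N_hist <- table(round(estimate_N(pmax(events$l_app[ok], 1e-12), l_p)))
  report <- list(
    n_in = nrow(events),
    n_kept = nrow(out),
    n_removed = nrow(events) - nrow(out),
    threshold_fraction = threshold_fraction,
    max_fraction = max_fraction,
    l_p = l_p,
    N_histogram = as.list(N_hist)
  )
  if (nrow(out) == 0) {
    abort(sprintf(
      "all %d events removed by the l_app filter [%g, %g] x l_p = %g nm; review the threshold or l_p.",
      nrow(events), threshold_fraction, max_fraction, l_p
    ))
  }
  attr(out, "filter_report") <- report
  out
}

#' Velocity-grouped mean-force spectrum
#'
#' Averages the filtered rupture events within each recorded retraction
#' velocity: arithmetic mean of the loading rate, arithmetic mean and
#' standard error of the rupture force, and the event count. Plotting and
#' fitting mean force against mean loading rate (rather than the raw
#' scatter, which only traces the tether's own force-vs-dF/dt curve) is
#' what makes the single-bond model applicable to polymer-linked data.
#'
#' @param events Event tibble with columns `velocity`, `f_r`, `r`.
#' @param min_events Velocities with fewer events than this are flagged
#'   (`low_n = TRUE`) and reported with a warning; default 5.
#' @return A tibble of class `dfs_spectrum`, one row per velocity:
#'   `velocity`, `mean_r`, `mean_f`, `sem_f`, `n_events`, `low_n`.
#' @export
build_spectrum <- function(events, min_events = 5) {
  events <- as_tibble(events)
  if (nrow(events) == 0) {
    abort("no events to average: the spectrum would be empty.")
  }
  out <- events |>
    group_by(.data$velocity) |>
    summarise(
      mean_r = mean(.data$r),
      mean_f = mean(.data$f_r),
      sem_f = sd(.data$f_r) / sqrt(n()),
      n_events = n(),
      .groups = "drop"
    ) |>
    mutate(low_n = .data$n_events < min_events) |>
    arrange(.data$mean_r)
  if (any(out$low_n)) {
    warn(sprintf("%d velocity group(s) have fewer than %d events.",
                 sum(out$low_n), min_events))
  }
  class(out) <- c("dfs_spectrum", class(out))
  out
}

#' QC report of a processed dataset as JSON
#'
#' @param events Event tibble from [process_curves()] (optionally after
#'   [filter_events()]; filter counts are included when present).
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
qc_report_json <- function(events, path = NULL) {
  qc <- attr(events, "qc")
  fr <- attr(events, "filter_report")
  obj <- c(
    qc %||% list(),
    if (!is.null(fr)) list(n_passed_filter = fr$n_kept, filter = fr)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
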