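# ggplot2 views of the main result types.

#' Plot a force curve with its detected rupture
#'
#' @param curve A [force_curve()].
#' @param detection Optional result of [detect_last_rupture()]; computed
#'   when `NULL`.
#' @param against `"x"` (separation, default) or `"t"` (time).
#' @return A ggplot.
#' @export
plot_force_curve <- function(curve, detection = NULL, against = c("x", "t")) {
  against <- match.arg(against)
  if (is.null(detection)) detection <- detect_last_rupture(curve)
  df <- as_tibble(curve)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[against]], y = .data$f)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::labs(
      x = if (against == "x") "separation (nm)" else "time (s)",
      y = "force (pN)",
      title = curve_id(curve),
      subtitle = sprintf("v = %g nm/s", curve_velocity(curve))
    )
  if (isTRUE(detection$detected)) {
    p <- p + ggplot2::geom_vline(
      xintercept = df[[against]][detection$index],
      linetype = "dashed", colour = "firebrick"
    )
  }
  p
}

#' Histogram of apparent persistence lengths with the filter window
#'
#' Shows which events the persistence-length filter keeps (the block
#' between `threshold_fraction * l_p` and `max_fraction * l_p`).
#'
#' @param events Event tibble with an `l_app` column.
#' @param l_p Single-polymer persistence length, nm.
#' @param threshold_fraction,max_fraction Filter cuts (see
#'   [filter_events()]).
#' @param bins Histogram bin count.
#' @return A ggplot.
#' @export
plot_lapp_histogram <- function(events, l_p, threshold_fraction = 0.7,
                                max_fraction = 2.0, bins = 40) {
  df <- dplyr::filter(as_tibble(events), is.finite(.data$l_app))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$l_app)) +
    ggplot2::annotate("rect",
      xmin = threshold_fraction * l_p, xmax = max_fraction * l_p,
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "grey40"
    ) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = l_p, linetype = "dashed") +
    ggplot2::labs(x = "apparent persistence length (nm)", y = "events")
}

#' Plot a mean-force spectrum
#'
#' @param object A `dfs_spectrum` from [build_spectrum()].
#' @param ... Unused.
#' @return A ggplot of mean rupture force vs mean loading rate (log axis)
#'   with standard-error bars.
#' @method autoplot dfs_spectrum
#' @export
autoplot.dfs_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_r, y = .data$mean_f)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_f - .data$sem_f,
                   ymax = .data$mean_f + .data$sem_f),
      width = 0.05, na.rm = TRUE
    ) +
    ggplot2::geom_point(size = 2, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean loading rate (pN/s)", y = "mean rupture force (pN)")
}

#' Plot a single-bond fit over its spectrum
#'
#' @param object A `bond_fit` from [fit_single_bond_model()].
#' @param ... Unused.
#' @return A ggplot: spectrum points with the fitted mean-rupture-force
#'   curve.
#' @method autoplot bond_fit
#' @export
autoplot.bond_fit <- function(object, ...) {
  sp <- object$spectrum
  r_grid <- 10^seq(log10(min(sp$mean_r)) - 0.3, log10(max(sp$mean_r)) + 0.3,
                   length.out = 200)
  curve_df <- tibble(
    r = r_grid,
    f = mean_rupture_force(r_grid, object$params["f_eq"],
                           object$params["x_t"], object$params["k_off"],
                           object$temperature)
  )
  p <- ggplot2::ggplot(sp, ggplot2::aes(x = .data$mean_r, y = .data$mean_f)) +
    ggplot2::geom_line(data = curve_df,
                       ggplot2::aes(x = .data$r, y = .data$f),
                       colour = "steelblue", linewidth = 0.7)
  if ("sem_f" %in% names(sp)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_f - .data$sem_f,
                   ymax = .data$mean_f + .data$sem_f),
      width = 0.05, na.rm = TRUE
    )
  }
  p +
    ggplot2::geom_point(size = 2, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "mean loading rate (pN/s)", y = "mean rupture force (pN)",
      subtitle = sprintf(
        "f_eq = %.1f pN, x_t = %.3f nm, k_off = %.3g 1/s",
        object$params["f_eq"], object$params["x_t"], object$params["k_off"]
      )
    )
}
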