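#' Plot a fitted time-course or titration model over its data
#'
#' For burst / exponential fits: product vs time with the fitted curve.
#' For Morrison fits: bound complex vs enzyme on a log axis. For mixture
#' fits: the binned histogram with the fitted mixture density.
#'
#' @param object An `apekin_fit`.
#' @param n_curve Points used to draw the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.apekin_fit <- function(object, n_curve = 200, ...) {
  d <- tibble::as_tibble(object$data)
  xcol <- names(d)[1]
  ycol <- names(d)[2]
  xr <- range(d[[xcol]])
  log_x <- object$model == "morrison"
  xs <- if (log_x) {
    10^seq(log10(max(min(xr[xr > 0]), 1e-3)), log10(xr[2]),
           length.out = n_curve)
  } else {
    seq(xr[1], xr[2], length.out = n_curve)
  }
  curve <- tibble::tibble(x = xs, y = object$predict_fun(xs))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data[[xcol]], .data[[ycol]])) +
    (if (object$model == "gaussian_mixture") {
      ggplot2::geom_col(width = diff(xr) / nrow(d), fill = "grey80",
                        colour = "grey50")
    } else {
      ggplot2::geom_point(alpha = 0.7)
    }) +
    ggplot2::geom_line(data = curve, ggplot2::aes(.data$x, .data$y),
                       colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(
      x = xcol, y = ycol,
      title = sprintf("%s fit", object$model)
    ) +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a FRET exchange or competition titration
#'
#' @param curve A titration tibble with `x_ratio` and `efret` or `y_norm`.
#' @param ymax,ymin Optional anchor lines (high/low FRET states).
#' @return A ggplot object.
#' @export
plot_titration <- function(curve, ymax = NULL, ymin = NULL) {
  curve <- tibble::as_tibble(curve)
  ycol <- if ("y_norm" %in% names(curve)) "y_norm" else "efret"
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$x_ratio, .data[[ycol]])) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "titrant / DNA ratio", y = ycol) +
    ggplot2::theme_minimal()
  if (!is.null(ymax)) p <- p + ggplot2::geom_hline(yintercept = ymax,
                                                   linetype = 2)
  if (!is.null(ymin)) p <- p + ggplot2::geom_hline(yintercept = ymin,
                                                   linetype = 2)
  p
}

#' Plot a mass-photometry event histogram with optional mixture overlay
#'
#' @param events Events tibble (`mass_kDa` column).
#' @param fit Optional `apekin_fit` from [fit_gaussian_mixture()].
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_mass_histogram <- function(events, fit = NULL, bins = 60) {
  h <- bin_mass_events(events, bins = bins)
  p <- ggplot2::ggplot(h, ggplot2::aes(.data$x, .data$counts)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey50",
                      width = diff(range(h$x)) / nrow(h)) +
    ggplot2::labs(x = "mass (kDa)", y = "events") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(min(h$x), max(h$x), length.out = 300)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(x = xs, counts = fit$predict_fun(xs)),
      colour = "#b2182b", linewidth = 0.8
    )
  }
  p
}
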