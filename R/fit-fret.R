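#' Plateau E_FRET from a time trace
#'
#' Reproduces the plateau-averaging rule for ensemble FRET titrations: the
#' signal is recorded (every 0.17 s by default) until E_FRET holds a
#' constant value for at least one minute, and the points within that
#' stable region are averaged. Operationally, the earliest window of
#' `window` seconds that is both quiet (relative standard deviation
#' sd/mean at most `tol`) and trendless (fitted linear drift across the
#' window at most `tol` of the mean -- a slow monotone ramp is not a
#' plateau however small its scatter) defines the plateau.
#'
#' @param trace A data frame with column `t_s` (strictly increasing) and
#'   either an `efret` column or intensity columns `I563`/`I665` (from
#'   which E_FRET is computed).
#' @param window Plateau duration requirement, seconds (default 60).
#' @param tol Maximum relative standard deviation within the window
#'   (default 0.02).
#' @return A one-row tibble with `efret` (window mean), `sd`, `t_start`
#'   (window start time) and `n` (points averaged).
#' @export
plateau_efret <- function(trace, window = 60, tol = 0.02) {
  trace <- tibble::as_tibble(trace)
  if (!"t_s" %in% names(trace)) stop("trace needs column t_s", call. = FALSE)
  if (is.unsorted(trace$t_s, strictly = TRUE)) {
    stop("trace time stamps must be strictly increasing", call. = FALSE)
  }
  if (!"efret" %in% names(trace)) {
    if (!all(c("I563", "I665") %in% names(trace))) {
      stop("trace needs efret or I563/I665 columns", call. = FALSE)
    }
    trace$efret <- efret(trace$I563, trace$I665)
  }
  t <- trace$t_s
  if (max(t) - min(t) < window) {
    stop("trace shorter than the plateau window", call. = FALSE)
  }
  for (i in seq_along(t)) {
    if (t[i] + window > max(t)) break  # trace does not cover this window
    j <- which(t >= t[i] & t <= t[i] + window)
    y <- trace$efret[j]
    m <- mean(y)
    s <- stats::sd(y)
    if (m <= 0 || s / m > tol) next
    drift <- abs(stats::coef(stats::lm(y ~ t[j]))[[2]]) * window
    if (drift / m > tol) next
    return(tibble::tibble(efret = m, sd = s, t_start = t[i], n = length(j)))
  }
  stop("no plateau: no window of the required duration is stable",
       call. = FALSE)
}

#' Normalize a titration curve between its FRET anchors
#'
#' Maps observed signal onto `[0, 1]` using the high anchor `ymax` (the
#' E_FRET with no competitor/titrant, fully bound labeled complex) and the
#' low anchor `ymin` (the predicted no-interaction E_FRET from summed
#' component spectra): `y' = (y - ymin) / (ymax - ymin)`.
#'
#' @param curve A data frame with a signal column `y` (or `efret`).
#' @param ymax,ymin Anchor values, `ymax > ymin`.
#' @return The curve with a `y_norm` column appended.
#' @export
normalize_titration <- function(curve, ymax, ymin) {
  if (!(ymax > ymin)) stop("ymax must exceed ymin", call. = FALSE)
  curve <- tibble::as_tibble(curve)
  ycol <- if ("y" %in% names(curve)) "y" else "efret"
  if (!ycol %in% names(curve)) {
    stop("curve needs a y or efret column", call. = FALSE)
  }
  curve$y_norm <- (curve[[ycol]] - ymin) / (ymax - ymin)
  curve
}

#' Competitor ratio at 50% inhibition
#'
#' Locates where a normalized, monotone-decreasing competition curve
#' crosses 0.5 by linear interpolation between the bracketing points. For a
#' self-competition titration (competitor identical to the labeled
#' substrate, equal affinities) the expected crossing is at
#' `[Competitor]/[DNA]_Total = 0.50`; a lower crossing indicates the
#' competitor binds tighter.
#'
#' @param curve A data frame with columns `x_ratio` (strictly increasing,
#'   `[Competitor]/[DNA]_Total`) and `y_norm` (normalized signal).
#' @param tol Slack allowed in the monotonicity check (absolute, default
#'   1e-9; raise for noisy curves).
#' @return The interpolated `x_ratio` at `y_norm = 0.5`.
#' @export
inhibition_midpoint <- function(curve, tol = 1e-9) {
  curve <- tibble::as_tibble(curve)
  if (!all(c("x_ratio", "y_norm") %in% names(curve))) {
    stop("curve needs columns x_ratio and y_norm", call. = FALSE)
  }
  x <- curve$x_ratio
  y <- curve$y_norm
  if (is.unsorted(x, strictly = TRUE)) {
    stop("x_ratio must be strictly increasing", call. = FALSE)
  }
  up <- which(diff(y) > tol)
  if (length(up) > 0) {
    stop(sprintf("curve is not monotone decreasing (first violation at index %d)",
                 up[1] + 1L), call. = FALSE)
  }
  below <- which(y <= 0.5)
  if (length(below) == 0 || all(y > 0.5) || all(y < 0.5)) {
    stop("0.5 is not bracketed by the curve (partial or absent exchange)",
         call. = FALSE)
  }
  j <- below[1]
  if (y[j] == 0.5) return(x[j])
  if (j == 1) stop("0.5 is not bracketed by the curve", call. = FALSE)
  i <- j - 1L
  x[i] + (0.5 - y[i]) * (x[j] - x[i]) / (y[j] - y[i])
}
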