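#' Bin mass-photometry events into a histogram
#'
#' @param events A data frame with column `mass_kDa` (or `contrast`), one
#'   row per landing event.
#' @param bins Number of equal-width bins.
#' @return A tibble with bin midpoints `x` and event `counts`.
#' @export
bin_mass_events <- function(events, bins = 60) {
  events <- tibble::as_tibble(events)
  col <- if ("mass_kDa" %in% names(events)) "mass_kDa" else "contrast"
  if (!col %in% names(events)) {
    stop("events need a mass_kDa or contrast column", call. = FALSE)
  }
  v <- events[[col]]
  h <- graphics::hist(v, breaks = bins, plot = FALSE)
  tibble::tibble(x = h$mids, counts = h$counts)
}

#' Fit a Gaussian mixture to a mass-photometry histogram
#'
#' Nonlinear least squares fit of the mixture
#' \eqn{f(x) = \sum_n a_n \exp(-((x-b_n)/c_n)^2)} to binned landing-event
#' counts, to discern the underlying stoichiometry populations (e.g. one
#' vs two protein copies per DNA). Components are returned mean-ordered
#' ascending. Because the exponent carries no 1/2 factor, `c` is
#' \eqn{\sigma\sqrt 2} for a conventional Gaussian of standard deviation
#' \eqn{\sigma} and component areas are \eqn{a c \sqrt\pi}.
#'
#' Initialization is by local maxima of the lightly smoothed histogram
#' (falling back to count quantiles when fewer peaks than components are
#' visible), refined by Levenberg-Marquardt with jittered restarts.
#' Components whose means approach within half the larger width carry a
#' `"component-collapse"` warning: the data do not support that many
#' populations.
#'
#' @param data Either raw events (column `mass_kDa` or `contrast`) or an
#'   already binned histogram (columns `x`, `counts`).
#' @param n_components Number of Gaussian components (1-3).
#' @param bins Bins used when `data` is raw events. Must give at least
#'   `5 * 3 * n_components` bins.
#' @return An `apekin_fit` whose `params$components` is a tibble with
#'   columns `a`, `b`, `c` and `fraction` (area-based population fraction).
#' @export
fit_gaussian_mixture <- function(data, n_components, bins = 60) {
  stopifnot(n_components %in% 1:3)
  data <- tibble::as_tibble(data)
  hist_tbl <- if (all(c("x", "counts") %in% names(data))) {
    data
  } else {
    bin_mass_events(data, bins = bins)
  }
  if (nrow(hist_tbl) < 5 * 3 * n_components) {
    stop(sprintf("need at least %d bins for %d components",
                 5 * 3 * n_components, n_components), call. = FALSE)
  }
  x <- hist_tbl$x
  cnt <- hist_tbl$counts

  init <- init_mixture(x, cnt, n_components)
  fit <- nls_positive(
    x, cnt,
    fn = function(p, xx) {
      m <- matrix(p, nrow = 3)
      Reduce(`+`, lapply(
        seq_len(ncol(m)),
        function(i) m[1, i] * exp(-((xx - m[2, i]) / m[3, i])^2)
      ))
    },
    start = init
  )
  if (!fit$converged) {
    stop("fit_gaussian_mixture failed to converge after restarts",
         call. = FALSE)
  }
  m <- matrix(fit$par, nrow = 3)
  sem <- matrix(fit$se, nrow = 3)
  ord <- order(m[2, ])
  comps <- tibble::tibble(
    a = m[1, ord], b = m[2, ord], c = m[3, ord],
    a_se = sem[1, ord], b_se = sem[2, ord], c_se = sem[3, ord]
  )
  warnings <- character()
  comps$fraction <- population_fractions(comps)
  if (nrow(comps) > 1) {
    for (i in seq_len(nrow(comps) - 1)) {
      gap <- comps$b[i + 1] - comps$b[i]
      if (gap < max(comps$c[i], comps$c[i + 1]) / 2) {
        warnings <- c(warnings, sprintf(
          "component-collapse: means %d and %d within half a width (gap %.3g)",
          i, i + 1, gap
        ))
      }
    }
    if (any(comps$fraction < 0.02)) {
      warnings <- c(warnings,
        "component-collapse: a component carries < 2% of the area; the data do not support this many populations")
    }
  }
  new_apekin_fit(
    model = "gaussian_mixture",
    params = list(components = comps),
    se = c(resid = NA_real_),
    residual_ss = fit$deviance,
    converged = TRUE,
    warnings = warnings,
    data = hist_tbl,
    predict_fun = function(x) eval_gaussian_mixture(x, comps)
  )
}

#' @export
tidy.apekin_gaussian_mixture_fit <- function(x, ...) {
  comps <- x$params$components
  tibble::tibble(
    component = seq_len(nrow(comps)),
    a = comps$a, b = comps$b, c = comps$c,
    fraction = comps$fraction,
    b_se = comps$b_se
  )
}

init_mixture <- function(x, cnt, n) {
  sm <- stats::filter(cnt, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- cnt[is.na(sm)]
  sm <- as.numeric(sm)
  peaks <- which(diff(sign(diff(sm))) == -2) + 1L
  peaks <- peaks[order(sm[peaks], decreasing = TRUE)]
  span <- diff(range(x))
  c0 <- span / (4 * n)
  if (length(peaks) >= n) {
    b0 <- sort(x[peaks[seq_len(n)]])
  } else {
    qs <- (seq_len(n) - 0.5) / n
    cum <- cumsum(cnt) / sum(cnt)
    b0 <- vapply(qs, function(q) x[which(cum >= q)[1]], numeric(1))
    b0 <- sort(b0)
    if (any(duplicated(b0))) b0 <- b0 + seq_len(n) * c0 / 2
  }
  a0 <- vapply(b0, function(b) max(cnt[which.min(abs(x - b))], 1), numeric(1))
  out <- as.numeric(rbind(a0, b0, rep(c0, n)))
  names(out) <- as.vector(t(outer(seq_len(n), c("a", "b", "c"),
                                  function(i, s) paste0(s, i))))
  out
}

#' Area-based population fractions of mixture components
#'
#' Under the no-1/2-exponent parameterization the area of component *i* is
#' \eqn{a_i c_i \sqrt\pi}, so the population fraction is
#' \eqn{a_i c_i / \sum_j a_j c_j}. Fractions sum to 1 exactly.
#'
#' @param components A data frame with columns `a` and `c` (one row per
#'   component), e.g. from [fit_gaussian_mixture()].
#' @return Numeric vector of fractions, one per component.
#' @export
population_fractions <- function(components) {
  components <- tibble::as_tibble(components)
  if (!all(c("a", "c") %in% names(components))) {
    stop("components must have columns a and c", call. = FALSE)
  }
  areas <- components$a * components$c
  if (all(areas == 0)) stop("all component areas are zero", call. = FALSE)
  areas / sum(areas)
}

#' Calibrate raw contrast to mass with a known standard
#'
#' Mass photometry measures interferometric contrast; a protein standard
#' with peaks of known mass (e.g. the oligomer series of beta-amylase) is
#' used to fit an affine contrast-to-mass map by least squares through the
#' standard's fitted peak centers.
#'
#' @param standard_events A data frame with column `contrast`, landing
#'   events of the mass standard.
#' @param standard_masses Known masses of the standard's peaks, kDa,
#'   ascending; at least 2.
#' @param bins Histogram bins for the peak fit.
#' @return A list with `slope`, `intercept`, the mapping function
#'   `to_mass(contrast)`, and `peak_contrasts` (fitted centers).
#' @export
calibrate_contrast <- function(standard_events, standard_masses, bins = 60) {
  if (length(standard_masses) < 2) {
    stop("need at least 2 standard peaks to calibrate", call. = FALSE)
  }
  standard_masses <- sort(standard_masses)
  fit <- fit_gaussian_mixture(standard_events,
                              n_components = length(standard_masses),
                              bins = bins)
  centers <- fit$params$components$b
  cal <- stats::lm(standard_masses ~ centers)
  slope <- unname(stats::coef(cal)[2])
  intercept <- unname(stats::coef(cal)[1])
  list(
    slope = slope,
    intercept = intercept,
    to_mass = function(contrast) intercept + slope * contrast,
    peak_contrasts = centers
  )
}
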