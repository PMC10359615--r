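#' Fit the burst model to a multiple-turnover time course
#'
#' Least-squares fit of \eqn{P(t) = A(1 - e^{-k_{obs} t}) + v_{ss} t} to a
#' product-formation time course recorded with substrate in excess of
#' enzyme. The steady-state rate constant `kss = vss / A` is derived from
#' the fit. Replicates (a `replicate` column) are pooled as repeated
#' measurements.
#'
#' When the two phases are kinetically close (`kobs / kss < 10`) they are
#' not easily differentiated during fitting and `kobs` is poorly
#' determined; the fit then carries a `"low-separation"` warning and a
#' single-turnover experiment is the appropriate confirmation.
#'
#' @param data A data frame with columns `time_s` and `product_nM`
#'   (optionally `replicate`), at least 6 distinct time points.
#' @return An `apekin_fit` with parameters `A` (nM), `kobs` (s^-1),
#'   `vss` (nM/s) and derived `kss` (s^-1). Use [tidy()] / [glance()] to
#'   extract estimates and fit diagnostics.
#' @examples
#' tc <- gen_timecourse(
#'   truth = list(A = 30, kobs = 10, vss = 81),
#'   design = design_multiple_turnover(),
#'   noise = noise_model(cv = 0, floor = 0, seed = 1)
#' )
#' tidy(fit_burst(tc))
#' @export
fit_burst <- function(data) {
  data <- check_timecourse(data, "multiple_turnover")
  t <- data$time_s
  y <- data$product_nM

  init <- init_burst(t, y)
  fit <- nls_positive(
    t, y,
    fn = function(p, x) p[1] * (1 - exp(-p[2] * x)) + p[3] * x,
    start = c(A = init$A, kobs = init$kobs, vss = init$vss)
  )
  if (!fit$converged) {
    stop("fit_burst failed to converge after restarts", call. = FALSE)
  }
  p <- as.list(fit$par)
  kss <- steady_state_rate(p$vss, p$A)
  kss_se <- kss * sqrt(
    (fit$se[["vss"]] / p$vss)^2 + (fit$se[["A"]] / p$A)^2
  )
  warnings <- character()
  if (p$kobs / kss < 10) {
    warnings <- c(warnings, sprintf(
      "low-separation: kobs/kss = %.2f < 10; kobs is poorly determined",
      p$kobs / kss
    ))
  }
  new_apekin_fit(
    model = "burst",
    params = list(A = p$A, kobs = p$kobs, vss = p$vss, kss = kss),
    se = c(fit$se, kss = unname(kss_se)),
    residual_ss = fit$deviance,
    converged = TRUE,
    warnings = warnings,
    data = data[, c("time_s", "product_nM")],
    predict_fun = function(t) eval_burst(t, p$A, p$kobs, p$vss)
  )
}

init_burst <- function(t, y) {
  ord <- order(t)
  t <- t[ord]
  y <- y[ord]
  tail_idx <- t >= stats::quantile(unique(t), 2 / 3)
  if (sum(tail_idx) >= 2 && stats::sd(t[tail_idx]) > 0) {
    tail_fit <- stats::lm(y[tail_idx] ~ t[tail_idx])
    vss <- max(unname(stats::coef(tail_fit)[2]), 1e-9)
    A <- max(unname(stats::coef(tail_fit)[1]), 1e-9)
  } else {
    vss <- max((max(y) - min(y)) / max(max(t), 1e-9) / 2, 1e-9)
    A <- max(max(y) / 2, 1e-9)
  }
  # log-linear estimate of the exponential rate from the burst-corrected rise
  yc <- 1 - (y - vss * t) / A
  keep <- yc > 0.05 & yc < 0.95 & t > 0
  kobs <- if (sum(keep) >= 2) {
    max(-stats::coef(stats::lm(log(yc[keep]) ~ 0 + t[keep]))[[1]], 1e-6)
  } else {
    log(2) / max(t[which(y >= A / 2)[1]], min(t[t > 0]))
  }
  list(A = A, kobs = kobs, vss = vss)
}

#' Fit a single exponential to a single-turnover time course
#'
#' Least-squares fit of \eqn{P(t) = A(1 - e^{-k_{obs} t})} to a time course
#' recorded with enzyme in excess of substrate, where product formation is
#' exponential with the chemistry-limited rate.
#'
#' Residual signs are checked with a one-sided Wald-Wolfowitz runs test; a
#' p-value below 0.01 (systematically structured residuals, e.g. data that
#' actually follow a double exponential) attaches a `"residual-structure"`
#' warning.
#'
#' @inheritParams fit_burst
#' @return An `apekin_fit` with parameters `A` (nM) and `kobs` (s^-1).
#' @export
fit_single_exp <- function(data) {
  data <- check_timecourse(data, "single_turnover")
  t <- data$time_s
  y <- data$product_nM

  A0 <- max(stats::quantile(y, 0.95), 1e-9)
  yc <- 1 - pmin(y / A0, 0.99)
  keep <- yc > 0.05 & t > 0
  k0 <- if (sum(keep) >= 2) {
    max(-stats::coef(stats::lm(log(yc[keep]) ~ 0 + t[keep]))[[1]], 1e-6)
  } else {
    1 / max(mean(t), 1e-9)
  }
  fit <- nls_positive(
    t, y,
    fn = function(p, x) p[1] * (1 - exp(-p[2] * x)),
    start = c(A = A0, kobs = k0)
  )
  if (!fit$converged) {
    stop("fit_single_exp failed to converge after restarts", call. = FALSE)
  }
  p <- as.list(fit$par)
  resid <- y - eval_single_exp(t, p$A, p$kobs)
  warnings <- character()
  if (runs_test_pvalue(resid[order(t)]) < 0.01) {
    warnings <- c(
      warnings,
      "residual-structure: runs test p < 0.01; consider a double exponential"
    )
  }
  new_apekin_fit(
    model = "single_exp",
    params = p,
    se = fit$se,
    residual_ss = fit$deviance,
    converged = TRUE,
    warnings = warnings,
    data = data[, c("time_s", "product_nM")],
    predict_fun = function(t) eval_single_exp(t, p$A, p$kobs)
  )
}

#' Fit a double exponential to a single-turnover time course
#'
#' Least-squares fit of \eqn{P(t) = A(1-e^{-k_1 t}) + B(1-e^{-k_2 t})},
#' used when two distinct cleavage populations are present. Components are
#' stored amplitude-descending (`A >= B`) and `major_rate = k1`, the rate
#' of the larger-amplitude (major) population.
#'
#' If the two rates collapse (relative difference below 5%) or one
#' amplitude vanishes, the biexponential is unidentifiable: a
#' `"degenerate-biexponential"` warning is attached and the returned object
#' is the single-exponential refit.
#'
#' @inheritParams fit_burst
#' @return An `apekin_fit` with parameters `A`, `k1`, `B`, `k2` and derived
#'   `major_rate`; or a single-exponential fit carrying the degeneracy
#'   warning.
#' @export
fit_double_exp <- function(data) {
  data <- check_timecourse(data, "single_turnover")
  t <- data$time_s
  y <- data$product_nM

  single <- fit_single_exp(data)
  k_mid <- single$params$kobs
  amp <- max(single$params$A, 1e-9)
  fit <- nls_positive(
    t, y,
    fn = function(p, x) {
      p[1] * (1 - exp(-p[2] * x)) + p[3] * (1 - exp(-p[4] * x))
    },
    start = c(A = amp / 2, k1 = k_mid / 8, B = amp / 2, k2 = k_mid * 8)
  )
  degenerate_to_single <- function(reason) {
    single$warnings <- c(
      single$warnings,
      paste0("degenerate-biexponential: ", reason, "; refit as single exponential")
    )
    single
  }
  if (!fit$converged) {
    return(degenerate_to_single("biexponential fit did not converge"))
  }
  p <- fit$par
  se <- fit$se
  # amplitude-descending order: component 1 is the major population
  if (p[["B"]] > p[["A"]]) {
    p <- p[c("B", "k2", "A", "k1")]
    se <- se[c("B", "k2", "A", "k1")]
    names(p) <- names(se) <- c("A", "k1", "B", "k2")
  }
  if (abs(p[["k1"]] - p[["k2"]]) / max(p[["k1"]], p[["k2"]]) < 0.05) {
    return(degenerate_to_single("rates collapsed (|k1-k2|/k1 < 0.05)"))
  }
  if (p[["B"]] < 0.01 * (p[["A"]] + p[["B"]])) {
    return(degenerate_to_single("minor amplitude vanished"))
  }
  pl <- as.list(p)
  new_apekin_fit(
    model = "double_exp",
    params = c(pl, list(major_rate = pl$k1)),
    se = c(se, major_rate = unname(se[["k1"]])),
    residual_ss = fit$deviance,
    converged = TRUE,
    data = data[, c("time_s", "product_nM")],
    predict_fun = function(t) eval_double_exp(t, pl$A, pl$k1, pl$B, pl$k2)
  )
}
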