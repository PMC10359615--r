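#' Bound complex from EMSA band intensities
#'
#' Converts quantified free-DNA and total-lane band intensities into the
#' bound-complex concentration at known total DNA:
#' `AB = BT * (1 - free / total)`.
#'
#' @param free_intensity Free-DNA band intensity (>= 0). Vectorized.
#' @param total_intensity Total lane intensity (> 0, >= free).
#' @param BT Total DNA concentration, nM.
#' @return Bound complex `AB` in nM.
#' @export
emsa_fraction_bound <- function(free_intensity, total_intensity, BT = 5) {
  check_nonneg(free_intensity, "free_intensity")
  check_pos(total_intensity, "total_intensity")
  check_pos(BT, "BT")
  if (any(free_intensity > total_intensity)) {
    stop("free band intensity exceeds total", call. = FALSE)
  }
  BT * (1 - free_intensity / total_intensity)
}

#' Fit the Morrison tight-binding quadratic to an EMSA titration
#'
#' Least-squares estimate of the apparent dissociation constant `KD_app`
#' from bound-complex concentrations measured over an enzyme titration at
#' fixed total DNA `BT`, using [morrison_bound()]. The tight-binding
#' quadratic is required because the DNA concentration (typically 5 nM) is
#' comparable to the affinities involved, so free enzyme cannot be equated
#' with total enzyme.
#'
#' Identifiability guards:
#' * if every non-zero titration point is more than 95% bound the curve
#'   carries no affinity information and the fit aborts with guidance to
#'   extend the titration to sub-saturating enzyme;
#' * a `"tight-binding"` warning is attached when the estimated `KD_app`
#'   falls below `BT` (the binding curve degenerates towards a
#'   stoichiometric step, so `KD_app` is weakly constrained there) or when
#'   it is resolved worse than 25% relative standard error.
#'
#' @param data A data frame with columns `enzyme_nM` (total enzyme `AT`)
#'   and either `bound_nM` or `fraction_bound` (of `BT`); optionally
#'   `replicate`.
#' @param BT Total DNA concentration, nM (fixed, default 5).
#' @return An `apekin_fit` with parameter `KD_app` (nM) and fields
#'   `BT`; `augment()` returns the data with fitted bound values.
#' @export
fit_morrison <- function(data, BT = 5) {
  data <- tibble::as_tibble(data)
  if (!"enzyme_nM" %in% names(data)) {
    stop("titration needs column enzyme_nM", call. = FALSE)
  }
  if (!"bound_nM" %in% names(data)) {
    if ("fraction_bound" %in% names(data)) {
      data$bound_nM <- data$fraction_bound * BT
    } else {
      stop("titration needs bound_nM or fraction_bound", call. = FALSE)
    }
  }
  check_nonneg(data$enzyme_nM, "enzyme_nM")
  at <- data$enzyme_nM
  ab <- data$bound_nM

  nz <- at > 0
  if (sum(nz) < 3) stop("too few titration points", call. = FALSE)
  if (all(ab[nz] / BT > 0.95)) {
    stop(
      paste(
        "titration is saturated (all points > 95% bound): KD_app is",
        "unidentifiable; extend the titration to sub-saturating enzyme"
      ),
      call. = FALSE
    )
  }

  # initialize at the enzyme concentration of half-maximal binding
  half <- max(ab) / 2
  kd0 <- max(stats::approx(ab[nz], at[nz], xout = half, ties = mean)$y,
             1e-3, na.rm = TRUE)
  fit <- nls_positive(
    at, ab,
    fn = function(p, x) morrison_bound(x, BT, p[1]),
    start = c(KD_app = kd0)
  )
  if (!fit$converged) {
    stop("fit_morrison failed to converge after restarts", call. = FALSE)
  }
  kd <- fit$par[["KD_app"]]
  se <- fit$se[["KD_app"]]
  warnings <- character()
  if (!is.finite(se) || se / kd > 0.25 || kd < BT) {
    warnings <- c(warnings, sprintf(
      "tight-binding: KD_app (%.3g nM) is below BT (%g nM) or resolved to %.0f%% relative SE; the titration is near-stoichiometric and KD_app is weakly constrained",
      kd, BT, 100 * se / kd
    ))
  }
  new_apekin_fit(
    model = "morrison",
    params = list(KD_app = kd),
    se = c(KD_app = se),
    residual_ss = fit$deviance,
    converged = TRUE,
    warnings = warnings,
    data = tibble::tibble(enzyme_nM = at, bound_nM = ab),
    predict_fun = function(at) morrison_bound(at, BT, kd),
    extra = list(BT = BT)
  )
}
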