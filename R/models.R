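#' Burst (biphasic multiple-turnover) product formation
#'
#' Evaluates the pre-steady-state burst model
#' \deqn{P(t) = A\,(1 - e^{-k_{obs} t}) + v_{ss}\, t}
#' where `A` is the burst amplitude (the concentration of actively engaged
#' enzyme, nM), `kobs` the first-order rate constant of the exponential
#' phase (s^-1, interpreted as the cleavage rate) and `vss` the steady-state
#' velocity (nM/s, interpreted as product release).
#'
#' @param t Time, seconds. Vectorized; all values must be >= 0.
#' @param A Burst amplitude, nM (>= 0).
#' @param kobs Exponential-phase rate constant, s^-1 (> 0).
#' @param vss Steady-state velocity, nM/s (>= 0).
#' @return Product concentration in nM, same length as `t`. Monotone
#'   non-decreasing in `t`.
#' @examples
#' eval_burst(0.1, A = 30, kobs = 10, vss = 81)
#' @seealso [eval_single_exp()], [steady_state_rate()], [fit_burst()]
#' @export
eval_burst <- function(t, A, kobs, vss) {
  check_nonneg(t, "t")
  check_nonneg(A, "A")
  check_pos(kobs, "kobs")
  check_nonneg(vss, "vss")
  A * (1 - exp(-kobs * t)) + vss * t
}

#' Single-exponential product formation
#'
#' Evaluates \eqn{P(t) = A (1 - e^{-k_{obs} t})}, the single-turnover model
#' for an enzyme-excess regime: exponential approach to the amplitude `A`
#' with half-rise at `log(2)/kobs`.
#'
#' @inheritParams eval_burst
#' @return Product concentration in nM.
#' @export
eval_single_exp <- function(t, A, kobs) {
  check_nonneg(t, "t")
  check_nonneg(A, "A")
  check_pos(kobs, "kobs")
  A * (1 - exp(-kobs * t))
}

#' Double-exponential product formation
#'
#' Evaluates \eqn{P(t) = A (1 - e^{-k_1 t}) + B (1 - e^{-k_2 t})}, the
#' two-population single-turnover model used when a mutant enzyme displays
#' two distinct cleavage rates. Asymptote is `A + B`.
#'
#' @inheritParams eval_burst
#' @param A,B Amplitudes of the two populations, nM (>= 0).
#' @param k1,k2 Rate constants of the two populations, s^-1 (> 0).
#' @return Product concentration in nM.
#' @export
eval_double_exp <- function(t, A, k1, B, k2) {
  check_nonneg(t, "t")
  check_nonneg(A, "A")
  check_nonneg(B, "B")
  check_pos(k1, "k1")
  check_pos(k2, "k2")
  A * (1 - exp(-k1 * t)) + B * (1 - exp(-k2 * t))
}

#' Steady-state rate constant from velocity and burst amplitude
#'
#' The steady-state rate constant is the steady-state velocity divided by
#' the burst amplitude, `kss = vss / A` (s^-1). It is interpreted as the
#' rate of product release.
#'
#' @param vss Steady-state velocity, nM/s (>= 0).
#' @param A Burst amplitude, nM (> 0).
#' @return `kss` in s^-1.
#' @export
steady_state_rate <- function(vss, A) {
  check_nonneg(vss, "vss")
  if (any(A <= 0)) {
    stop("steady_state_rate() is undefined for A <= 0", call. = FALSE)
  }
  vss / A
}

#' Fold change between two rates
#'
#' Fold change as reported in kinetics tables: the ratio of the larger rate
#' to the smaller, always >= 1, together with the direction of change of
#' `val` relative to `ref`.
#'
#' @param ref Reference rate, s^-1 (> 0).
#' @param val Rate to compare, s^-1 (> 0).
#' @return A tibble with columns `fold` (>= 1) and `direction`
#'   (`"increase"`, `"decrease"` or `"none"`).
#' @examples
#' fold_change(129, 10) # 12.9-fold decrease
#' @export
fold_change <- function(ref, val) {
  check_pos(ref, "ref")
  check_pos(val, "val")
  fold <- pmax(ref, val) / pmin(ref, val)
  direction <- dplyr::case_when(
    val < ref ~ "decrease",
    val > ref ~ "increase",
    .default = "none"
  )
  tibble::tibble(fold = fold, direction = direction)
}

#' Morrison tight-binding bound-complex concentration
#'
#' Concentration of enzyme:DNA complex at total enzyme `AT`, total DNA `BT`
#' and apparent dissociation constant `KD`, from the tight-binding quadratic
#' \deqn{AB = \frac{(A_T + B_T + K_D) - \sqrt{(A_T + B_T + K_D)^2 - 4 A_T B_T}}{2}.}
#' Used when the ligand concentration is comparable to `KD`, so free and
#' total enzyme cannot be equated. Internally the algebraically equivalent
#' form \eqn{2 A_T B_T / ((A_T+B_T+K_D) + \sqrt{(A_T+B_T+K_D)^2 - 4 A_T B_T})}
#' is evaluated, which is numerically stable as `KD -> 0` (no catastrophic
#' cancellation).
#'
#' @param AT Total enzyme, nM (>= 0). Vectorized.
#' @param BT Total DNA, nM (>= 0).
#' @param KD Apparent dissociation constant, nM (>= 0).
#' @return Complex concentration `AB` in nM, in `[0, min(AT, BT)]`.
#' @examples
#' morrison_bound(2000, 5, 22)
#' @export
morrison_bound <- function(AT, BT, KD) {
  check_nonneg(AT, "AT")
  check_nonneg(BT, "BT")
  check_nonneg(KD, "KD")
  s <- AT + BT + KD
  disc <- sqrt(pmax(s^2 - 4 * AT * BT, 0))
  denom <- s + disc
  ab <- ifelse(denom > 0, 2 * AT * BT / denom, 0)
  pmin(ab, pmin(AT, BT))
}

#' FRET proximity ratio
#'
#' The FRET efficiency proxy \eqn{E_{FRET} = I_{665} / (I_{665} + I_{563})}
#' from simultaneously recorded acceptor (665 nm, Cy5) and donor (563 nm,
#' Cy3) emission intensities.
#'
#' @param I563 Donor-channel intensity, arbitrary units (>= 0). Vectorized.
#' @param I665 Acceptor-channel intensity, arbitrary units (>= 0).
#' @return `E_FRET` in `[0, 1]`.
#' @export
efret <- function(I563, I665) {
  check_nonneg(I563, "I563")
  check_nonneg(I665, "I665")
  if (any(I563 + I665 <= 0)) {
    stop("E_FRET undefined: both channels zero", call. = FALSE)
  }
  I665 / (I665 + I563)
}

#' Predicted no-interaction FRET from component spectra
#'
#' The E_FRET expected if the labeled protein never engages the labeled DNA,
#' computed by summing the separately recorded emission intensities of the
#' two components channel-wise and taking the proximity ratio:
#' \deqn{E_{FRET} = (I_{665}^{RPA} + I_{665}^{DNA}) /
#'   ((I_{665}^{RPA} + I_{665}^{DNA}) + (I_{563}^{RPA} + I_{563}^{DNA})).}
#' This anchors the low-FRET endpoint (Y-Min) of exchange titrations.
#'
#' @param rpa_I563,rpa_I665 Donor/acceptor intensities of the protein alone.
#' @param dna_I563,dna_I665 Donor/acceptor intensities of the DNA alone.
#' @return Predicted `E_FRET` in `[0, 1]`.
#' @export
predicted_no_interaction_efret <- function(rpa_I563, rpa_I665,
                                           dna_I563, dna_I665) {
  efret(rpa_I563 + dna_I563, rpa_I665 + dna_I665)
}

#' Gaussian-mixture mass distribution
#'
#' Evaluates the mixture \eqn{f(x) = \sum_n a_n \exp(-((x - b_n)/c_n)^2)}
#' used to decompose mass-photometry histograms. Note there is no 1/2
#' factor in the exponent: the width parameter `c` relates to a conventional
#' Gaussian standard deviation by \eqn{c = \sigma \sqrt{2}}, and the area of
#' a component is \eqn{a\, c\, \sqrt{\pi}}.
#'
#' @param x Mass (kDa) or raw contrast; vectorized.
#' @param components A data frame with one row per component and columns
#'   `a` (amplitude, counts, >= 0), `b` (mean) and `c` (width, > 0).
#' @return Expected counts at `x`.
#' @examples
#' eval_gaussian_mixture(150, tibble::tibble(a = 100, b = 130, c = 20))
#' @export
eval_gaussian_mixture <- function(x, components) {
  components <- validate_components(components)
  Reduce(`+`, lapply(seq_len(nrow(components)), function(i) {
    components$a[i] * exp(-((x - components$b[i]) / components$c[i])^2)
  }))
}

validate_components <- function(components) {
  components <- tibble::as_tibble(components)
  if (nrow(components) == 0) {
    stop("mixture needs at least one component", call. = FALSE)
  }
  if (!all(c("a", "b", "c") %in% names(components))) {
    stop("components must have columns a, b, c", call. = FALSE)
  }
  if (any(components$a < 0) || any(components$c <= 0)) {
    stop("invalid component: need a >= 0 and c > 0", call. = FALSE)
  }
  components
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  }
  invisible(x)
}

check_pos <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and positive", name), call. = FALSE)
  }
  invisible(x)
}
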