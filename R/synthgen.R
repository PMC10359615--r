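#' Noise model for synthetic assay data
#'
#' Proportional Gaussian noise with an additive floor: an observation with
#' true value `y` is perturbed by a zero-mean Gaussian with standard
#' deviation `sqrt((cv * y)^2 + floor^2)`. The 3% coefficient of variation
#' default matches the replicate scatter typical of quantified gel bands;
#' the floor represents detection-limit noise (0.5 nM for product
#' concentrations; use ~0.005 for E_FRET signals).
#'
#' @param cv Proportional coefficient of variation (>= 0, default 0.03).
#' @param floor Additive standard deviation in signal units (default 0.5).
#' @param seed Integer RNG seed; required, so every generated data set is
#'   reproducible.
#' @return A `noise_model` list.
#' @export
noise_model <- function(cv = 0.03, floor = 0.5, seed) {
  if (missing(seed)) stop("noise_model() requires a seed", call. = FALSE)
  check_nonneg(cv, "cv")
  check_nonneg(floor, "floor")
  structure(list(cv = cv, floor = floor, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(y, noise, clamp_min = 0, clamp_max = Inf) {
  if (is.null(noise)) return(y)
  sdv <- sqrt((noise$cv * y)^2 + noise$floor^2)
  pmin(pmax(y + stats::rnorm(length(y), 0, sdv), clamp_min), clamp_max)
}

#' Multiple-turnover experiment design
#'
#' Default design of the rapid-quench multiple-turnover assay: DNA (100 nM)
#' in excess of enzyme (30 nM), time grid log-spaced from the 0.002 s
#' instrument minimum, three replicates.
#'
#' @param E0 Enzyme concentration, nM.
#' @param S0 Substrate (DNA) concentration, nM.
#' @param t_grid Sampling times, seconds.
#' @param n_reps Replicates.
#' @return A design list (regime `"multiple_turnover"`).
#' @export
design_multiple_turnover <- function(E0 = 30, S0 = 100,
                                     t_grid = c(10^seq(log10(0.002),
                                                       log10(0.3),
                                                       length.out = 18),
                                                seq(0.4, 0.8, by = 0.1)),
                                     n_reps = 3) {
  list(regime = "multiple_turnover", E0 = E0, S0 = S0,
       t_grid = sort(t_grid), n_reps = n_reps)
}

#' Single-turnover experiment design
#'
#' Enzyme (500 nM) in excess of DNA (50 nM); product formation is a single
#' (or double) exponential read on a rapid-quench grid from 0.002 s.
#'
#' @inheritParams design_multiple_turnover
#' @return A design list (regime `"single_turnover"`).
#' @export
design_single_turnover <- function(E0 = 500, S0 = 50,
                                   t_grid = 10^seq(log10(0.002),
                                                   log10(1.5),
                                                   length.out = 20),
                                   n_reps = 3) {
  list(regime = "single_turnover", E0 = E0, S0 = S0,
       t_grid = sort(t_grid), n_reps = n_reps)
}

#' EMSA titration design
#'
#' DNA fixed at 5 nM, enzyme titrated 0-2000 nM as a serial two-fold
#' dilution series (the standard way an EMSA titration is pipetted) plus
#' the zero lane, three replicates.
#'
#' @param BT Total DNA, nM.
#' @param AT_grid Total enzyme concentrations, nM.
#' @param n_reps Replicates.
#' @return A design list.
#' @export
design_emsa <- function(BT = 5,
                        AT_grid = c(0, 2000 / 2^(10:0)),
                        n_reps = 3) {
  list(BT = BT, AT_grid = sort(AT_grid), n_reps = n_reps)
}

#' Generate a synthetic product-formation time course
#'
#' Evaluates the closed-form kinetic model named by `truth` on the design's
#' time grid (or integrates a [mechanism_scheme()] when one is supplied)
#' and adds seeded replicate noise. The truth is recorded in the `truth`
#' attribute so recovery tests can compare blind fits against it.
#'
#' `truth` is a named list selecting the model:
#' * `A`, `kobs`, `vss` -- burst (multiple turnover);
#' * `A`, `kobs` -- single exponential (single turnover);
#' * `A`, `k1`, `B`, `k2` -- double exponential;
#' * a `mechanism_scheme` -- mass-action ODE of the turnover scheme.
#'
#' @param truth Named list of true parameters (see Details) or a
#'   [mechanism_scheme()].
#' @param design A design list from [design_multiple_turnover()] or
#'   [design_single_turnover()].
#' @param noise A [noise_model()] (its seed drives all randomness), or
#'   `NULL` for noiseless output.
#' @param n_reps Replicates; defaults to the design's.
#' @return A tibble `(time_s, replicate, product_nM)` with attributes
#'   `truth` and `design`.
#' @export
gen_timecourse <- function(truth, design, noise = NULL,
                           n_reps = design$n_reps) {
  t <- design$t_grid
  clean <- if (inherits(truth, "mechanism_scheme")) {
    # the assay observable is total cleaved DNA (enzyme-bound + released)
    simulate_turnover_ode(truth, design$E0, design$S0, t)$cleaved_nM
  } else if (all(c("A", "k1", "B", "k2") %in% names(truth))) {
    if (design$regime != "single_turnover") {
      stop("double-exponential truth requires a single-turnover design",
           call. = FALSE)
    }
    eval_double_exp(t, truth$A, truth$k1, truth$B, truth$k2)
  } else if (all(c("A", "kobs", "vss") %in% names(truth))) {
    if (design$regime != "multiple_turnover") {
      stop("burst truth requires a multiple-turnover design", call. = FALSE)
    }
    eval_burst(t, truth$A, truth$kobs, truth$vss)
  } else if (all(c("A", "kobs") %in% names(truth))) {
    if (design$regime != "single_turnover") {
      stop("single-exponential truth requires a single-turnover design",
           call. = FALSE)
    }
    eval_single_exp(t, truth$A, truth$kobs)
  } else {
    stop("unrecognized truth parameterization", call. = FALSE)
  }
  gen <- function() {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      tibble::tibble(
        time_s = t,
        replicate = r,
        product_nM = apply_noise(clean, noise)
      )
    })
  }
  out <- if (is.null(noise)) gen() else withr::with_seed(noise$seed, gen())
  attr(out, "truth") <- if (inherits(truth, "mechanism_scheme")) {
    unclass(truth)
  } else {
    truth
  }
  attr(out, "design") <- design
  out
}

#' Generate a synthetic EMSA titration
#'
#' Bound-complex concentrations from the tight-binding quadratic at each
#' enzyme concentration of the design, with seeded noise applied to the
#' bound fraction (emulating band-quantification error).
#'
#' @param KD True apparent dissociation constant, nM (>= 0).
#' @param design A design from [design_emsa()].
#' @param noise A [noise_model()] (floor interpreted on the 0-1 bound
#'   fraction scale; use ~0.01), or `NULL`.
#' @param n_reps Replicates; defaults to the design's.
#' @return A tibble `(enzyme_nM, replicate, fraction_bound, bound_nM)` with
#'   `truth` and `design` attributes.
#' @export
gen_emsa_titration <- function(KD, design = design_emsa(), noise = NULL,
                               n_reps = design$n_reps) {
  check_nonneg(KD, "KD")
  frac <- morrison_bound(design$AT_grid, design$BT, KD) / design$BT
  gen <- function() {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      fb <- apply_noise(frac, noise, clamp_min = 0, clamp_max = 1)
      tibble::tibble(
        enzyme_nM = design$AT_grid,
        replicate = r,
        fraction_bound = fb,
        bound_nM = fb * design$BT
      )
    })
  }
  out <- if (is.null(noise)) gen() else withr::with_seed(noise$seed, gen())
  attr(out, "truth") <- list(KD = KD, BT = design$BT)
  attr(out, "design") <- design
  out
}

#' Generate a FRET exchange titration
#'
#' Emulates titrating a pre-formed labeled-protein:labeled-DNA complex with
#' an unlabeled competitor protein. In `full_exchange` mode the E_FRET
#' signal decays (saturating exponential in the titrant ratio, decay scale
#' `x50`) from the high anchor `ymax` (complex intact) to the low anchor
#' `ymin` (the predicted no-interaction value); in `no_exchange` mode it
#' stays at `ymax`, the behavior of a substrate whose bound protein is not
#' displaced.
#'
#' @param ymax High-FRET anchor (no titrant). Default 0.475.
#' @param ymin Low-FRET anchor (protein fully disengaged). Default 0.204.
#' @param mode `"full_exchange"` or `"no_exchange"`.
#' @param x_grid Titrant-to-DNA ratios (non-negative, increasing).
#' @param noise A [noise_model()] on the E_FRET scale (use floor ~0.005),
#'   or `NULL`.
#' @param x50 Decay scale of the exchange in ratio units.
#' @return A tibble `(x_ratio, efret)` with a `truth` attribute.
#' @export
gen_fret_exchange_titration <- function(ymax = 0.475, ymin = 0.204,
                                        mode = c("full_exchange",
                                                 "no_exchange"),
                                        x_grid = c(0, 1, 2, 4, 6, 8, 12, 16,
                                                   20, 30, 40),
                                        noise = NULL, x50 = 5) {
  mode <- match.arg(mode)
  if (!(ymax > ymin)) stop("ymax must exceed ymin", call. = FALSE)
  y <- switch(mode,
    full_exchange = ymin + (ymax - ymin) * exp(-x_grid / x50),
    no_exchange = rep(ymax, length(x_grid))
  )
  gen <- function() {
    tibble::tibble(
      x_ratio = x_grid,
      efret = apply_noise(y, noise, clamp_min = 0, clamp_max = 1)
    )
  }
  out <- if (is.null(noise)) gen() else withr::with_seed(noise$seed, gen())
  attr(out, "truth") <- list(ymax = ymax, ymin = ymin, mode = mode, x50 = x50)
  out
}

#' Generate a normalized competition titration
#'
#' Proportional-partitioning competition: with the labeled substrate at
#' `L` nM and unlabeled competitor at `C` nM, a limiting amount of binding
#' protein distributes between the two in proportion to concentration
#' weighted by relative affinity, so the normalized labeled-complex signal
#' is \eqn{y = L / (L + \rho C)} where \eqn{\rho} is the competitor's
#' affinity relative to the labeled substrate. The curve is reported
#' against `x_ratio = C / (L + C)`, the competitor share of total DNA; for
#' \eqn{\rho = 1} the 50% crossing falls exactly at 0.50.
#'
#' The protein-limiting assumption (`rpa_active <= L`) is what makes the
#' partitioning proportional; it encodes the self-competition expectation,
#' not a measured active fraction.
#'
#' @param L Labeled DNA concentration, nM (default 25).
#' @param rpa_active Active binding-protein concentration, nM (must not
#'   exceed `L`).
#' @param rel_affinity Competitor affinity relative to the labeled
#'   substrate (1 = identical).
#' @param C_grid Competitor concentrations, nM (increasing, starting at 0).
#' @param noise A [noise_model()] on the normalized signal, or `NULL`.
#' @return A tibble `(competitor_nM, x_ratio, y_norm)` with a `truth`
#'   attribute.
#' @export
gen_competition_titration <- function(L = 25, rpa_active = 20,
                                      rel_affinity = 1,
                                      C_grid = seq(0, 6 * L,
                                                   length.out = 121),
                                      noise = NULL) {
  check_pos(L, "L")
  check_pos(rel_affinity, "rel_affinity")
  if (rpa_active > L) {
    stop("proportional partitioning requires rpa_active <= L", call. = FALSE)
  }
  y <- L / (L + rel_affinity * C_grid)
  gen <- function() {
    tibble::tibble(
      competitor_nM = C_grid,
      x_ratio = C_grid / (L + C_grid),
      y_norm = apply_noise(y, noise, clamp_min = 0, clamp_max = 1)
    )
  }
  out <- if (is.null(noise)) gen() else withr::with_seed(noise$seed, gen())
  attr(out, "truth") <- list(L = L, rpa_active = rpa_active,
                             rel_affinity = rel_affinity)
  out
}

#' Generate mass-photometry landing events
#'
#' I.i.d. draws from a Gaussian mixture over particle mass. `sigmas` are
#' conventional standard deviations; fitting with [fit_gaussian_mixture()]
#' returns widths on the no-1/2-exponent scale (`c = sigma * sqrt(2)`).
#'
#' @param weights Mixture weights, summing to 1.
#' @param means_kDa Component means, kDa.
#' @param sigmas Component standard deviations, kDa.
#' @param n_events Number of landing events (>= 100).
#' @param seed Integer RNG seed (required).
#' @return A tibble with column `mass_kDa` and a `truth` attribute.
#' @export
gen_mass_events <- function(weights, means_kDa, sigmas, n_events, seed) {
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("weights must sum to 1", call. = FALSE)
  }
  if (n_events < 100) stop("need at least 100 events", call. = FALSE)
  stopifnot(length(weights) == length(means_kDa),
            length(weights) == length(sigmas))
  out <- withr::with_seed(as.integer(seed), {
    comp <- sample.int(length(weights), n_events, replace = TRUE,
                       prob = weights)
    tibble::tibble(
      mass_kDa = stats::rnorm(n_events, means_kDa[comp], sigmas[comp])
    )
  })
  attr(out, "truth") <- list(weights = weights, means_kDa = means_kDa,
                             sigmas = sigmas)
  out
}

#' Generate a percent-product-formation panel
#'
#' Emulates endpoint cleavage assays on protein-coated substrate: DNA
#' (default 100 nM) pre-saturated with a single-strand-binding protein
#' (default 200 nM) is mixed with enzyme at several enzyme:DNA ratios and
#' quenched at fixed times. Product formation follows a pseudo-first-order
#' model whose apparent rate increases with enzyme (saturating in the
#' ratio) and is divided by `suppression` (>= 1), the factor by which the
#' bound protein slows cleavage; `suppression = 1` reproduces the
#' unsuppressed kinetics.
#'
#' @param rate Intrinsic cleavage rate, s^-1.
#' @param ratios Enzyme:DNA ratios (default 1, 5, 10).
#' @param timepoints Quench times, seconds (default 30, 60, 600).
#' @param noise A [noise_model()] on the percent scale (floor ~1), or
#'   `NULL`.
#' @param suppression Rate-suppression factor (>= 1).
#' @param dna_nM,rpa_nM Design concentrations (recorded, not varied).
#' @return A tibble `(ratio, time_s, percent_product)` in `[0, 100]`, with
#'   a `truth` attribute.
#' @export
gen_product_formation_panel <- function(rate, ratios = c(1, 5, 10),
                                        timepoints = c(30, 60, 600),
                                        noise = NULL, suppression = 1,
                                        dna_nM = 100, rpa_nM = 200) {
  check_pos(rate, "rate")
  if (suppression < 1) stop("suppression must be >= 1", call. = FALSE)
  grid <- tidyr::expand_grid(ratio = ratios, time_s = timepoints)
  k_app <- rate * grid$ratio / (grid$ratio + 1) / suppression
  pct <- 100 * (1 - exp(-k_app * grid$time_s))
  gen <- function() {
    grid$percent_product <- apply_noise(pct, noise, clamp_min = 0,
                                        clamp_max = 100)
    grid
  }
  out <- if (is.null(noise)) gen() else withr::with_seed(noise$seed, gen())
  attr(out, "truth") <- list(rate = rate, suppression = suppression,
                             dna_nM = dna_nM, rpa_nM = rpa_nM)
  out
}
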