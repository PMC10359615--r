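---
title: "Models and methods behind apekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind apekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apekin)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the numerical
choices, and what the synthetic-data validation does and does not show.

## Kinetic models

### Biphasic multiple-turnover kinetics

With substrate DNA in excess of enzyme (the standard design here is DNA
100 nM, enzyme 30 nM), product formation from an abasic-site endonuclease
is biphasic:

$$P(t) = A\,(1 - e^{-k_{obs} t}) + v_{ss}\,t$$

The exponential phase is the first turnover on every productively engaged
enzyme: its amplitude $A$ (nM) measures the actively bound enzyme
population and its rate $k_{obs}$ (s$^{-1}$) the incision chemistry. The
linear phase is rate-limited by whatever step recycles the enzyme —
presumed product release — with steady-state velocity $v_{ss}$ (nM/s) and
rate constant $k_{ss} = v_{ss}/A$ (s$^{-1}$, `steady_state_rate()`).

An identifiability caveat is built into `fit_burst()`: when
$k_{obs}/k_{ss} < 10$ the two phases blend and $k_{obs}$ is poorly
determined, so the fit carries a `low-separation` warning. This is not a
convergence failure — the optimizer converges — but a statement that the
experiment, not the fitter, limits the precision; the appropriate
confirmation is a single-turnover measurement, fitted by
`fit_single_exp()` ($P(t) = A(1-e^{-k_{obs}t})$, enzyme in excess) or, for
enzymes with two kinetically distinct populations, `fit_double_exp()`.
In the biexponential the components are stored amplitude-descending and
`major_rate` is the rate of the larger-amplitude population — the
operational reading of "the rate of the major population". If the two
rates collapse (relative difference < 5%) or one amplitude vanishes, the
biexponential is unidentifiable and the function falls back to the single
exponential with a `degenerate-biexponential` warning rather than
reporting meaningless split parameters.

### The mechanistic simulator and what "product" means

The minimal scheme that produces biphasic kinetics is

$$E + S \rightleftharpoons ES \xrightarrow{k_{chem}} EP \xrightarrow{k_{rel}} E + P$$

implemented as a mass-action ODE (`simulate_turnover_ode()`, `deSolve`
with relative tolerance $10^{-8}$ and absolute tolerance $10^{-10}$ nM —
the rates span six orders of magnitude, so a stiff-capable integrator is
required) and as an exact stochastic simulation
(`simulate_turnover_stochastic()`, Gillespie direct method over molecule
counts; identical seeds give identical event lists). Binding defaults to
fast ($k_{on} = 100$ nM$^{-1}$s$^{-1}$, $k_{off} = 0$) because the fitted
closed form has no binding step; both are exposed for sensitivity work.

Two modeling points deserve emphasis:

* **The assay observable is total cleaved DNA.** A rapid-quench assay
  denatures all complexes, so enzyme-bound product counts as product on
  the gel. The quantity the burst closed form describes is therefore
  $EP + P$ (`cleaved_nM`), not released $P$; fitting released product
  alone would misestimate the burst badly whenever release is slow.
* **Two meanings of $k_{ss}$.** Under saturating substrate the scheme
  implies $k_{obs} = k_{chem} + k_{rel}$,
  $A = E_0 (k_{chem}/(k_{chem}+k_{rel}))^2$ and
  $v_{ss} = E_0\, k_{chem} k_{rel}/(k_{chem}+k_{rel})$
  (`effective_burst_params()`). The *per-enzyme* steady-state rate is
  $v_{ss}/E_0 = k_{chem}k_{rel}/(k_{chem}+k_{rel})$, which is what the
  closed form reports as `kss`; the *operational* estimator $v_{ss}/A$
  equals $k_{rel}(k_{chem}+k_{rel})/k_{chem}$ instead. The two converge
  only when $k_{chem} \gg k_{rel}$ — which is also the only regime in
  which "$k_{ss}$ is product release" is a safe interpretation. The
  oracle-equivalence tests therefore compare the fitted $v_{ss}/E_0$
  against the closed-form `kss`, and the package never silently equates
  $v_{ss}/A$ with $k_{rel}$.

When comparing the ODE to the closed form, the substrate pool must
actually remain saturating over the fit window: at $k_{chem}=10$,
$k_{rel}=2.7$, $E_0=30$ nM, a 100 nM pool is exhausted before 1 s, so the
equivalence tests use a 300 nM pool over a 1.5 s window (and the 100 nM
design over a correspondingly shorter window). The tests state their
problem sizes (200 stochastic trajectories, 150-point ODE grids) as the
sizes at which the Monte-Carlo and discretization errors are comfortably
below the 5% comparison band.

## Tight-binding (Morrison) analysis

At 5 nM DNA the affinities involved are comparable to the ligand
concentration, so free enzyme cannot be equated with total enzyme and the
bound complex follows the tight-binding quadratic implemented in
`morrison_bound()`. The package evaluates the algebraically equivalent
form $2A_TB_T/((A_T+B_T+K_D) + \sqrt{(A_T+B_T+K_D)^2-4A_TB_T})$, which
avoids the catastrophic cancellation of the textbook form as
$K_D \to 0$; equality of the two forms is property-tested across eleven
orders of magnitude.

`fit_morrison()` estimates only $K_{D,app}$, with $B_T$ fixed (default
5 nM), matching how such titrations are analyzed. Its identifiability
guards encode two distinct failure modes:

* all non-zero points > 95% bound — the curve carries no affinity
  information at all and the fit aborts with guidance;
* $\hat K_D < B_T$ (or relative SE > 25%) — the titration is
  near-stoichiometric: the curve degenerates towards a step at
  $A_T = B_T$ and $K_D$ is only weakly constrained. The fit succeeds but
  carries a `tight-binding` warning. We chose the $\hat K_D < B_T$ trigger
  in addition to the empirical-SE trigger because with three pooled
  replicates at realistic noise the formal SE can look respectable
  (~10%) even though the estimate rests on one or two lanes near the
  stoichiometric corner — the regime itself, not the fitted SE, is the
  reliable danger signal.

The default EMSA design is a serial two-fold dilution series
(2000/2$^{10..0}$ nM plus the zero lane), which is how such titrations are
actually pipetted; an arbitrary dense log grid reaching far below 1 nM
would overstate how well a gel experiment constrains sub-nanomolar
affinities.

## FRET exchange and competition

$E_{FRET} = I_{665}/(I_{665}+I_{563})$ (`efret()`) is a proximity ratio,
not a corrected FRET efficiency; fluorophore photophysics (quantum
yields, crosstalk, inner-filter effects) are deliberately out of scope.
The no-interaction anchor is computed by summing the component spectra
channel-wise before taking the ratio
(`predicted_no_interaction_efret()`), an algebraic identity that is
property-tested.

`plateau_efret()` operationalizes "record until the signal is constant
for at least one minute, then average": the earliest 60 s window that is
both quiet (sd/mean ≤ 2%) and trendless (fitted linear drift across the
window ≤ 2% of the mean). The drift condition matters: a slow monotone
ramp can have window scatter below any sd threshold while never being a
plateau. The 2% constancy tolerance is our choice (the procedure's
source states the window but not the tolerance); it sits well above the
generator's E_FRET noise floor (~0.005/0.3 ≈ 1.7%) and well below any
real exchange transition (~0.27 span).

Exchange titrations are normalized between the observed no-competitor
anchor (Y-max) and the predicted no-interaction anchor (Y-min)
(`normalize_titration()`), and the 50%-inhibition point of a competition
curve is located by linear interpolation between the bracketing points
(`inhibition_midpoint()`) — not by a 4-parameter logistic fit, because
the reported quantity is the crossing ratio itself, and interpolation on
a dense monotone curve is exact to the grid resolution. A curve that
never reaches 0.5 (partial exchange) raises an error rather than
extrapolating.

The competition generator uses RPA-limiting proportional partitioning:
with labeled substrate $L$ and competitor $C$ at relative affinity
$\rho$, the normalized labeled-complex signal is $y = L/(L+\rho C)$,
reported against $C/(L+C)$. For $\rho = 1$ the 50% crossing falls at
exactly 0.50 — the self-competition expectation that validates the
approach — and at $\rho = 1.5$ at 0.40, the qualitative signature of a
tighter-binding competitor. The protein-limiting assumption
(`rpa_active <= L`) is what makes partitioning proportional; it encodes
the expectation rather than a measured active fraction, and the
generator refuses configurations that violate it.

## Mass photometry

Landing-event histograms are decomposed by nonlinear least squares into
the mixture $f(x) = \sum_n a_n \exp(-((x-b_n)/c_n)^2)$ — note the absence
of the usual $\tfrac12$ factor in the exponent. The width parameter
therefore relates to a conventional Gaussian standard deviation by
$c = \sigma\sqrt2$, and component areas are $a c \sqrt\pi$, so population
fractions are $a_i c_i / \sum_j a_j c_j$ (`population_fractions()`),
which sum to 1 exactly. The event generator draws from conventional-σ
Gaussians; the $\sqrt2$ conversion on fitting is covered by tests.

Initialization finds local maxima of the lightly smoothed histogram
(falling back to count quantiles), and the fit warns on component
collapse — either two means within half the larger width, or a component
carrying under 2% of the area. Both are ways the data can fail to
support the requested number of populations; the second matters because
an overfit component often resolves as a vanishing far peak rather than
two overlapping means. Contrast-to-mass calibration
(`calibrate_contrast()`) is an affine least-squares map through the
fitted peak centers of a known standard.

As an independent cross-check, the test suite compares the binned-NLS
decomposition against an EM fit of the raw events (`mclust`): means and
fractions agree within the recovery tolerances, by two entirely
different estimation routes.

## Fitting machinery

All nonlinear fits go through one internal routine: Levenberg–Marquardt
least squares (`minpack.lm`) on log-transformed parameters. The log
transform enforces positivity (rates spanning $10^{-4}$–$130$
s$^{-1}$ make box constraints awkward) and equalizes step scales across
that range; standard errors are mapped back by the delta method. On
non-convergence the start is jittered (5 restarts, SD 0.4 in log space,
fixed internal seed, best deviance wins). Residuals are unweighted,
matching gel-quantification practice where per-point variances are not
available. Starting values are model-specific: the burst fit seeds
$v_{ss}$ and $A$ from a linear fit of the tail and $k_{obs}$ from a
log-linear fit of the burst-corrected rise; the Morrison fit seeds
$K_D$ from the enzyme concentration at half-maximal binding.

Lack-of-fit for the single exponential is screened by a one-sided
Wald–Wolfowitz runs test on residual signs (`residual-structure` warning
at p < 0.01): data generated by a well-separated double exponential leave
long same-sign runs. The package deliberately does not auto-select
between single and double exponentials — the warning invites the
analyst's judgment instead of an information criterion, since the choice
in practice rests on mechanistic knowledge of the enzyme.

Fold changes between rates are reported as the ≥ 1 ratio with a
direction, and their uncertainties by first-order ratio propagation
($se = fold\sqrt{(se_{ref}/ref)^2 + (se_{val}/val)^2}$). Published
fold-change uncertainties of this kind are not always internally
consistent with any single propagation rule, so only central fold values
should be compared against printed tables.

## The generators: what they emulate, and what passing tests show

Each generator reproduces the statistical structure its analysis
assumes: biphasic or exponential time courses on rapid-quench grids
(instrument minimum 0.002 s), quadratic saturation at 5 nM DNA,
two-endpoint exchange titrations, proportional-partitioning competition,
two-component mass mixtures. Noise is proportional Gaussian
(cv 3%) with an additive floor (0.5 nM product, ~0.005 E_FRET, 1%
bound-fraction), chosen once to match typical replicate scatter of
quantified gel bands; every generator takes a required seed and records
its truth in a `truth` attribute (and a `# truth:` CSV header via
`write_experiment_table()`), so recovery tests are blind but auditable.

What the generators do **not** emulate bounds what passing tests can
claim: real quench-flow data have timing jitter and quench dead-time,
gels have lane-to-lane loading variation and saturation, FRET traces
have photobleaching drifts, and mass photometry has contrast
nonlinearity at low mass. Parameter recovery here demonstrates that the
estimators are unbiased and correctly calibrated *under the assumed
error model* — it validates the analysis pipeline, not the instruments.

Default problem sizes (3 replicates of 21–25 time points, 12-lane
titrations in triplicate, 5000 landing events, 200 stochastic
trajectories) are the sizes of the corresponding real experiments; they
also keep the full validation suite fast.

## Known limitations

* No global multi-curve fitting, Bayesian inference, or formal model
  selection; warnings flag, the analyst decides.
* The two-step scheme excludes product rebinding/inhibition and
  multi-substrate competition; `kss ≈ k_rel` is asserted only in the
  $k_{chem} \gg k_{rel}$ limit.
* Morrison fits treat $B_T$ as exactly known; errors in the DNA
  concentration propagate directly into $K_{D,app}$.
* The competition model assumes equilibrium proportional partitioning
  with limiting protein; kinetically trapped complexes would violate it.
* E_FRET is a proximity ratio; absolute distances are out of scope.
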