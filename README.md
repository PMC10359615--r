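# apekin

Quantitative analysis of AP-endonuclease 1 (APE1) cleavage assays at DNA
substrates that mimic stalled replication forks — primer–template junctions
(PTJ), recessed junctions and single-stranded DNA carrying an abasic site —
together with the binding and biophysical assays that surround them.

APE1 incises the DNA backbone 5′ of an abasic site. On these substrates its
pre-steady-state kinetics are biphasic: a fast burst (the first turnover on
every productively engaged enzyme, rate *k*<sub>obs</sub>, interpreted as
chemistry) followed by a slower linear steady state (rate
*k*<sub>ss</sub> = *v*<sub>ss</sub>/*A*, interpreted as product release).
The package fits every quantitative model used in this kind of study and
pairs each fit with a seeded synthetic-data generator and a mechanistic
simulator, so the whole pipeline is verifiable by parameter recovery
without any external data.

## What it fits

| Assay | Model | Function |
|---|---|---|
| Multiple-turnover quench flow | *P*(*t*) = *A*(1 − e<sup>−*k*<sub>obs</sub>*t*</sup>) + *v*<sub>ss</sub>*t* | `fit_burst()` |
| Single-turnover quench flow | *P*(*t*) = *A*(1 − e<sup>−*k*<sub>obs</sub>*t*</sup>) | `fit_single_exp()` |
| Two-population single turnover | *A*(1 − e<sup>−*k*<sub>1</sub>*t*</sup>) + *B*(1 − e<sup>−*k*<sub>2</sub>*t*</sup>) | `fit_double_exp()` |
| EMSA titration (tight binding) | Morrison quadratic: *AB* = ((*A*<sub>T</sub>+*B*<sub>T</sub>+*K*<sub>D</sub>) − √((*A*<sub>T</sub>+*B*<sub>T</sub>+*K*<sub>D</sub>)² − 4*A*<sub>T</sub>*B*<sub>T</sub>))/2 | `fit_morrison()` |
| Ensemble FRET exchange | *E*<sub>FRET</sub> = *I*<sub>665</sub>/(*I*<sub>665</sub>+*I*<sub>563</sub>), plateau averaging, Y-max/Y-min normalization | `plateau_efret()`, `normalize_titration()` |
| Competition titration | proportional partitioning, 50%-inhibition crossing | `inhibition_midpoint()` |
| Mass photometry | Gaussian mixture *f*(*x*) = Σ *a*<sub>n</sub> exp(−((*x*−*b*<sub>n</sub>)/*c*<sub>n</sub>)²) | `fit_gaussian_mixture()` |

A minimal two-step turnover scheme (E+S ⇌ ES →<sup>*k*chem</sup> EP
→<sup>*k*rel</sup> E+P) is implemented as a deterministic ODE and an exact
stochastic (Gillespie) simulation (`simulate_turnover_ode()`,
`simulate_turnover_stochastic()`); its closed-form burst parameters
(`effective_burst_params()`) serve as an independent oracle for the fitted
model. Every assay has a seeded generator (`gen_timecourse()`,
`gen_emsa_titration()`, `gen_fret_exchange_titration()`,
`gen_competition_titration()`, `gen_mass_events()`,
`gen_product_formation_panel()`).

Fits are returned as tidy objects: `tidy()` gives the parameter table,
`glance()` the fit summary, `augment()` fitted values and residuals, and
`autoplot()` a diagnostic figure.

## Worked example

Simulate three replicate multiple-turnover time courses at the standard
design (DNA 100 nM, APE1 30 nM, rapid-quench grid from 0.002 s) from a
PTJ-like truth (*k*<sub>obs</sub> = 10 s⁻¹, *k*<sub>ss</sub> = 2.7 s⁻¹,
*A* = 30 nM) with 3% noise, and fit the burst model:

```r
library(apekin)

tc <- gen_timecourse(
  truth  = list(A = 30, kobs = 10, vss = 81),   # vss = kss * A
  design = design_multiple_turnover(),
  noise  = noise_model(cv = 0.03, floor = 0.5, seed = 101)
)
fit <- fit_burst(tc)
tidy(fit)
#> # A tibble: 4 × 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 A        28.4      0.999
#> 2 kobs     10.7      0.596
#> 3 vss      82.5      1.68
#> 4 kss       2.90     0.118
```

The truth is recovered (`kobs` 10.7 ± 0.6 vs 10; `kss` 2.90 ± 0.12 vs
2.7), and because the two phases are kinetically close
(*k*<sub>obs</sub>/*k*<sub>ss</sub> = 3.7 < 10) the fit carries the
`low-separation` warning — exactly the regime where a single-turnover
experiment should confirm *k*<sub>obs</sub>:

```r
glance(fit)$warnings
#> [1] "low-separation: kobs/kss = 3.70 < 10; kobs is poorly determined"
```

Rate tables with fold changes (first-order error propagation, reference
row dashed) are produced by `report_kinetics()`:

```r
rates <- tibble::tibble(
  substrate = c("dsDNA", "PTJ", "RecPTJ", "ssDNA"),
  kobs = c(129, 10, 30, 2),      kobs_se = c(24, 1, 4, 0.2),
  kss  = c(1.7, 2.7, 5.9, 0.15), kss_se  = c(0.26, 0.21, 0.32, 0.018)
)
format_kinetics_report(report_kinetics(rates, reference = "dsDNA"))
#> # A tibble: 4 × 5
#>   substrate kobs     kobs_fold   kss          kss_fold
#>   <chr>     <chr>    <chr>       <chr>        <chr>
#> 1 dsDNA     129 ± 24 –           1.7 ± 0.26   –
#> 2 PTJ       10 ± 1   12.9 ± 2.7  2.7 ± 0.21   1.6 ± 0.3
#> 3 RecPTJ    30 ± 4   4.3 ± 1.0   5.9 ± 0.32   3.5 ± 0.6
#> 4 ssDNA     2 ± 0.2  64.5 ± 13.6 0.15 ± 0.018 11.3 ± 2.2
```

A 12.9-fold slower chemistry at the junction, 64.5-fold slower on pure
ssDNA, with product release mildly accelerated at junctions — the
substrate-position dependence this analysis quantifies.

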