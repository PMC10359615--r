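# Published central rates used as generator truths and report inputs:
# wild-type multiple-turnover parameters per substrate (kobs, kss in 1/s).
wt_rates <- function() {
  tibble::tibble(
    substrate = c("dsDNA", "PTJ", "RecPTJ", "ssDNA"),
    kobs = c(129, 10, 30, 2),
    kobs_se = c(24, 1, 4, 0.2),
    kss = c(1.7, 2.7, 5.9, 0.15),
    kss_se = c(0.26, 0.21, 0.32, 0.018)
  )
}

# Wild-type / R177A pairs for the paired-mode report.
paired_rates <- function() {
  dplyr::bind_rows(
    dplyr::mutate(wt_rates()[2:4, ], enzyme = "WT"),
    tibble::tibble(
      enzyme = "R177A",
      substrate = c("PTJ", "RecPTJ", "ssDNA"),
      kobs = c(0.23, 0.12, 0.001),
      kobs_se = c(0.03, 0.015, 0.0001),
      kss = c(0.07, 0.06, 0.0001),
      kss_se = c(0.003, 0.006, 0.000008)
    )
  )
}

# burst truth for the PTJ substrate: A = 30 nM (all enzyme engaged),
# kobs = 10/s, vss = kss * A = 81 nM/s
ptj_truth <- function() list(A = 30, kobs = 10, vss = 81)
dsdna_truth <- function() list(A = 30, kobs = 129, vss = 51)

expect_rel_equal <- function(actual, expected, rtol) {
  expect_true(
    all(abs(actual - expected) <= rtol * abs(expected)),
    label = sprintf("%.8g vs %.8g (rtol %g)", actual[1], expected[1], rtol)
  )
}
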