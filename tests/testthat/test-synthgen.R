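test_that("generators are deterministic under a fixed seed", {
  n <- noise_model(seed = 42)
  a <- gen_timecourse(ptj_truth(), design_multiple_turnover(), n)
  b <- gen_timecourse(ptj_truth(), design_multiple_turnover(), n)
  expect_identical(a, b)
  c1 <- gen_timecourse(ptj_truth(), design_multiple_turnover(),
                       noise_model(seed = 43))
  expect_false(identical(a, c1))

  e1 <- gen_mass_events(c(0.9, 0.1), c(150, 260), c(12, 16), 500, seed = 3)
  e2 <- gen_mass_events(c(0.9, 0.1), c(150, 260), c(12, 16), 500, seed = 3)
  expect_identical(e1, e2)
})

test_that("zero noise reproduces the model exactly and truth is attached", {
  tc <- gen_timecourse(ptj_truth(), design_multiple_turnover(),
                       noise_model(cv = 0, floor = 0, seed = 1), n_reps = 1)
  expect_equal(tc$product_nM,
               eval_burst(tc$time_s, 30, 10, 81), tolerance = 1e-12)
  expect_equal(attr(tc, "truth"), ptj_truth())
  expect_equal(attr(tc, "design")$regime, "multiple_turnover")

  tit <- gen_emsa_titration(22, design_emsa(), NULL, n_reps = 1)
  expect_equal(tit$bound_nM, morrison_bound(tit$enzyme_nM, 5, 22),
               tolerance = 1e-12)
  expect_equal(attr(tit, "truth")$KD, 22)
})

test_that("stoichiometric binding steps to saturation at KD = 0", {
  tit <- gen_emsa_titration(0, design_emsa(), NULL, n_reps = 1)
  at <- tit$enzyme_nM
  expect_equal(tit$fraction_bound[at >= 5], rep(1, sum(at >= 5)))
  expect_equal(tit$bound_nM[at < 5], pmin(at[at < 5], 5))
})

test_that("generator truths round-trip through their fitters end to end", {
  tc <- gen_timecourse(ptj_truth(), design_multiple_turnover(),
                       noise_model(seed = 10))
  expect_rel_equal(fit_burst(tc)$params$kobs, 10, 0.10)

  tit <- gen_emsa_titration(22, design_emsa(),
                            noise_model(cv = 0.03, floor = 0.01, seed = 8))
  expect_rel_equal(fit_morrison(tit)$params$KD_app, 22, 0.20)

  ev <- gen_mass_events(c(0.9, 0.1), c(150, 260), c(12, 16), 5000, seed = 9)
  fr <- fit_gaussian_mixture(ev, 2)$params$components$fraction
  expect_equal(fr[1], 0.9, tolerance = 0.03)
})

test_that("mass-event draws respect the component means", {
  ev <- gen_mass_events(1, 150, 12, 2000, seed = 21)
  expect_lt(abs(mean(ev$mass_kDa) - 150), 3 * 12 / sqrt(2000))
  expect_error(gen_mass_events(c(0.5, 0.4), c(1, 2), c(1, 1), 500, seed = 1),
               "sum to 1")
  expect_error(gen_mass_events(1, 150, 12, 50, seed = 1), "at least 100")
})

test_that("product-formation panels are bounded and monotone in enzyme", {
  pan <- gen_product_formation_panel(rate = 0.02, suppression = 3,
                                     noise = noise_model(cv = 0.03,
                                                         floor = 1,
                                                         seed = 6))
  expect_true(all(pan$percent_product >= 0 & pan$percent_product <= 100))
  clean <- gen_product_formation_panel(rate = 0.02, suppression = 3)
  by_time <- split(clean, clean$time_s)
  for (tbl in by_time) {
    expect_true(all(diff(tbl$percent_product[order(tbl$ratio)]) >= 0))
  }
  # no suppression reproduces the unsuppressed kinetics
  free <- gen_product_formation_panel(rate = 0.02, suppression = 1)
  k_app <- 0.02 * free$ratio / (free$ratio + 1)
  expect_equal(free$percent_product, 100 * (1 - exp(-k_app * free$time_s)),
               tolerance = 1e-12)
})
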