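test_that("effective burst parameters match the two-step closed forms", {
  # single-turnover limit: no release, the whole enzyme pool bursts
  p0 <- effective_burst_params(mechanism_scheme(10, 0), E0 = 30)
  expect_equal(p0$kobs, 10)
  expect_equal(p0$A, 30)
  expect_equal(p0$vss, 0)
  # frozen closed-form arithmetic at kc = 10, kr = 2.7
  p1 <- effective_burst_params(mechanism_scheme(10, 2.7), E0 = 30)
  expect_equal(p1$kobs, 12.7)
  expect_equal(p1$A, 30 * (10 / 12.7)^2, tolerance = 1e-12)
  expect_equal(round(p1$A, 2), 18.6)
  expect_equal(round(p1$kss, 3), 2.126)
  # chemistry >> release: amplitude ~ E0, kss ~ k_rel
  p2 <- effective_burst_params(mechanism_scheme(129, 1.7), E0 = 30)
  expect_equal(round(p2$A, 2), 29.22)
  expect_equal(round(p2$kss, 3), 1.678)
  expect_error(effective_burst_params(mechanism_scheme(0, 1), 30), "positive")
})

test_that("ODE simulation conserves mass and respects bounds", {
  sch <- mechanism_scheme(10, 2.7)
  tg <- seq(0.01, 1, by = 0.01)
  out <- simulate_turnover_ode(sch, E0 = 30, S0 = 100, t_grid = tg)
  expect_lt(max(abs(out$E + out$ES + out$EP - 30)), 1e-6)
  expect_lt(max(abs(out$S + out$ES + out$EP + out$product_nM - 100)), 1e-6)
  expect_true(all(diff(out$cleaved_nM) >= -1e-9))
  expect_true(all(out$cleaved_nM <= 100 + 1e-6))
  expect_true(all(out[, c("S", "ES", "EP", "E", "product_nM")] >= -1e-8))
  # no substrate, no product
  none <- simulate_turnover_ode(sch, 30, 0, tg)
  expect_equal(max(none$cleaved_nM), 0)
})

test_that("a burst fit of the simulated course recovers the closed forms", {
  sch <- mechanism_scheme(10, 2.7)
  eff <- effective_burst_params(sch, E0 = 30)
  # saturating substrate so the closed form's premise holds over the window
  ode <- simulate_turnover_ode(sch, E0 = 30, S0 = 300,
                               t_grid = seq(0.002, 1.5, by = 0.01))
  tc <- tibble::tibble(time_s = ode$time_s, product_nM = ode$cleaved_nM)
  attr(tc, "design") <- list(regime = "multiple_turnover")
  fit <- fit_burst(tc)
  expect_rel_equal(fit$params$kobs, eff$kobs, 0.05)
  expect_rel_equal(fit$params$A, eff$A, 0.05)
  # closed-form kss is the per-enzyme steady-state rate, i.e. vss / E0
  expect_rel_equal(fit$params$vss / 30, eff$kss, 0.05)
})

test_that("stochastic simulation is seed-deterministic and empty without substrate", {
  sch <- mechanism_scheme(10, 2.7)
  t1 <- simulate_turnover_stochastic(sch, 30, 100, 1, seed = 11)
  t2 <- simulate_turnover_stochastic(sch, 30, 100, 1, seed = 11)
  expect_identical(t1, t2)
  t3 <- simulate_turnover_stochastic(sch, 30, 100, 1, seed = 12)
  expect_false(identical(t1, t3))
  empty <- simulate_turnover_stochastic(sch, 30, 0, 1, seed = 1)
  expect_equal(max(empty$P), 0)
  expect_error(simulate_turnover_stochastic(sch, 30, 10, 0, seed = 1),
               "positive")
})

test_that("stochastic trajectory means agree with the ODE solution", {
  sch <- mechanism_scheme(10, 2.7)
  tpts <- c(0.1, 0.3, 0.6)
  sims <- vapply(
    1:200,
    function(s) stochastic_product_at(
      simulate_turnover_stochastic(sch, 30, 100, 0.65, seed = s), tpts
    ),
    numeric(3)
  )
  ode <- simulate_turnover_ode(sch, 30, 100, tpts)$cleaved_nM
  mc_mean <- rowMeans(sims)
  mc_sem <- apply(sims, 1, stats::sd) / sqrt(ncol(sims))
  expect_true(all(abs(mc_mean - ode) <= 3 * mc_sem))
})
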