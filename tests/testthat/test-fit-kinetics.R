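test_that("noiseless time-course fits are round-trip identities", {
  mt <- gen_timecourse(ptj_truth(), design_multiple_turnover(), NULL,
                       n_reps = 1)
  fb <- fit_burst(mt)
  expect_rel_equal(fb$params$A, 30, 1e-6)
  expect_rel_equal(fb$params$kobs, 10, 1e-6)
  expect_rel_equal(fb$params$vss, 81, 1e-6)
  expect_rel_equal(fb$params$kss, 2.7, 1e-6)

  st <- gen_timecourse(list(A = 50, kobs = 13.6), design_single_turnover(),
                       NULL, n_reps = 1)
  fs <- fit_single_exp(st)
  expect_rel_equal(fs$params$A, 50, 1e-6)
  expect_rel_equal(fs$params$kobs, 13.6, 1e-6)

  slow <- design_single_turnover(t_grid = 10^seq(log10(0.02), log10(120),
                                                 length.out = 22))
  d0 <- gen_timecourse(list(A = 40, k1 = 0.05, B = 10, k2 = 2), slow, NULL,
                       n_reps = 1)
  fd <- fit_double_exp(d0)
  expect_rel_equal(fd$params$A, 40, 1e-5)
  expect_rel_equal(fd$params$k1, 0.05, 1e-5)
  expect_rel_equal(fd$params$B, 10, 1e-5)
  expect_rel_equal(fd$params$k2, 2, 1e-5)
  expect_equal(fd$params$major_rate, fd$params$k1)
})

test_that("round-trip identity holds across the published rate magnitudes", {
  withr::with_seed(17, {
    for (i in 1:8) {
      kobs <- 10^runif(1, -2, 2.1)
      kss <- kobs / 10^runif(1, 0.3, 1.5)
      A <- runif(1, 10, 60)
      grid <- c(10^seq(log10(0.05 / kobs), log10(3 / kobs), length.out = 14),
                seq(4, 10, by = 2) / kobs)
      d <- design_multiple_turnover(t_grid = grid)
      tc <- gen_timecourse(list(A = A, kobs = kobs, vss = kss * A), d,
                           NULL, n_reps = 1)
      f <- fit_burst(tc)
      expect_rel_equal(f$params$kobs, kobs, 1e-5)
      expect_rel_equal(f$params$kss, kss, 1e-5)
    }
  })
})

test_that("burst recovery at the published designs behaves as documented", {
  # substrate with kinetically close phases: recovery works but kobs is
  # flagged as poorly separated (kobs/kss < 10)
  tc <- gen_timecourse(ptj_truth(), design_multiple_turnover(),
                       noise_model(cv = 0.02, floor = 0.5, seed = 1))
  f <- fit_burst(tc)
  expect_rel_equal(f$params$kobs, 10, 0.10)
  expect_true(has_fit_warning(f, "low-separation"))

  # fast-chemistry substrate sampled from the 0.002 s instrument minimum:
  # phases well separated, no warning
  tcd <- gen_timecourse(dsdna_truth(), design_multiple_turnover(),
                        noise_model(cv = 0.03, floor = 0.5, seed = 1))
  fd <- fit_burst(tcd)
  expect_equal(min(attr(tcd, "design")$t_grid), 0.002)
  expect_rel_equal(fd$params$kobs, 129, 0.15)
  expect_false(has_fit_warning(fd, "low-separation"))
})

test_that("single-turnover recovery and misspecification detection", {
  st <- gen_timecourse(list(A = 50, kobs = 13.6), design_single_turnover(),
                       noise_model(cv = 0.02, floor = 0.5, seed = 2))
  f <- fit_single_exp(st)
  expect_rel_equal(f$params$kobs, 13.6, 0.10)
  expect_false(has_fit_warning(f, "residual-structure"))

  # data from a well-separated double exponential leave structured residuals
  slow <- design_single_turnover(t_grid = 10^seq(log10(0.02), log10(120),
                                                 length.out = 22))
  dbl <- gen_timecourse(list(A = 40, k1 = 0.05, B = 10, k2 = 2), slow,
                        noise_model(cv = 0.02, floor = 0.2, seed = 5))
  fm <- fit_single_exp(dbl)
  expect_true(has_fit_warning(fm, "residual-structure"))
})

test_that("double-exponential fit orders by amplitude and detects degeneracy", {
  slow <- design_single_turnover(t_grid = 10^seq(log10(0.02), log10(120),
                                                 length.out = 22))
  noisy <- gen_timecourse(list(A = 40, k1 = 0.05, B = 10, k2 = 2), slow,
                          noise_model(cv = 0.03, floor = 0.3, seed = 3))
  f <- fit_double_exp(noisy)
  expect_gte(f$params$A, f$params$B)
  expect_equal(f$params$major_rate, f$params$k1)
  expect_rel_equal(f$params$major_rate, 0.05, 0.15)

  # single-exponential truth: biexponential is degenerate, falls back
  single <- gen_timecourse(list(A = 50, kobs = 0.05), slow, NULL, n_reps = 1)
  fdeg <- fit_double_exp(single)
  expect_true(has_fit_warning(fdeg, "degenerate-biexponential"))
  expect_equal(fdeg$model, "single_exp")
  expect_rel_equal(fdeg$params$kobs, 0.05, 1e-4)
})

test_that("replicate aggregation follows the at-least-three convention", {
  agg <- aggregate_replicates(c(5, 5, 5))
  expect_equal(unlist(agg[, c("mean", "sd", "sem")]),
               c(mean = 5, sd = 0, sem = 0))
  agg2 <- aggregate_replicates(c(1, 2, 3))
  expect_equal(agg2$mean, 2)
  expect_equal(agg2$sd, 1)
  expect_equal(agg2$sem, 1 / sqrt(3), tolerance = 1e-9)
  expect_warning(aggregate_replicates(c(1, 2)), "3 independent")
  expect_error(aggregate_replicates(5), "at least 2")
})

test_that("fold-change errors follow first-order ratio propagation", {
  fc <- fold_change_with_error(129, 24, 10, 1)
  expect_equal(fc$fold, 12.9)
  # oracle: fold * sqrt((24/129)^2 + (1/10)^2)
  expect_equal(fc$fold_se, 12.9 * sqrt((24 / 129)^2 + 0.01),
               tolerance = 1e-12)
  expect_equal(round(fc$fold_se, 1), 2.7)
  expect_equal(fold_change_with_error(5, 0, 2, 0)$fold_se, 0)
  big <- fold_change_with_error(2, 0.2, 0.001, 0.0001)
  expect_equal(big$fold, 2000)
  expect_equal(big$fold_se, 2000 * sqrt(0.02), tolerance = 1e-9)
})

test_that("tidy, glance and augment expose fit internals", {
  mt <- gen_timecourse(ptj_truth(), design_multiple_turnover(), NULL,
                       n_reps = 1)
  f <- fit_burst(mt)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_setequal(td$term, c("A", "kobs", "vss", "kss"))
  gl <- glance(f)
  expect_true(gl$converged)
  expect_equal(gl$n, nrow(mt))
  au <- augment(f)
  expect_lt(max(abs(au$.resid)), 1e-5)
})
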