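test_that("burst model evaluates the closed form and its limits", {
  # direct arithmetic oracle: 30(1 - e^-1) + 81 * 0.1
  expect_equal(eval_burst(0.1, A = 30, kobs = 10, vss = 81),
               30 * (1 - exp(-1)) + 8.1, tolerance = 1e-12)
  expect_equal(eval_burst(0, A = 30, kobs = 10, vss = 81), 0)
  # once the exponential is exhausted the curve is linear with slope vss
  slope <- eval_burst(11, 30, 10, 81) - eval_burst(10, 30, 10, 81)
  expect_rel_equal(slope, 81, 1e-6)
  expect_error(eval_burst(-1, 30, 10, 81), "non-negative")
  expect_error(eval_burst(1, 30, 0, 81), "positive")
})

test_that("single exponential saturates at A with half-rise at ln2/k", {
  expect_rel_equal(eval_single_exp(100 / 13.6, A = 50, kobs = 13.6), 50, 1e-9)
  expect_equal(eval_single_exp(log(2) / 13.6, A = 50, kobs = 13.6), 25)
  expect_equal(eval_single_exp(0, 50, 13.6), 0)
})

test_that("double exponential sums components and degenerates cleanly", {
  t <- c(0, 0.1, 0.5, 2, 10, 100)
  expect_equal(eval_double_exp(t, A = 40, k1 = 0.05, B = 0, k2 = 2),
               eval_single_exp(t, 40, 0.05))
  # frozen from high-precision arithmetic: 40(1-e^-0.025) + 10(1-e^-1)
  expect_equal(eval_double_exp(0.5, 40, 0.05, 10, 2), 7.3088091,
               tolerance = 1e-7)
  expect_rel_equal(eval_double_exp(1e4, 40, 0.05, 10, 2), 50, 1e-9)
})

test_that("burst reduces to the single exponential when vss = 0", {
  withr::with_seed(42, {
    for (i in 1:25) {
      A <- runif(1, 1, 100)
      k <- 10^runif(1, -3, 2)
      t <- sort(runif(8, 0, 5 / k))
      expect_equal(eval_burst(t, A, k, 0), eval_single_exp(t, A, k))
    }
  })
})

test_that("steady-state rate constant is vss / A", {
  expect_equal(steady_state_rate(0, 30), 0)
  expect_equal(steady_state_rate(81, 30), 2.7)
  expect_equal(steady_state_rate(51, 30), 1.7)
  expect_equal(steady_state_rate(81, 30) * 30, 81)
  expect_error(steady_state_rate(81, 0), "undefined")
})

test_that("fold change is the >= 1 ratio with a direction", {
  fc <- fold_change(129, 10)
  expect_equal(fc$fold, 12.9)
  expect_equal(fc$direction, "decrease")
  fc2 <- fold_change(1.7, 2.7)
  expect_equal(round(fc2$fold, 1), 1.6)
  expect_equal(fc2$direction, "increase")
  fc3 <- fold_change(5, 5)
  expect_equal(fc3$fold, 1)
  expect_equal(fc3$direction, "none")
  expect_error(fold_change(0, 5), "positive")
  # symmetric under swap except direction
  withr::with_seed(7, {
    for (i in 1:20) {
      r <- 10^runif(2, -4, 3)
      expect_equal(fold_change(r[1], r[2])$fold, fold_change(r[2], r[1])$fold)
    }
  })
})

test_that("Morrison quadratic obeys its limits and the printed form", {
  expect_equal(morrison_bound(10, 5, 0), 5)   # stoichiometric limit
  expect_equal(morrison_bound(0, 5, 22), 0)
  expect_equal(morrison_bound(2000, 0, 22), 0)
  # oracle: the quadratic as printed, evaluated directly
  quad <- function(AT, BT, KD) {
    s <- AT + BT + KD
    (s - sqrt(s^2 - 4 * AT * BT)) / 2
  }
  expect_rel_equal(morrison_bound(2000, 5, 22), quad(2000, 5, 22), 1e-10)
  expect_equal(round(morrison_bound(2000, 5, 22), 3), 4.945)
  # weak-binding hyperbolic limit: BT << KD
  expect_rel_equal(morrison_bound(2000, 0.1, 22), 0.1 * 2000 / (2000 + 22),
                   0.01)
  # stable form == printed form across magnitudes, including tiny KD
  withr::with_seed(11, {
    for (i in 1:40) {
      AT <- 10^runif(1, -2, 4)
      BT <- 10^runif(1, -2, 2)
      KD <- 10^runif(1, -8, 3)
      expect_rel_equal(morrison_bound(AT, BT, KD),
                       quad(AT, BT, KD), 1e-7)
    }
  })
})

test_that("Morrison bound is monotone in AT, BT and KD", {
  at <- 10^seq(-1, 3.5, length.out = 30)
  expect_true(all(diff(morrison_bound(at, 5, 22)) >= 0))
  bt <- seq(0, 50, length.out = 30)
  expect_true(all(diff(morrison_bound(100, bt, 22)) >= 0))
  kd <- 10^seq(-3, 3, length.out = 30)
  expect_true(all(diff(morrison_bound(100, 5, kd)) <= 0))
})

test_that("E_FRET is the acceptor share and sums channel-wise", {
  expect_equal(efret(1, 1), 0.5)
  expect_equal(efret(1, 0), 0)
  expect_equal(efret(1, 3), 0.75)
  expect_error(efret(0, 0), "both channels zero")
  expect_equal(predicted_no_interaction_efret(0, 1, 1, 0), 0.5)
  expect_equal(predicted_no_interaction_efret(6, 2, 3, 1), 0.25)
  # identical reads leave the ratio unchanged; general reads: ratio of sums
  withr::with_seed(13, {
    for (i in 1:20) {
      r <- runif(4, 0.01, 10)
      expect_equal(predicted_no_interaction_efret(r[1], r[2], r[3], r[4]),
                   efret(r[1] + r[3], r[2] + r[4]))
      expect_equal(predicted_no_interaction_efret(r[1], r[2], r[1], r[2]),
                   efret(r[1], r[2]))
    }
  })
})

test_that("Gaussian mixture uses the no-half-exponent parameterization", {
  one <- tibble::tibble(a = 100, b = 130, c = 20)
  expect_equal(eval_gaussian_mixture(130, one), 100)
  # at b + c the exponent is exactly -1
  expect_equal(eval_gaussian_mixture(150, one), 100 / exp(1))
  two <- tibble::tibble(a = c(100, 50), b = c(100, 700), c = c(20, 25))
  expect_rel_equal(eval_gaussian_mixture(100, two), 100, 1e-8)
  expect_error(eval_gaussian_mixture(1, two[0, ]), "at least one")
  expect_error(eval_gaussian_mixture(1, tibble::tibble(a = 1, b = 0, c = 0)),
               "invalid component")
})
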