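test_that("hill activation hits its landmark values and bounds", {
  expect_equal(hill_activation(1, K = 1, n = 2, beta = 0), 0.5)
  expect_equal(hill_activation(5, K = 5, n = 3.7, beta = 0.2), 0.7)
  expect_equal(hill_activation(0, K = 2, n = 1, beta = 0.03), 0.03)
  expect_equal(hill_activation(3, K = 1, n = 1, beta = 0), 0.75)
  x <- 10^seq(-3, 3, length.out = 200)
  y <- hill_activation(x, K = 0.7, n = 2, beta = 0.01)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 0.01 & y <= 1.01))
  expect_error(hill_activation(-1, 1, 1, 0), "x must be finite")
  expect_error(hill_activation(NaN, 1, 1, 0), "x must be finite")
})

test_that("hill repression decreases from 1+beta to beta", {
  expect_equal(hill_repression(0, K = 1, n = 2, beta = 0.05), 1.05)
  expect_equal(hill_repression(3, K = 3, n = 4, beta = 0), 0.5)
  expect_equal(hill_repression(1e12, K = 1, n = 1, beta = 0.02), 0.02,
               tolerance = 1e-8)
  x <- 10^seq(-3, 3, length.out = 200)
  y <- hill_repression(x, K = 2, n = 3, beta = 0)
  expect_true(all(diff(y) < 0))
})

test_that("input drive matches its closed-form limits", {
  p <- update_parameters(p_ideal(), K_TFtot = 3, K_IR = 1, n_RA = 1,
                         beta_RA = 0)
  expect_equal(input_drive(2, p), 0.5)
  expect_equal(input_drive(0, p), 0.25)
  p2 <- update_parameters(p, beta_RA = 0.01)
  expect_equal(input_drive(1e9, p2), 1.01, tolerance = 1e-8)
  inputs <- 10^seq(-2, 4, length.out = 100)
  expect_true(all(diff(input_drive(inputs, p)) > 0))
  expect_error(input_drive(-2, p), "input")
})

test_that("self-activation factor respects form and variant", {
  p <- p_hill()
  B <- c(0, 0.5, 20, 100)
  expect_equal(self_activation_factor(B, p),
               hill_activation(B, p$K_BB, p$n_BB, p$beta_BB))
  pl <- p_ideal()
  expect_equal(self_activation_factor(B, pl), B / pl$K_BB + pl$beta_BB)
  pw <- update_parameters(pl, n_BB = 2, self_activation_form = "ideal_power")
  expect_equal(self_activation_factor(B, pw), (B / pw$K_BB)^2 + pw$beta_BB)
  pn <- update_parameters(p, variant = "null_pf", c_pf = 0.37)
  expect_equal(self_activation_factor(B, pn), rep(0.37, 4))
})

test_that("analytic kernel derivatives agree with numerical differentiation", {
  h <- 1e-6
  num_d <- function(f, x) (f(x + h) - f(x - h)) / (2 * h)
  set.seed(11)
  for (i in 1:20) {
    K <- 10^runif(1, -1, 1)
    n <- sample(1:4, 1)
    x <- 10^runif(1, -1, 1)
    expect_equal(rpacirc:::.d_hill_activation(x, K, n),
                 num_d(function(z) hill_activation(z, K, n, 0), x),
                 tolerance = 1e-5)
    expect_equal(rpacirc:::.d_hill_repression(x, K, n),
                 num_d(function(z) hill_repression(z, K, n, 0), x),
                 tolerance = 1e-5)
  }
  p <- p_hill()
  expect_equal(rpacirc:::.d_self_activation(0.8, p),
               num_d(function(z) self_activation_factor(z, p), 0.8),
               tolerance = 1e-5)
})
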