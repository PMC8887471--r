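test_that("the vector field vanishes at the closed-form steady state", {
  p <- p_ideal()
  st <- closed_form_state(p, input = 2)
  expect_equal(unname(st), c(1, 0.25))
  d <- dstate_dt(st, input = 2, p = p)
  expect_lt(max(abs(d)), 1e-9)
  # leak-free origin is invariant
  expect_equal(unname(dstate_dt(c(A = 0, B = 0), 5, p)), c(0, 0))
})

test_that("steady states match the closed form over a 100-fold input range", {
  p <- p_ideal()
  for (input in c(2, 20, 200)) {
    ss <- steady_state(input, p)
    expect_true(ss$converged)
    cf <- closed_form_state(p, input)
    expect_equal(ss$state[["A"]], cf[["A"]], tolerance = 1e-6)
    expect_equal(ss$state[["B"]], cf[["B"]], tolerance = 1e-6)
    expect_equal(ss$state[["A"]], rpa_setpoint(p), tolerance = 1e-6)
  }
})

test_that("ideal-linear steady output depends on alpha2 but not input, alpha1 or K_BA", {
  set.seed(101)
  for (i in 1:20) {
    p <- update_parameters(p_ideal(),
                           alpha2 = 10^runif(1, 0.2, 1),
                           K_BB = 1, gammaB = 1,
                           alpha1 = 10^runif(1, 1.2, 2.5),
                           K_BA = 10^runif(1, -0.5, 0.5),
                           beta_RA = runif(1, 0, 0.02))
    # the B->A leak must stay below the activation the set-point requires,
    # else no positive adapted state exists
    bBA_cap <- p$gammaA * rpa_setpoint(p) / (p$alpha1 * 1.01)
    p <- update_parameters(p, beta_BA = runif(1, 0, 0.5) * bBA_cap)
    A_star <- vapply(c(1, 10, 100), function(inp) {
      ss <- steady_state(inp, p)
      expect_true(ss$converged)
      ss$state[["A"]]
    }, numeric(1))
    # input independence
    expect_lt(diff(range(A_star)) / mean(A_star), 1e-6)
    expect_equal(A_star[1], rpa_setpoint(p), tolerance = 1e-6)
    # strictly increasing in alpha2
    p_up <- update_parameters(p, alpha2 = p$alpha2 * 1.5)
    expect_gt(steady_state(10, p_up)$state[["A"]], A_star[2])
  }
})

test_that("a null step leaves the trajectory at the steady state", {
  p <- p_ideal(leak_free = FALSE)
  ex <- step_experiment(2, 2, seq(0, 10, by = 0.5))
  sim <- simulate_step(ex, p, dense = FALSE)
  y <- trajectory_outputs(sim$stepped)$output
  expect_lt(diff(range(y)) / mean(y), 1e-6)
})

test_that("a step produces a single transient pulse that returns to baseline", {
  p <- p_ideal()
  sim <- simulate_step(ex_default(200), p)
  y <- sim$stepped$data$output
  base <- sim$baseline[["A"]]
  expect_equal(y[length(y)], base, tolerance = 1e-5)
  i_max <- which.max(y)
  expect_gt(y[i_max], base)
  expect_true(i_max > 1 && i_max < length(y))
  # a single excursion above baseline: monotone rise to the peak, and no
  # later re-crossing of the baseline (the return may ring below it)
  expect_true(all(diff(y[1:i_max]) > -1e-10))
  after <- y[i_max:length(y)]
  expect_true(all(after <= y[i_max] + 1e-10))
  # any later ringing above baseline stays small relative to the pulse
  i_back <- i_max + which(after <= base)[1] - 1
  expect_lt(max(y[i_back:length(y)] - base), 0.05 * (y[i_max] - base))
})

test_that("the saturating form tracks the ideal-linear prediction in the weak regime", {
  p <- p_hill(leak_free = TRUE)
  ss <- steady_state(300, p)
  expect_true(ss$converged)
  expect_lt(ss$state[["B"]] / p$K_BB, 0.05)
  expect_lt(abs(ss$state[["A"]] - rpa_setpoint(p)) / rpa_setpoint(p), 0.05)
})

test_that("fixed-point analysis counts and classifies correctly", {
  # monostable reference circuit
  fp <- find_fixed_points(2, p_hill())
  expect_equal(nrow(fp), 1L)
  expect_true(fp$stable)
  # clamped-B cubic-like balance: alpha2 (B^2.3/(1+B^2.3) + 0.01) - B
  pc <- update_parameters(p_hill(), variant = "no_repression", beta_AB = 0,
                          alpha2 = 4, K_BB = 1, n_BB = 2.3, beta_BB = 0.01,
                          self_activation_form = "hill")
  fp3 <- find_fixed_points(2, pc)
  roots <- oracle_fixed_points(2, pc)
  expect_equal(nrow(fp3), 3L)
  expect_equal(fp3$B, roots, tolerance = 1e-8)
  expect_equal(fp3$stable, c(TRUE, FALSE, TRUE))
  # frozen oracle landmarks of the low/high stable states
  expect_equal(fp3$B[1], 0.0429, tolerance = 1e-2)
  expect_equal(fp3$B[3], 3.87, tolerance = 1e-2)
})

test_that("the bistable nonlinear-PF operating point has two stable states", {
  fp <- find_fixed_points(2, bistable_params())
  expect_equal(nrow(fp), 3L)
  expect_equal(sum(fp$stable), 2L)
  expect_equal(sum(!fp$stable), 1L)
})

test_that("fixed points agree with a dense brute-force sign scan", {
  set.seed(202)
  n_checked <- 0
  for (i in 1:50) {
    p <- update_parameters(p_hill(),
                           alpha1 = 10^runif(1, 0, 2.5),
                           alpha2 = 10^runif(1, 0, 2.5),
                           K_BA = 10^runif(1, -1, 1.5),
                           K_AB = 10^runif(1, -1, 1),
                           K_BB = 10^runif(1, -0.5, 1.5),
                           n_BA = sample(1:3, 1), n_AB = sample(1:4, 1),
                           n_BB = sample(c(1, 2.3), 1))
    fp <- suppressWarnings(find_fixed_points(2, p))
    roots <- oracle_fixed_points(2, p)
    expect_equal(nrow(fp), length(roots))
    if (length(roots) > 0) {
      expect_equal(fp$B, roots, tolerance = 1e-8)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 40)
})

test_that("the linear self-activation order is the unique adapting one", {
  sel <- select_self_activation_order(candidates = c(1, 2, 3))
  expect_equal(sel$selected, 1)
  det <- sel$detail
  expect_true(det$responsive[det$n_BB == 1])
  expect_lt(det$spread[det$n_BB == 1], 1e-6)
  # higher orders collapse to the extinct state in the zero-leak weak limit
  expect_false(any(det$responsive[det$n_BB > 1]))
})
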