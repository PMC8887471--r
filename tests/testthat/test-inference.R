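test_that("noiseless Hill curves round-trip through the fitter", {
  doses <- 10^seq(-2, 2, length.out = 8) * 5
  truth <- c(alpha_max = 100, K = 5, n = 1.2, beta = 0.01)
  dr <- dose_response(doses, hill_response(doses, 100, 5, 1.2, 0.01))
  f <- fit_hill(dr, n_starts = 8, seed = 1)
  est <- unlist(f$parameters)
  expect_true(f$converged)
  expect_lt(max(abs(est - truth) / truth), 1e-3)
})

test_that("degenerate dose-response data is rejected, not silently fitted", {
  doses <- 10^seq(-1, 2, length.out = 8)
  expect_error(fit_hill(dose_response(doses, rep(7, 8))), "unidentifiable")
  expect_error(fit_hill(dose_response(doses[1:4], rep(c(1, 5), 2))),
               "5 distinct")
  expect_error(dose_response(c(2, 1, 3), c(1, 2, 3)), "increasing")
})

test_that("Hill coefficients are recovered from noisy triplicate panels", {
  hits <- 0
  for (s in 1:25) {
    pan <- generate_promoter_panel(n_promoters = 1,
                                   noise = noise_model(0.1, 3, seed = s),
                                   doses = 10^seq(-2, 2, length.out = 8))
    truth <- attr(pan[[1]], "truth")
    f <- fit_hill(pan[[1]], n_starts = 6, seed = s)
    if (abs(f$parameters$n - truth$n) <= 0.15) hits <- hits + 1
  }
  expect_gte(hits, 22)
})

test_that("noiseless circuit data round-trips for small free subsets", {
  p <- defaults_v1("ideal_linear")
  ex <- step_experiment(2, 200, seq(0, 24, by = 2))
  tc <- generate_timecourse(ex, p, noise_model(cv = 0, n_reps = 1, seed = 1))
  ds <- list(list(experiment = ex,
                  stepped = tc$stepped[, c("time_h", "output")],
                  control = tc$control[, c("time_h", "output")]))
  for (free in list("alpha2", c("alpha1", "K_AB"))) {
    init <- stats::setNames(lapply(free, function(k) p[[k]] * 1.6), free)
    p_init <- do.call(update_parameters, c(list(p), init))
    f <- fit_circuit(ds, p_init, free = free, n_starts = 3, seed = 3)
    est <- unlist(f$parameters)
    truth <- unlist(unclass(p)[free])
    expect_lt(max(abs(est - truth) / truth), 0.01)
    # the optimum improves on the perturbed start
    expect_true(f$converged)
  }
  expect_error(fit_circuit(ds, p, free = "alpha9"), "alpha9")
  expect_error(fit_circuit(ds, p, free = character(0)), "non-empty")
})

test_that("substituting the fitted alpha2 back is self-consistent", {
  p <- p_ideal()
  ex <- step_experiment(2, 200, seq(0, 36, by = 2))
  pred <- predict_substitution(p, alpha2_new = 4, list(ex), dense = FALSE,
                               rtol = 1e-11, atol = 1e-13)
  r <- adaptation_result(pred[[1]])
  # new adapted plateau at the closed-form set-point, still flat in input
  expect_equal(r$output1, sqrt(3), tolerance = 1e-4)
  expect_lt(r$aerr, 1e-6)
  # identity substitution reproduces the original trajectories
  same <- predict_substitution(p, p$alpha2, list(ex), dense = FALSE)
  base <- simulate_step(ex, p, dense = FALSE)
  expect_equal(trajectory_outputs(same[[1]]$stepped),
               trajectory_outputs(base$stepped))
  # fit on the predicted data recovers the substituted value
  tc <- generate_timecourse(ex, update_parameters(p, alpha2 = 4),
                            noise_model(cv = 0, n_reps = 1, seed = 1))
  ds <- list(list(experiment = ex,
                  stepped = tc$stepped[, c("time_h", "output")],
                  control = tc$control[, c("time_h", "output")]))
  f <- fit_circuit(ds, p, free = "alpha2", n_starts = 3, seed = 5)
  expect_lt(abs(f$parameters$alpha2 - 4) / 4, 0.01)
})

test_that("weakening the buffer promoter lowers the plateau but keeps adaptation", {
  # alpha2 must stay above gammaB*K_BB for an adapted state to exist, so
  # the downward substitution is 2 -> 1.5, not a full halving
  p <- p_ideal()
  pred <- predict_substitution(p, 1.5,
                               list(step_experiment(2, 200,
                                                    seq(0, 36, by = 1))),
                               dense = FALSE, rtol = 1e-11, atol = 1e-13)
  r <- adaptation_result(pred[[1]])
  expect_lt(r$output1, rpa_setpoint(p))
  expect_lt(r$aerr, 1e-6)
})
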