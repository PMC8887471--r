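test_that("dose-response generation is exact at zero noise and seeded", {
  p <- p_ideal(leak_free = FALSE)
  doses <- c(1, 2, 5, 20, 100)
  dr0 <- generate_dose_response(p, doses, noise_model(cv = 0, n_reps = 3))
  expect_equal(dr0$response, attr(dr0, "truth"))
  expect_equal(dr0$sd, rep(0, 5))
  dr1 <- generate_dose_response(p, doses, noise_model(0.1, 3, seed = 4))
  dr2 <- generate_dose_response(p, doses, noise_model(0.1, 3, seed = 4))
  expect_identical(dr1, dr2)
  expect_false(identical(dr1$response,
                         generate_dose_response(p, doses,
                                                noise_model(0.1, 3, 5))$response))
})

test_that("replicate noise is multiplicative with the nominal CV", {
  p <- p_ideal(leak_free = FALSE)
  doses <- 10^seq(-0.5, 2.2, length.out = 50)
  dr <- generate_dose_response(p, doses, noise_model(0.1, 3, seed = 8))
  reps <- attr(dr, "replicates")
  expect_true(all(reps > 0))
  # pooled relative SD close to the nominal cv
  expect_true(mean(dr$sd / dr$response) > 0.05 &&
                mean(dr$sd / dr$response) < 0.15)
  # high-cv noise still yields strictly positive values
  drh <- generate_dose_response(p, c(1, 5, 20, 50, 100),
                                noise_model(cv = 1.5, n_reps = 20, seed = 2))
  expect_true(all(attr(drh, "replicates") > 0))
})

test_that("replicate means converge to the noiseless signal", {
  p <- p_ideal(leak_free = FALSE)
  dr <- generate_dose_response(p, c(2, 20), noise_model(0.2, 1e4, seed = 6))
  rel_err <- abs(dr$response - attr(dr, "truth")) / attr(dr, "truth")
  expect_true(all(rel_err < 3 * 0.2 / sqrt(1e4)))
})

test_that("time-course tables mirror the simulator and share the baseline", {
  p <- p_ideal()
  ex <- ex_default(200)
  tc0 <- generate_timecourse(ex, p, noise_model(cv = 0, n_reps = 1))
  sim <- simulate_step(ex, p, dense = FALSE)
  expect_equal(tc0$stepped$output, trajectory_outputs(sim$stepped)$output)
  expect_equal(tc0$control$output, trajectory_outputs(sim$control)$output)
  expect_equal(tc0$stepped$output[1], tc0$control$output[1])
  expect_error(step_experiment(2, 200, numeric(0)), "t_grid")
  expect_error(step_experiment(2, 200, c(0.5, 1)), "t_grid")
})

test_that("noise propagates through the AErr statistic within bounds", {
  p <- p_ideal()
  ex <- ex_default(200)
  ok <- 0
  for (s in 1:30) {
    tc <- generate_timecourse(ex, p, noise_model(0.05, 3, seed = s))
    aerr <- adaptation_error(
      steady_outputs(trajectory_from_table(tc$stepped, "stepped"),
                     trajectory_from_table(tc$control, "control"))[["output1"]],
      steady_outputs(trajectory_from_table(tc$stepped, "stepped"),
                     trajectory_from_table(tc$control, "control"))[["output2"]])
    if (aerr < 0.15) ok <- ok + 1
  }
  expect_gte(ok, 29)
})

test_that("promoter panels span the activity range exactly", {
  pan <- generate_promoter_panel(noise = noise_model(0.1, 3, seed = 3))
  expect_length(pan, 6)
  tops <- vapply(pan, function(d) attr(d, "truth")$alpha_max, numeric(1))
  expect_equal(max(tops) / min(tops), 150)
  ns <- vapply(pan, function(d) attr(d, "truth")$n, numeric(1))
  expect_true(all(ns >= 1 & ns <= 1.3))
  pan2 <- generate_promoter_panel(noise = noise_model(0.1, 3, seed = 3))
  expect_identical(pan, pan2)
})

test_that("a noiseless unit-coefficient panel is fitted back exactly", {
  pan <- generate_promoter_panel(n_true_range = c(1, 1), n_promoters = 3,
                                 noise = noise_model(cv = 0, n_reps = 1),
                                 doses = 10^seq(-2, 2, length.out = 8))
  for (d in pan) {
    f <- fit_hill(d, n_starts = 4, seed = 2)
    expect_equal(f$parameters$n, 1, tolerance = 1e-5)
  }
})
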