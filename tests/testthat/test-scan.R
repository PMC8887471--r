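test_that("cassette sampling is seeded, bounded and validated", {
  rg <- parameter_ranges(n_samples = 50, seed = 9)
  cs1 <- sample_parameters(rg)
  cs2 <- sample_parameters(rg)
  expect_identical(cs1, cs2)
  expect_length(cs1, 50)
  for (p in cs1) {
    expect_true(p$alpha1 >= 0.1 && p$alpha1 <= 1000)
    expect_true(p$K_AB >= 0.01 && p$K_AB <= 100)
    expect_true(p$beta_BB >= 1e-4 && p$beta_BB <= 0.01)
    expect_true(p$n_AB %in% 1:4)
    expect_identical(p$gammaA, 1)
  }
  expect_error(parameter_ranges(0), "n_samples")
  expect_error(parameter_ranges(10, ranges = list(alpha1 = c(5, 2))),
               "alpha1")
})

test_that("cassette evaluation reproduces the reference behaviours", {
  rec <- evaluate_cassette(p_ideal(),
                           step_experiment(2, 300, seq(0, 24, by = 0.1)))
  expect_true(rec$adapts)
  expect_lt(rec$aerr, 1e-5)
  expect_identical(rec$class, "adapting")
  # constitutive replacement of the self-activation breaks precision
  pn <- as_variant(p_hill(), "null_pf", strength = 1, input = 2)
  rec_n <- evaluate_cassette(pn, step_experiment(2, 300, seq(0, 24, by = 0.1)))
  expect_false(rec_n$adapts)
  expect_gt(rec_n$aerr, 0.1)
})

test_that("removing repression abolishes adaptation entirely", {
  pr <- as_variant(p_hill(), "no_repression")
  ex <- step_experiment(2, 1000, seq(0, 24, by = 0.1))
  sim <- simulate_step(ex, pr, dense = FALSE)
  y <- trajectory_outputs(sim$stepped)$output
  expect_true(all(diff(y) >= -1e-9))
  # the output climbs to a new plateau: responsive, but never adapting
  rec <- evaluate_cassette(pr, ex)
  expect_false(rec$adapts)
  expect_identical(rec$class, "non_adapting")
})

test_that("constitutive-strength damage to precision is monotone", {
  p <- p_hill()
  ex <- step_experiment(2, 300, seq(0, 24, by = 0.1))
  aerrs <- vapply(c(1, 2, 4), function(s) {
    pn <- as_variant(p, "null_pf", strength = s, input = 2)
    evaluate_cassette(pn, ex)$aerr
  }, numeric(1))
  expect_true(all(diff(aerrs) >= 0))
  expect_true(all(aerrs > 0.2))
})

test_that("topology scans are reproducible and conserve cassette counts", {
  rg <- parameter_ranges(n_samples = 12, seed = 31, fixed = list(n_BB = 1))
  s1 <- scan_topology(rg, "full", sens_min = 0.2)
  s2 <- scan_topology(rg, "full", sens_min = 0.2)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$fraction_adapting, s2$fraction_adapting)
  tab <- table(factor(s1$records$class,
                      levels = c("adapting", "non_adapting",
                                 "non_responsive", "failed")))
  expect_equal(sum(tab), s1$n_samples)
  expect_equal(s1$n_adapting, unname(tab[["adapting"]]))
  expect_lte(s1$n_adapting, s1$n_responsive)
  # single-cassette scan
  s_one <- scan_topology(parameter_ranges(1, seed = 2), "full")
  expect_equal(s_one$n_samples, 1L)
  expect_true(s_one$n_adapting %in% c(0L, 1L))
})

test_that("edge sweeps scale the intended interaction and keep pairing", {
  p <- p_hill()
  ex <- step_experiment(2, 300, seq(0, 24, by = 0.2))
  sw <- edge_perturbation_sweep(p, "self_activation", c(1), step = ex)
  ref <- evaluate_cassette(p, ex)
  expect_equal(sw$aerr, ref$aerr)
  expect_error(edge_perturbation_sweep(p, "input_edge", 1), "unknown edge")
  sw2 <- edge_perturbation_sweep(p, "B_to_A", c(0.2, 0.04), step = ex)
  expect_equal(sw2$factor, c(0.2, 0.04))
  expect_gt(sw2$peak_fold[2], sw2$peak_fold[1])
})
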