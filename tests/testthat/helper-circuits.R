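# Shared fixtures for the circuit tests.

# Analytically solvable reference: ideal-linear weak positive feedback.
p_ideal <- function(leak_free = TRUE) defaults_v1("ideal_linear", leak_free)

# Saturating self-activation reference in the robust operating regime.
p_hill <- function(leak_free = FALSE) defaults_v1("hill", leak_free)

# Closed-form steady state of the ideal-linear, zero-B-leak circuit:
# the B balance pins the repression factor at gammaB K_BB / alpha2, the A
# balance then yields B. An independent derivation used as test oracle.
closed_form_state <- function(p, input) {
  h_rep <- p$gammaB * p$K_BB / p$alpha2 - p$beta_AB
  stopifnot(h_rep > 0, h_rep <= 1)
  A <- p$K_AB * (1 / h_rep - 1)^(1 / p$n_AB)
  h_act <- p$gammaA * A / (p$alpha1 * input_drive(input, p)) - p$beta_BA
  stopifnot(h_act > 0, h_act < 1)
  u <- h_act / (1 - h_act)
  B <- p$K_BA * u^(1 / p$n_BA)
  c(A = A, B = B)
}

# Coarse default grid for step experiments in tests.
ex_default <- function(input_final = 200, by = 0.5) {
  step_experiment(2, input_final, seq(0, 24, by = by))
}

# Brute-force fixed-point oracle: dense sign scan of the reduced B residual
# (evaluated through the package kernels, but bracketing/rooting logic is
# independent of find_fixed_points).
oracle_fixed_points <- function(input, p, n_pts = 1e5, B_lo = 1e-6, B_hi = 1e6) {
  g <- function(B) {
    A <- p$alpha1 * input_drive(input, p) *
      hill_activation(B, p$K_BA, p$n_BA, p$beta_BA) / p$gammaA
    rep_fac <- if (p$variant == "no_repression") 1 + p$beta_AB else
      hill_repression(A, p$K_AB, p$n_AB, p$beta_AB)
    p$alpha2 * rep_fac * self_activation_factor(B, p) - p$gammaB * B
  }
  Bg <- exp(seq(log(B_lo * p$K_BB), log(B_hi * p$K_BB), length.out = n_pts))
  gv <- g(Bg)
  idx <- which(sign(gv[-1]) * sign(gv[-n_pts]) < 0)
  sort(vapply(idx, function(i) {
    stats::uniroot(g, c(Bg[i], Bg[i + 1]), tol = 1e-14)$root
  }, numeric(1)))
}
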