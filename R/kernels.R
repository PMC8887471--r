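# Hill regulation kernels. All regulations in the circuit are Hill
# functions, mutually insulated and combined with AND logic (products).

#' Hill activation kernel
#'
#' `x^n / (K^n + x^n) + beta`: saturating activation with basal leak.
#' Strictly increasing in `x`, bounded in `[beta, 1 + beta]`.
#'
#' @param x Regulator concentration (>= 0); vectorised.
#' @param K Half-maximal concentration (> 0).
#' @param n Hill coefficient (>= 1).
#' @param beta Leak (>= 0).
#' @return Dimensionless activation factor(s).
#' @export
hill_activation <- function(x, K, n, beta = 0) {
  .check_kernel_args(x, K, n, beta)
  u <- (x / K)^n
  u / (1 + u) + beta
}

#' Hill repression kernel
#'
#' `1 / (1 + (x/K)^n) + beta`: strictly decreasing in `x`, bounded in
#' `(beta, 1 + beta]`.
#'
#' @inheritParams hill_activation
#' @return Dimensionless repression factor(s).
#' @export
hill_repression <- function(x, K, n, beta = 0) {
  .check_kernel_args(x, K, n, beta)
  1 / (1 + (x / K)^n) + beta
}

.check_kernel_args <- function(x, K, n, beta) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("regulator concentration x must be finite and >= 0", call. = FALSE)
  }
  stopifnot(K > 0, n >= 1, beta >= 0)
}

#' Input drive of node A
#'
#' The inducer acts indirectly: it titrates a constitutive repressor, so the
#' drive on node A is `1 / (1 + (K_TFtot / (1 + input/K_IR))^n_RA) + beta_RA`.
#' Strictly increasing in `input`, from `1/(1 + K_TFtot^n_RA) + beta_RA` at
#' zero inducer to `1 + beta_RA` at saturation.
#'
#' @param input Inducer concentration (uM, >= 0); vectorised.
#' @param p A `circuit_parameters` object.
#' @return Dimensionless drive factor(s).
#' @export
input_drive <- function(input, p) {
  if (any(!is.finite(input)) || any(input < 0)) {
    stop("input concentration must be finite and >= 0", call. = FALSE)
  }
  1 / (1 + (p$K_TFtot / (1 + input / p$K_IR))^p$n_RA) + p$beta_RA
}

#' Buffer-node self-activation factor S(B)
#'
#' Evaluates the variant- and form-dependent self-activation factor:
#' Hill (`hill`), exact linear limit (`ideal_linear`), power-law weak limit
#' (`ideal_power`), or the constitutive constant `c_pf` for the `null_pf`
#' variant.
#'
#' @param B Buffer-node concentration (a.u., >= 0); vectorised.
#' @param p A `circuit_parameters` object.
#' @return Dimensionless factor(s).
#' @export
self_activation_factor <- function(B, p) {
  if (any(!is.finite(B)) || any(B < 0)) {
    stop("B must be finite and >= 0", call. = FALSE)
  }
  if (p$variant == "null_pf") {
    return(rep_len(p$c_pf, length(B)))
  }
  switch(p$self_activation_form,
    hill = hill_activation(B, p$K_BB, p$n_BB, p$beta_BB),
    ideal_linear = B / p$K_BB + p$beta_BB,
    ideal_power = (B / p$K_BB)^p$n_BB + p$beta_BB
  )
}

# Derivatives of the kernels w.r.t. the regulator, used by the Jacobian.

.d_hill_activation <- function(x, K, n) {
  if (x == 0) {
    if (n == 1) return(1 / K)
    return(0)
  }
  u <- (x / K)^n
  (n / x) * u / (1 + u)^2
}

.d_hill_repression <- function(x, K, n) {
  if (x == 0) {
    if (n == 1) return(-1 / K)
    return(0)
  }
  u <- (x / K)^n
  -(n / x) * u / (1 + u)^2
}

.d_self_activation <- function(B, p) {
  if (p$variant == "null_pf") return(0)
  switch(p$self_activation_form,
    hill = .d_hill_activation(B, p$K_BB, p$n_BB),
    ideal_linear = 1 / p$K_BB,
    ideal_power = if (B == 0 && p$n_BB > 1) 0 else
      p$n_BB * (B / p$K_BB)^(p$n_BB - 1) / p$K_BB
  )
}
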