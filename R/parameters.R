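#' @keywords internal
"_PACKAGE"

# Numeric parameter keys of the two-node circuit model, in canonical order.
.param_keys <- c(
  "alpha1", "alpha2", "gammaA", "gammaB",
  "K_TFtot", "K_IR", "n_RA", "beta_RA",
  "K_BA", "n_BA", "beta_BA",
  "K_AB", "n_AB", "beta_AB",
  "K_BB", "n_BB", "beta_BB"
)

.rate_keys <- c("alpha1", "alpha2", "gammaA", "gammaB",
                "K_TFtot", "K_IR", "K_BA", "K_AB", "K_BB")
.hill_keys <- c("n_RA", "n_BA", "n_AB", "n_BB")
.leak_keys <- c("beta_RA", "beta_BA", "beta_AB", "beta_BB")

.sa_forms <- c("hill", "ideal_linear", "ideal_power")
.variants <- c("full", "null_pf", "nonlinear_pf", "no_repression")

#' Circuit parameter set for the two-node RPA model
#'
#' Bundles every rate, affinity, cooperativity and leak constant of the
#' two-node negative-feedback circuit with buffer-node positive feedback,
#' together with the model-form switches. Node A is the output node (sfGFP
#' readout); node B is the buffer node (T7 RNAP-like self-activator).
#'
#' The buffer-node self-activation factor `S(B)` is controlled by
#' `self_activation_form`:
#' \describe{
#'   \item{`hill`}{`B^n_BB / (K_BB^n_BB + B^n_BB) + beta_BB` (saturating).}
#'   \item{`ideal_linear`}{`B / K_BB + beta_BB`, the exact weak-feedback
#'     limit `B << K_BB`; requires `n_BB = 1`.}
#'   \item{`ideal_power`}{`(B / K_BB)^n_BB + beta_BB`, the weak-feedback
#'     limit for arbitrary cooperativity, used when asking which
#'     self-activation order permits perfect adaptation.}
#' }
#'
#' `variant` selects topology disruptions mirroring the wet-lab controls:
#' `null_pf` replaces self-activation by a constitutive factor `c_pf`
#' (promoter swap), `nonlinear_pf` forces a cooperative Hill self-activation
#' with `n_BB = 2.3` (phage activator substitution), and `no_repression`
#' pins the A-to-B repression factor at its unrepressed value `1 + beta_AB`
#' (dCpf1 deletion).
#'
#' @param alpha1,alpha2 Maximum production rates of nodes A and B (a.u./h).
#' @param gammaA,gammaB First-order removal rates of A and B (1/h);
#'   dilution by growth is folded into these.
#' @param K_TFtot Effective repressor-abundance constant of the input drive
#'   (dimensionless).
#' @param K_IR Inducer-repressor half-effect concentration (uM).
#' @param n_RA Input-drive Hill coefficient.
#' @param beta_RA Input-drive leak (>= 0).
#' @param K_BA,n_BA,beta_BA Half-max (a.u.), Hill coefficient and leak of
#'   the B-to-A activation.
#' @param K_AB,n_AB,beta_AB Half-max (a.u.), Hill coefficient and leak of
#'   the A-to-B repression.
#' @param K_BB,n_BB,beta_BB Half-max (a.u.), Hill coefficient and leak of
#'   the B self-activation.
#' @param self_activation_form One of `"hill"`, `"ideal_linear"`,
#'   `"ideal_power"`.
#' @param variant One of `"full"`, `"null_pf"`, `"nonlinear_pf"`,
#'   `"no_repression"`.
#' @param c_pf Constitutive self-activation factor, required for
#'   `variant = "null_pf"` (dimensionless, > 0).
#'
#' @return An object of class `circuit_parameters` (a validated named list).
#' @seealso [defaults_v1()], [scale_edge()], [as_variant()]
#' @export
circuit_parameters <- function(alpha1, alpha2, gammaA, gammaB,
                               K_TFtot, K_IR, n_RA, beta_RA,
                               K_BA, n_BA, beta_BA,
                               K_AB, n_AB, beta_AB,
                               K_BB, n_BB, beta_BB,
                               self_activation_form = c("hill", "ideal_linear",
                                                        "ideal_power"),
                               variant = c("full", "null_pf", "nonlinear_pf",
                                           "no_repression"),
                               c_pf = NULL) {
  self_activation_form <- match.arg(self_activation_form)
  variant <- match.arg(variant)
  p <- list(alpha1 = alpha1, alpha2 = alpha2, gammaA = gammaA, gammaB = gammaB,
            K_TFtot = K_TFtot, K_IR = K_IR, n_RA = n_RA, beta_RA = beta_RA,
            K_BA = K_BA, n_BA = n_BA, beta_BA = beta_BA,
            K_AB = K_AB, n_AB = n_AB, beta_AB = beta_AB,
            K_BB = K_BB, n_BB = n_BB, beta_BB = beta_BB,
            self_activation_form = self_activation_form,
            variant = variant,
            c_pf = c_pf)
  validate_circuit_parameters(p)
}

#' Validate a circuit parameter list
#'
#' Enforces the model invariants: strictly positive rates and half-max
#' constants, non-negative leaks, Hill coefficients >= 1, `n_BB = 1` for the
#' ideal-linear form, a positive `c_pf` for the null-PF variant, and
#' `n_BB = 2.3` for the nonlinear-PF variant.
#'
#' @param p A named list with the fields of [circuit_parameters()].
#' @return The validated `circuit_parameters` object.
#' @export
validate_circuit_parameters <- function(p) {
  stopifnot(is.list(p))
  missing_keys <- setdiff(.param_keys, names(p))
  if (length(missing_keys) > 0L) {
    stop("missing required parameter(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  for (k in .param_keys) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", k, "' must be a single finite number", call. = FALSE)
    }
  }
  for (k in .rate_keys) {
    if (p[[k]] <= 0) {
      stop("parameter '", k, "' must be strictly positive (got ", p[[k]], ")",
           call. = FALSE)
    }
  }
  for (k in .leak_keys) {
    if (p[[k]] < 0) {
      stop("leak '", k, "' must be >= 0 (got ", p[[k]], ")", call. = FALSE)
    }
  }
  for (k in .hill_keys) {
    if (p[[k]] < 1) {
      stop("Hill coefficient '", k, "' must be >= 1 (got ", p[[k]], ")",
           call. = FALSE)
    }
  }
  form <- p$self_activation_form
  if (is.null(form) || !form %in% .sa_forms) {
    stop("self_activation_form must be one of: ", paste(.sa_forms, collapse = ", "),
         call. = FALSE)
  }
  variant <- p$variant
  if (is.null(variant) || !variant %in% .variants) {
    stop("variant must be one of: ", paste(.variants, collapse = ", "),
         call. = FALSE)
  }
  if (form == "ideal_linear" && p$n_BB != 1) {
    stop("ideal_linear self-activation requires n_BB = 1 (got n_BB = ",
         p$n_BB, ")", call. = FALSE)
  }
  if (variant == "null_pf") {
    if (is.null(p$c_pf) || !is.numeric(p$c_pf) || length(p$c_pf) != 1L ||
        !is.finite(p$c_pf) || p$c_pf <= 0) {
      stop("variant 'null_pf' requires a single positive c_pf", call. = FALSE)
    }
  }
  if (variant == "nonlinear_pf") {
    if (p$n_BB != 2.3) {
      stop("variant 'nonlinear_pf' fixes n_BB = 2.3 (got ", p$n_BB, ")",
           call. = FALSE)
    }
    if (form != "hill") {
      stop("variant 'nonlinear_pf' requires the hill self-activation form",
           call. = FALSE)
    }
  }
  known <- c(.param_keys, "self_activation_form", "variant", "c_pf")
  unknown <- setdiff(names(p), known)
  if (length(unknown) > 0L) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- p[known[known %in% names(p)]]
  class(p) <- "circuit_parameters"
  p
}

#' Reference parameter set (defaults v1)
#'
#' The package's reference operating point. Two flavours are provided, one
#' per self-activation form; both sit in the weak-positive-feedback regime
#' that makes near-perfect adaptation possible.
#'
#' For `ideal_linear` (the analytically solvable limit) the set is
#' `alpha1 = 10, alpha2 = 2, gammaA = gammaB = 1, K_TFtot = 3, K_IR = 1,
#' n_RA = 1, K_BA = 1, n_BA = 1, K_AB = 1, n_AB = 2, K_BB = 1, n_BB = 1`;
#' the adapted set-point is `A* = K_AB (alpha2/(gammaB K_BB) - 1)^(1/n_AB) = 1`.
#'
#' For `hill` the saturating self-activation imposes two extra regime
#' conditions that the reference point must respect with headroom: the
#' positive-feedback balance `alpha2 > gammaB * K_BB` (with margin for
#' several-fold downward perturbation of alpha2) and set-point reachability
#' `alpha1 * input_drive * (1 + beta_BA) > gammaA * A*` (with margin for
#' strong downward perturbation of alpha1). In addition the basal leak must
#' stay small relative to the operating self-activation signal
#' (`beta_BB << B*/K_BB`), and a steep repression edge keeps the set-point
#' insensitive to the residual leak coupling. The hill reference therefore
#' uses `alpha1 = 120, alpha2 = 320, K_BA = 30, n_AB = 4, K_BB = 20`
#' (operating point `B*/K_BB ~ 0.04`, inside `B << K_BB`), other constants
#' as above.
#'
#' @param form Self-activation form of the returned set: `"ideal_linear"`
#'   or `"hill"`.
#' @param leak_free If `TRUE` all four leaks are 0 (the idealised limit);
#'   otherwise all leaks are 0.01 (weak basal expression).
#' @return A `circuit_parameters` object.
#' @export
defaults_v1 <- function(form = c("ideal_linear", "hill"), leak_free = FALSE) {
  form <- match.arg(form)
  leak <- if (leak_free) 0 else 0.01
  base <- list(alpha1 = 10, alpha2 = 2, gammaA = 1, gammaB = 1,
               K_TFtot = 3, K_IR = 1, n_RA = 1, beta_RA = leak,
               K_BA = 1, n_BA = 1, beta_BA = leak,
               K_AB = 1, n_AB = 2, beta_AB = leak,
               K_BB = 1, n_BB = 1, beta_BB = leak,
               self_activation_form = form, variant = "full", c_pf = NULL)
  if (form == "hill") {
    base$alpha1 <- 120
    base$alpha2 <- 320
    base$K_BA <- 30
    base$n_AB <- 4
    base$K_BB <- 20
  }
  validate_circuit_parameters(base)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced and the result
#' re-validated. Convenience for perturbation studies.
#'
#' @param p A `circuit_parameters` object.
#' @param ... Named fields to replace (e.g. `alpha2 = 4`).
#' @return A `circuit_parameters` object.
#' @export
update_parameters <- function(p, ...) {
  mods <- list(...)
  if (length(mods) > 0L && (is.null(names(mods)) || any(names(mods) == ""))) {
    stop("all replacement fields must be named", call. = FALSE)
  }
  q <- unclass(p)
  for (nm in names(mods)) q[[nm]] <- mods[[nm]]
  validate_circuit_parameters(q)
}

#' Scale one regulatory edge of the circuit
#'
#' Applies a fold-change to the strength of a single regulatory interaction,
#' mirroring promoter-mutant or gRNA-retargeting perturbations:
#' \describe{
#'   \item{`self_activation`}{scales the buffer-node self-activation
#'     strength, i.e. multiplies `alpha2` (the self-activation factor only
#'     ever enters the dynamics multiplied by `alpha2`).}
#'   \item{`B_to_A`}{scales the B-to-A activation strength, i.e. `alpha1`.}
#'   \item{`A_to_B`}{scales the repression affinity, i.e. multiplies
#'     `K_AB` (a retargeted repressor changes its effective affinity).}
#' }
#'
#' @param p A `circuit_parameters` object.
#' @param edge One of `"self_activation"`, `"B_to_A"`, `"A_to_B"`.
#' @param factor Positive fold-change.
#' @return A `circuit_parameters` object.
#' @export
scale_edge <- function(p, edge, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop("factor must be a single positive number", call. = FALSE)
  }
  switch(edge,
    self_activation = update_parameters(p, alpha2 = p$alpha2 * factor),
    B_to_A = update_parameters(p, alpha1 = p$alpha1 * factor),
    A_to_B = update_parameters(p, K_AB = p$K_AB * factor),
    stop("unknown edge '", edge,
         "'; expected self_activation, B_to_A or A_to_B", call. = FALSE)
  )
}

#' Derive a topology-disruption variant from a full circuit
#'
#' For `null_pf` the constitutive level `c_pf` is expressed as a multiple
#' (`strength`) of the full circuit's self-activation factor at its own
#' operating point under `input`, so constitutive replacements of different
#' strengths are comparable across parameter sets. For `nonlinear_pf` the
#' self-activation becomes a Hill term with `n_BB = 2.3`. `no_repression`
#' only flips the variant flag.
#'
#' @param p A full-variant `circuit_parameters` object.
#' @param variant Target variant.
#' @param strength Constitutive strength multiple for `null_pf` (1 matches
#'   the full circuit's operating-point production exactly).
#' @param input Inducer level (uM) defining the operating point used to
#'   match `c_pf`.
#' @return A `circuit_parameters` object of the requested variant.
#' @export
as_variant <- function(p, variant = c("null_pf", "nonlinear_pf", "no_repression"),
                       strength = 1, input = 2) {
  variant <- match.arg(variant)
  q <- unclass(p)
  if (variant == "null_pf") {
    ss <- steady_state(input, p)
    if (!ss$converged) {
      stop("cannot match c_pf: full-circuit steady state did not converge",
           call. = FALSE)
    }
    s_op <- self_activation_factor(ss$state[["B"]], p)
    q$c_pf <- strength * s_op
  } else if (variant == "nonlinear_pf") {
    q$n_BB <- 2.3
    q$self_activation_form <- "hill"
  }
  q$variant <- variant
  validate_circuit_parameters(q)
}

#' Bistable operating point of the nonlinear-PF variant
#'
#' A cooperative self-activation (`n_BB = 2.3`, the characterized
#' substitute activator) combined with weakened repression admits
#' coexisting low and high buffer-node states. This reference operating
#' point — the hill defaults with `alpha2 = 10`, `K_AB = 10`, `K_BB = 2`
#' under the `nonlinear_pf` variant — sits inside the bistable window
#' located by a fixed-point scan over `K_BB`, and is used by the
#' fixed-point analyses and their tests (two stable states, one saddle,
#' mirroring the two cell populations seen by cytometry).
#'
#' @param leak_free Zero all leaks if `TRUE`.
#' @return A `circuit_parameters` object (`variant = "nonlinear_pf"`).
#' @export
bistable_params <- function(leak_free = FALSE) {
  update_parameters(defaults_v1("hill", leak_free = leak_free),
                    alpha2 = 10, K_AB = 10, K_BB = 2, n_BB = 2.3,
                    variant = "nonlinear_pf")
}

#' @export
print.circuit_parameters <- function(x, ...) {
  cat("Two-node RPA circuit parameters\n")
  cat("  variant:", x$variant,
      "| self-activation form:", x$self_activation_form, "\n")
  vals <- unlist(x[.param_keys])
  cat(paste0("  ", format(names(vals), width = 8), " = ",
             format(vals, digits = 6), collapse = "\n"), "\n")
  if (!is.null(x$c_pf)) cat("  c_pf     =", format(x$c_pf, digits = 6), "\n")
  invisible(x)
}
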