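# Parameter-cassette robustness screen and single-edge perturbation sweeps.

#' Sampling ranges for the robustness screen
#'
#' Defines the log-uniform sampling box for a parameter-cassette screen.
#' Default ranges: production rates `alpha1`, `alpha2` in [0.1, 1000];
#' affinities `K_BA`, `K_AB`, `K_BB` in [0.01, 100]; leaks in
#' [1e-4, 0.01] (weak basal expression); removal rates fixed at 1
#' (time-scale normalisation) and the input-drive constants fixed at the
#' reference values (the input module is the experimental handle, not part
#' of the screened topology). Hill coefficients `n_BA`, `n_AB` are drawn
#' uniformly from the integer grid {1, 2, 3, 4} unless fixed; `n_RA` and
#' `n_BB` are fixed at 1 by default.
#'
#' @param n_samples Number of cassettes (>= 1).
#' @param seed Integer seed.
#' @param ranges Named list of `c(low, high)` bounds overriding the
#'   defaults (log-uniform sampling; `low < high`, both > 0).
#' @param fixed Named list of parameters to hold fixed (overrides ranges).
#' @param hill_grid Integer grid for sampled Hill coefficients.
#' @return An object of class `parameter_ranges`.
#' @export
parameter_ranges <- function(n_samples, seed = 1, ranges = list(),
                             fixed = list(), hill_grid = 1:4) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1) {
    stop("n_samples must be >= 1", call. = FALSE)
  }
  default_ranges <- list(alpha1 = c(0.1, 1000), alpha2 = c(0.1, 1000),
                         K_BA = c(0.01, 100), K_AB = c(0.01, 100),
                         K_BB = c(0.01, 100),
                         beta_RA = c(1e-4, 0.01), beta_BA = c(1e-4, 0.01),
                         beta_AB = c(1e-4, 0.01), beta_BB = c(1e-4, 0.01))
  default_fixed <- list(gammaA = 1, gammaB = 1, K_TFtot = 3, K_IR = 1,
                        n_RA = 1, n_BB = 1)
  rng <- utils::modifyList(default_ranges, ranges)
  fix <- utils::modifyList(default_fixed, fixed)
  rng <- rng[setdiff(names(rng), names(fix))]
  for (nm in names(rng)) {
    b <- rng[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] <= 0 || b[1] >= b[2]) {
      stop("invalid range for '", nm, "': need 0 < low < high", call. = FALSE)
    }
  }
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 ranges = rng, fixed = fix, hill_grid = as.integer(hill_grid)),
            class = "parameter_ranges")
}

# draw one cassette from the current RNG stream
.draw_cassette <- function(ranges) {
  vals <- list(self_activation_form = "hill", variant = "full")
  for (nm in names(ranges$ranges)) {
    b <- ranges$ranges[[nm]]
    vals[[nm]] <- exp(stats::runif(1, log(b[1]), log(b[2])))
  }
  for (nm in intersect(c("n_BA", "n_AB"), setdiff(.hill_keys,
                                                  names(ranges$fixed)))) {
    if (!nm %in% names(ranges$ranges)) {
      vals[[nm]] <- sample(ranges$hill_grid, 1)
    }
  }
  for (nm in names(ranges$fixed)) vals[[nm]] <- ranges$fixed[[nm]]
  # any key still missing falls back to the hill reference set
  ref <- unclass(defaults_v1("hill"))
  for (nm in .param_keys) if (is.null(vals[[nm]])) vals[[nm]] <- ref[[nm]]
  validate_circuit_parameters(vals)
}

#' Sample parameter cassettes
#'
#' Draws `n_samples` complete parameter cassettes, each parameter
#' independently log-uniform within its range (Hill coefficients uniform on
#' the integer grid). Deterministic given the seed. An optional regime
#' filter keeps only cassettes satisfying a predicate, drawing replacements
#' until `n_samples` are accepted (rejection sampling from one seeded
#' stream, capped at `max_tries` draws).
#'
#' @param ranges A [parameter_ranges()] object.
#' @param regime Optional predicate `function(p) TRUE/FALSE` restricting
#'   the accepted cassettes (e.g. [rpa_regime_filter()]).
#' @param max_tries Cap on total draws during rejection sampling.
#' @return A list of `circuit_parameters` cassettes.
#' @export
sample_parameters <- function(ranges, regime = NULL, max_tries = 100 * ranges$n_samples) {
  stopifnot(inherits(ranges, "parameter_ranges"))
  .with_seed(ranges$seed, {
    out <- vector("list", ranges$n_samples)
    accepted <- 0L
    tries <- 0L
    while (accepted < ranges$n_samples) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("rejection sampling exceeded ", max_tries,
             " draws; regime filter too restrictive for the ranges",
             call. = FALSE)
      }
      p <- .draw_cassette(ranges)
      if (!is.null(regime) && !isTRUE(tryCatch(regime(p),
                                               error = function(e) FALSE))) {
        next
      }
      accepted <- accepted + 1L
      out[[accepted]] <- p
    }
    out
  })
}

#' Weak-linear-positive-feedback regime filter
#'
#' Predicate for the restricted analytic screen, formalising the regime in
#' which the ideal-linear analysis applies ("linear weak positive feedback
#' and weak leaked expression", with every regulatory edge operating in its
#' responsive range). At the converged operating point under `input` it
#' requires:
#' \itemize{
#'   \item feedback balance with margin: `alpha2 >= balance_margin * gammaB
#'     * K_BB` (away from the set-point bifurcation at equality);
#'   \item weak self-activation: `B* <= x_max * K_BB`, with the feedback
#'     signal dominating its leak, `B*/K_BB >= leak_margin * beta_BB`;
#'   \item leak-subdominant repression: `beta_AB <= (gammaB K_BB / alpha2)
#'     / leak_margin` (the operating repression factor);
#'   \item a responsive B-to-A edge: `leak_margin * beta_BA <=
#'     H_act(B*) <= h_act_max` (neither leak-dominated nor saturated).
#' }
#'
#' @param p A `circuit_parameters` cassette.
#' @param input Operating inducer level (uM, default 2).
#' @param x_max Maximum allowed `B*/K_BB` (default 0.05).
#' @param leak_margin Minimum ratio of each operating signal to the leak it
#'   competes with (default 10).
#' @param balance_margin Minimum `alpha2 / (gammaB K_BB)` (default 2).
#' @param h_act_max Saturation cap on the operating B-to-A activation
#'   (default 0.8).
#' @return Logical.
#' @export
rpa_regime_filter <- function(p, input = 2, x_max = 0.05, leak_margin = 10,
                              balance_margin = 2, h_act_max = 0.8) {
  if (p$alpha2 < balance_margin * p$gammaB * p$K_BB) return(FALSE)
  if (p$beta_AB * leak_margin > p$gammaB * p$K_BB / p$alpha2) return(FALSE)
  ss <- steady_state(input, p)
  if (!ss$converged) return(FALSE)
  x <- ss$state[["B"]] / p$K_BB
  if (x > x_max || x < leak_margin * p$beta_BB) return(FALSE)
  h_act <- hill_activation(ss$state[["B"]], p$K_BA, p$n_BA, 0)
  h_act >= leak_margin * p$beta_BA && h_act <= h_act_max
}

#' Evaluate one parameter cassette
#'
#' Runs the step simulation, computes the adaptation metrics and assigns
#' the cassette to exactly one outcome class: `"adapting"`,
#' `"non_adapting"` (responsive but imprecise), `"non_responsive"`, or
#' `"failed"` (non-converged integration/pre-equilibration, recorded, never
#' dropped).
#'
#' @param p A `circuit_parameters` cassette.
#' @param step A [step_experiment()].
#' @param sens_min,aerr_max Classification thresholds (see
#'   [classify_adaptation()]).
#' @param tail_n Tail length for `output1`.
#' @return A one-row data frame with the metrics, outcome class and the
#'   cassette's parameters.
#' @export
evaluate_cassette <- function(p, step, sens_min = 0.5, aerr_max = 0.1,
                              tail_n = 3) {
  rec <- tryCatch({
    sim <- simulate_step(step, p, dense = FALSE)
    r <- adaptation_result(sim, tail_n = tail_n, sens_min = sens_min,
                           aerr_max = aerr_max)
    responsive <- r$peak_fold - 1 >= sens_min
    data.frame(output1 = r$output1, output2 = r$output2, aerr = r$aerr,
               peak_fold = r$peak_fold, peak_time = r$peak_time,
               responsive = responsive, adapts = r$adapts,
               class = if (r$adapts) "adapting" else
                 if (responsive) "non_adapting" else "non_responsive",
               stringsAsFactors = FALSE)
  }, error = function(e) {
    data.frame(output1 = NA_real_, output2 = NA_real_, aerr = NA_real_,
               peak_fold = NA_real_, peak_time = NA_real_,
               responsive = FALSE, adapts = FALSE, class = "failed",
               stringsAsFactors = FALSE)
  })
  pars <- as.data.frame(unclass(p)[.param_keys])
  cbind(rec, pars)
}

#' Parameter-cassette robustness screen
#'
#' Samples cassettes, optionally converts each to a topology-disruption
#' variant (with the null-PF constitutive level matched at the cassette's
#' own operating point), evaluates every cassette against the step
#' experiment and aggregates the outcome. Runs with the same seed, ranges
#' and thresholds are bit-identical. If more than `max_failed_frac` of
#' cassettes fail to integrate the scan aborts with a range diagnostic.
#'
#' @param ranges A [parameter_ranges()] object.
#' @param variant `"full"` or a disruption variant applied to every
#'   cassette.
#' @param step The screen's step experiment (default 2 -> 200 uM, 0-24 h
#'   at 0.1 h resolution).
#' @param sens_min,aerr_max Classification thresholds, serialized into the
#'   report.
#' @param regime Optional cassette filter (see [sample_parameters()]).
#' @param null_pf_strength Constitutive strength multiple for
#'   `variant = "null_pf"`.
#' @param max_failed_frac Abort threshold for the failed fraction
#'   (default 0.05).
#' @param cassettes Optional pre-sampled cassette list (from
#'   [sample_parameters()]); lets paired variant scans share one sampling
#'   pass. When supplied, `ranges` only contributes the seed recorded in
#'   the report.
#' @return An object of class `scan_report`: list with `variant`,
#'   `n_samples`, `n_responsive`, `n_adapting`, `fraction_adapting`,
#'   `records` (per-cassette data frame), `sens_min`, `aerr_max`, `seed`.
#' @export
scan_topology <- function(ranges, variant = "full",
                          step = step_experiment(2, 200, seq(0, 24, by = 0.1)),
                          sens_min = 0.5, aerr_max = 0.1, regime = NULL,
                          null_pf_strength = 1, max_failed_frac = 0.05,
                          cassettes = NULL) {
  stopifnot(variant %in% .variants)
  if (is.null(cassettes)) {
    cassettes <- sample_parameters(ranges, regime = regime)
  }
  records <- lapply(cassettes, function(p) {
    q <- if (variant == "full") p else
      tryCatch(as_variant(p, variant, strength = null_pf_strength,
                          input = step$input_initial),
               error = function(e) NULL)
    if (is.null(q)) {
      rec <- evaluate_cassette(p, step, sens_min, aerr_max)
      rec$class <- "failed"
      rec$adapts <- FALSE
      rec$responsive <- FALSE
      return(rec)
    }
    evaluate_cassette(q, step, sens_min, aerr_max)
  })
  records <- do.call(rbind, records)
  n_failed <- sum(records$class == "failed")
  if (n_failed > max_failed_frac * nrow(records)) {
    stop(n_failed, "/", nrow(records), " cassettes failed to integrate; ",
         "sampling ranges likely include non-integrable regimes", call. = FALSE)
  }
  structure(list(variant = variant,
                 n_samples = nrow(records),
                 n_responsive = sum(records$responsive),
                 n_adapting = sum(records$adapts),
                 fraction_adapting = mean(records$adapts),
                 n_failed = n_failed,
                 sens_min = sens_min, aerr_max = aerr_max,
                 seed = ranges$seed,
                 records = records),
            class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf(paste0("Robustness screen [%s]: %d cassettes, %d responsive, ",
                     "%d adapting (fraction %.3f), %d failed\n",
                     "  thresholds: sens_min = %g, aerr_max = %g; seed %d\n"),
              x$variant, x$n_samples, x$n_responsive, x$n_adapting,
              x$fraction_adapting, x$n_failed, x$sens_min, x$aerr_max,
              x$seed))
  invisible(x)
}

#' Single-edge perturbation sweep
#'
#' Scales one regulatory edge by each fold factor (see [scale_edge()]) and
#' evaluates the adaptation of each perturbed circuit under the step
#' experiment.
#'
#' @param p The base `circuit_parameters`.
#' @param edge `"self_activation"`, `"B_to_A"` or `"A_to_B"`.
#' @param fold_factors Positive fold-changes (1 = unperturbed).
#' @param step A [step_experiment()].
#' @param sens_min,aerr_max,tail_n Passed to [evaluate_cassette()].
#' @return A data frame, one row per factor, with `edge`, `factor` and the
#'   cassette metrics.
#' @export
edge_perturbation_sweep <- function(p, edge, fold_factors,
                                    step = step_experiment(2, 300,
                                                           seq(0, 24, by = 0.1)),
                                    sens_min = 0.5, aerr_max = 0.1,
                                    tail_n = 3) {
  stopifnot(all(fold_factors > 0))
  out <- lapply(fold_factors, function(f) {
    q <- scale_edge(p, edge, f)
    rec <- evaluate_cassette(q, step,
                             sens_min = sens_min, aerr_max = aerr_max,
                             tail_n = tail_n)
    cbind(data.frame(edge = edge, factor = f, stringsAsFactors = FALSE), rec)
  })
  do.call(rbind, out)
}
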