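# Parameter inference: Hill dose-response fits, full-circuit time-course
# fits and promoter-substitution prediction.

#' Dose-response data container
#'
#' @param doses Non-negative, strictly increasing inducer/activator levels.
#' @param responses Mean outputs (a.u., > 0).
#' @param sds Optional per-dose standard deviations (a.u.).
#' @param n_reps Replicate count behind each mean.
#' @return An object of class `dose_response` (data frame).
#' @export
dose_response <- function(doses, responses, sds = NULL, n_reps = 1L) {
  stopifnot(length(doses) == length(responses))
  if (any(doses < 0) || any(diff(doses) <= 0)) {
    stop("doses must be non-negative and strictly increasing", call. = FALSE)
  }
  if (!is.null(sds) && length(sds) != length(doses)) {
    stop("sds must match doses in length", call. = FALSE)
  }
  d <- data.frame(dose = as.numeric(doses), response = as.numeric(responses),
                  sd = if (is.null(sds)) NA_real_ else as.numeric(sds),
                  n_reps = as.integer(n_reps))
  class(d) <- c("dose_response", "data.frame")
  d
}

#' Hill activation response model
#'
#' `alpha_max * (x^n / (K^n + x^n) + beta)`: the promoter activation curve
#' used for dose-response fits.
#'
#' @param x Activator/inducer level(s).
#' @param alpha_max Maximal activity (a.u.).
#' @param K Half-maximal level.
#' @param n Hill coefficient.
#' @param beta Relative leak.
#' @return Modelled response(s).
#' @export
hill_response <- function(x, alpha_max, K, n, beta = 0) {
  # fitted curves may have sub-unit cooperativity, unlike the circuit kernels
  stopifnot(alpha_max > 0, K > 0, n > 0, beta >= 0)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("doses must be finite and >= 0", call. = FALSE)
  }
  u <- (x / K)^n
  alpha_max * (u / (1 + u) + beta)
}

# seeded local RNG so callers' RNG state is never disturbed
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

#' Fit a Hill activation curve to dose-response data
#'
#' Least squares of `log10(model)` against `log10(response)` (fluorescence
#' spans decades, so log residuals weight the whole curve evenly), by
#' multi-start Nelder-Mead on transformed parameters. Bounds: `n` in
#' [0.5, 4]; `K` within the dose range scaled by [0.1, 10]; `alpha_max` and
#' `beta` positive. When per-dose standard deviations are available,
#' residuals are weighted by `(response/sd)^2` (the delta-method variance of
#' a log-scale residual).
#'
#' @param data A [dose_response()] object with at least 5 distinct positive
#'   doses spanning the transition region.
#' @param n_starts Number of Nelder-Mead restarts (default 12).
#' @param seed Seed for restart jitter (default 1).
#' @return An object of class `fit_result`: list with `parameters`
#'   (alpha_max, K, n, beta), `loss`, `n_restarts_used`, `converged`,
#'   `covariance_proxy` (per-parameter sd across converged restarts) and
#'   `trace` (best objective per restart).
#' @export
fit_hill <- function(data, n_starts = 12, seed = 1) {
  stopifnot(inherits(data, "dose_response"))
  d <- data[data$dose > 0, , drop = FALSE]
  if (length(unique(d$dose)) < 5) {
    stop("need at least 5 distinct positive doses", call. = FALSE)
  }
  if (any(d$response <= 0)) stop("responses must be positive", call. = FALSE)
  if (max(d$response) / min(d$response) < 2) {
    stop("unidentifiable Hill coefficient: responses vary less than 2-fold",
         call. = FALSE)
  }
  K_lo <- 0.1 * min(d$dose)
  K_hi <- 10 * max(d$dose)
  w <- if (all(is.finite(d$sd)) && all(d$sd > 0)) (d$response / d$sd)^2
       else rep(1, nrow(d))
  w <- w / mean(w)
  ly <- log10(d$response)

  unpack <- function(th) {
    list(alpha_max = exp(th[1]),
         K = exp(log(K_lo) + (log(K_hi) - log(K_lo)) * .inv_logit(th[2])),
         n = 0.5 + 3.5 * .inv_logit(th[3]),
         beta = exp(th[4]))
  }
  obj <- function(th) {
    q <- unpack(th)
    m <- hill_response(d$dose, q$alpha_max, q$K, q$n, q$beta)
    if (any(m <= 0) || any(!is.finite(m))) return(1e10)
    sum(w * (log10(m) - ly)^2)
  }
  # heuristic centre: alpha ~ max response, K ~ dose nearest half-max
  a0 <- max(d$response)
  K0 <- d$dose[which.min(abs(d$response - a0 / 2))]
  K0 <- min(max(K0, K_lo * 1.01), K_hi * 0.99)
  b0 <- max(min(d$response) / a0, 1e-4)
  th0 <- c(log(a0),
           .logit((log(K0) - log(K_lo)) / (log(K_hi) - log(K_lo))),
           .logit((1.2 - 0.5) / 3.5),
           log(b0))
  fits <- .with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      th <- if (i == 1) th0 else th0 + stats::rnorm(4, 0, 0.75)
      stats::optim(th, obj, method = "Nelder-Mead",
                   control = list(maxit = 4000, reltol = 1e-14))
    })
  })
  .assemble_fit(fits, unpack)
}

.assemble_fit <- function(fits, unpack) {
  losses <- vapply(fits, function(f) f$value, numeric(1))
  best <- fits[[which.min(losses)]]
  conv <- vapply(fits, function(f) f$convergence == 0, logical(1))
  pars_all <- do.call(rbind, lapply(fits, function(f) unlist(unpack(f$par))))
  near <- losses <= min(losses) * (1 + 1e-3) + 1e-12
  spread <- apply(pars_all[near, , drop = FALSE], 2, stats::sd)
  structure(list(parameters = unpack(best$par),
                 loss = best$value,
                 n_restarts_used = length(fits),
                 converged = any(conv),
                 covariance_proxy = spread,
                 trace = losses),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit result (", x$n_restarts_used, " restarts, converged: ",
      x$converged, ")\n  loss = ", format(x$loss, digits = 6), "\n", sep = "")
  p <- unlist(x$parameters)
  cat(paste0("  ", format(names(p), width = 10), " = ",
             format(p, digits = 6), collapse = "\n"), "\n")
  invisible(x)
}

#' Fit circuit parameters to step-response time courses
#'
#' Minimises the summed squared residuals of `log10(output)` across all
#' stepped and control series, with the parameters named in `free` varied
#' (log-transformed) and all others held at `p_init`. Optimisation is
#' multi-start Nelder-Mead; restart 1 starts exactly at `p_init`, later
#' restarts jitter the free parameters log-normally. Per-time SDs, when
#' present, weight residuals by `(mean/sd)^2`.
#'
#' @param datasets A list of datasets, each a list with `experiment` (a
#'   [step_experiment()]), `stepped` and `control` (data frames with
#'   `time_h`, `output` and optionally `sd`, on the experiment's grid).
#' @param p_init `circuit_parameters`: initial values and the fixed
#'   parameters.
#' @param free Character vector of parameter names to fit (non-empty,
#'   subset of the numeric parameter keys).
#' @param n_starts Number of restarts (default 20).
#' @param seed Seed for restart jitter.
#' @param jitter_sd Log-scale SD of restart jitter (default 0.3).
#' @return A `fit_result`; `parameters` holds the fitted free parameters,
#'   and `p_fitted` the full updated `circuit_parameters`.
#' @export
fit_circuit <- function(datasets, p_init, free, n_starts = 20, seed = 1,
                        jitter_sd = 0.3) {
  if (length(free) == 0L) stop("free parameter set must be non-empty",
                               call. = FALSE)
  bad <- setdiff(free, .param_keys)
  if (length(bad) > 0L) {
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(length(datasets) >= 1L)
  for (ds in datasets) {
    stopifnot(inherits(ds$experiment, "step_experiment"),
              is.data.frame(ds$stepped), is.data.frame(ds$control))
  }
  th0 <- log(unlist(unclass(p_init)[free]))
  unpack <- function(th) {
    do.call(update_parameters,
            c(list(p_init), as.list(stats::setNames(exp(th), free))))
  }
  resids <- function(p) {
    out <- 0
    for (ds in datasets) {
      sim <- simulate_step(ds$experiment, p, dense = FALSE)
      for (series in c("stepped", "control")) {
        obs <- ds[[series]]
        mod <- trajectory_outputs(sim[[series]])$output
        if (length(mod) != nrow(obs)) {
          stop("simulated grid does not match observed table", call. = FALSE)
        }
        w <- if (!is.null(obs$sd) && all(is.finite(obs$sd)) && all(obs$sd > 0))
          (obs$output / obs$sd)^2 else rep(1, nrow(obs))
        w <- w / mean(w)
        out <- out + sum(w * (log10(pmax(mod, 1e-12)) -
                                log10(pmax(obs$output, 1e-12)))^2)
      }
    }
    out
  }
  obj <- function(th) {
    p <- tryCatch(unpack(th), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    tryCatch(resids(p), error = function(e) 1e10)
  }
  fits <- .with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      th <- if (i == 1) th0 else
        th0 + stats::rnorm(length(th0), 0, jitter_sd)
      if (length(th) == 1L) {
        # simplex degenerates in 1-D; use bounded scalar minimisation on
        # the log scale (+- 5 log units ~ 150-fold either way)
        stats::optim(th, obj, method = "Brent",
                     lower = th0 - 5, upper = th0 + 5,
                     control = list(reltol = 1e-12))
      } else {
        stats::optim(th, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
      }
    })
  })
  unpack_named <- function(th) as.list(stats::setNames(exp(th), free))
  res <- .assemble_fit(fits, unpack_named)
  best <- fits[[which.min(res$trace)]]
  res$p_fitted <- unpack(best$par)
  if (all(res$trace >= 1e10)) {
    stop("all restarts failed; per-restart losses: ",
         paste(format(res$trace, digits = 3), collapse = ", "), call. = FALSE)
  }
  res
}

#' Predict behaviour under buffer-node promoter substitution
#'
#' Replaces only the buffer-node maximal production rate `alpha2` (the
#' promoter strength of the B node) in a fitted parameter set and
#' re-simulates the given step experiments without refitting.
#'
#' @param p_fitted `circuit_parameters` from a previous fit.
#' @param alpha2_new New buffer-node production rate (a.u./h, > 0).
#' @param experiments List of [step_experiment()] objects.
#' @param ... Passed to [simulate_step()].
#' @return A list (one element per experiment) of [simulate_step()] results.
#' @export
predict_substitution <- function(p_fitted, alpha2_new, experiments, ...) {
  stopifnot(alpha2_new > 0)
  p_new <- update_parameters(p_fitted, alpha2 = alpha2_new)
  lapply(experiments, function(ex) simulate_step(ex, p_new, ...))
}
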