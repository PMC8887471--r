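# Synthetic-data generation: cytometry-like dose-response and time-course
# tables with multiplicative log-normal replicate noise.

#' Replicate noise model
#'
#' Multiplicative log-normal noise with a given coefficient of variation,
#' normalised to unit mean (`meanlog = -sdlog^2/2`), mimicking
#' mean-fluorescence error bars that scale with the mean. Three replicates
#' with cv = 0.1 is the package's default emulation of triplicate cytometry
#' means.
#'
#' @param cv Coefficient of variation (>= 0).
#' @param n_reps Replicate count (>= 1).
#' @param seed Integer seed making every generated table reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.1, n_reps = 3, seed = 1) {
  stopifnot(cv >= 0, n_reps >= 1)
  structure(list(cv = cv, n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "noise_model")
}

# n x n_reps matrix of unit-mean log-normal factors
.noise_factors <- function(n, noise) {
  if (noise$cv == 0) return(matrix(1, n, noise$n_reps))
  sdlog <- sqrt(log(1 + noise$cv^2))
  matrix(stats::rlnorm(n * noise$n_reps, meanlog = -sdlog^2 / 2,
                       sdlog = sdlog),
         nrow = n, ncol = noise$n_reps)
}

#' Generate a steady-state dose-response table
#'
#' Computes the noiseless steady-state output at each dose and overlays
#' per-replicate multiplicative noise; returns per-dose mean, SD and the
#' replicate matrix (attribute `"replicates"`), plus the noiseless signal
#' (attribute `"truth"`). Deterministic given the noise model's seed.
#'
#' @param p A `circuit_parameters` object.
#' @param doses Non-negative inducer concentrations (uM), strictly
#'   increasing.
#' @param noise A [noise_model()].
#' @return A [dose_response()] object.
#' @export
generate_dose_response <- function(p, doses, noise = noise_model()) {
  stopifnot(all(doses >= 0))
  truth <- vapply(doses, function(d) {
    ss <- steady_state(d, p)
    if (!ss$converged) {
      stop("steady state did not converge at dose ", d, " uM", call. = FALSE)
    }
    ss$state[["A"]]
  }, numeric(1))
  reps <- .with_seed(noise$seed,
                     truth * .noise_factors(length(doses), noise))
  out <- dose_response(doses,
                       responses = rowMeans(reps),
                       sds = apply(reps, 1, stats::sd),
                       n_reps = noise$n_reps)
  attr(out, "replicates") <- reps
  attr(out, "truth") <- truth
  out
}

#' Generate noisy step-response time-course tables
#'
#' Simulates the step experiment and overlays per-sample replicate noise on
#' both the stepped and the control series; both share the pre-equilibrated
#' baseline. Deterministic given the noise model's seed.
#'
#' @param exp A [step_experiment()].
#' @param p A `circuit_parameters` object.
#' @param noise A [noise_model()].
#' @return A list with `stepped` and `control` data frames (`time_h`,
#'   `output`, `sd`, `n_reps`; replicate matrices in attribute
#'   `"replicates"`, noiseless signal in `"truth"`), plus `experiment`.
#' @export
generate_timecourse <- function(exp, p, noise = noise_model()) {
  sim <- simulate_step(exp, p, dense = FALSE)
  n_t <- length(exp$t_grid)
  tabs <- .with_seed(noise$seed, {
    lapply(c(stepped = "stepped", control = "control"), function(series) {
      truth <- trajectory_outputs(sim[[series]])$output
      reps <- truth * .noise_factors(n_t, noise)
      out <- data.frame(time_h = exp$t_grid,
                        output = rowMeans(reps),
                        sd = apply(reps, 1, stats::sd),
                        n_reps = noise$n_reps)
      attr(out, "replicates") <- reps
      attr(out, "truth") <- truth
      out
    })
  })
  c(tabs, list(experiment = exp))
}

#' Rebuild a trajectory object from a measured-style table
#'
#' Wraps a `time_h`/`output` table (e.g. from [generate_timecourse()] or a
#' trajectory CSV) as a `circuit_trajectory` so the adaptation metrics can
#' be applied to measured data. Node concentrations default to the output.
#'
#' @param tab Data frame with `time_h` and `output` columns.
#' @param series `"stepped"` or `"control"`.
#' @param input_uM Input level of the series (uM).
#' @param experiment Optional [step_experiment()].
#' @return A `circuit_trajectory`.
#' @export
trajectory_from_table <- function(tab, series = "stepped", input_uM = NA_real_,
                                  experiment = NULL) {
  stopifnot(all(c("time_h", "output") %in% names(tab)))
  d <- data.frame(time_h = tab$time_h,
                  A = if ("A" %in% names(tab)) tab$A else tab$output,
                  B = if ("B" %in% names(tab)) tab$B else NA_real_,
                  output = tab$output,
                  sampled = TRUE)
  .make_trajectory(experiment, d, series, input_uM)
}

#' Generate a panel of promoter activation curves
#'
#' Emulates a set of promoter mutants with maximal activities log-spaced
#' over exactly `activity_range_fold` and Hill coefficients drawn uniformly
#' in `n_true_range`, sampled at the given doses with replicate noise.
#' The generating parameters of each panel member are stored in the
#' attribute `"truth"`, making the panel the standard fixture for Hill-fit
#' recovery studies.
#'
#' @param n_true_range Length-2 range for the true Hill coefficient
#'   (default `c(1, 1.3)`).
#' @param activity_range_fold Ratio of strongest to weakest maximal
#'   activity (default 150).
#' @param n_promoters Number of panel members (default 6).
#' @param noise A [noise_model()].
#' @param doses Activator levels (default 9 log-spaced points spanning the
#'   transition around `K_true`).
#' @param K_true Half-maximal activator level shared by the panel
#'   (default 1).
#' @param beta_true Relative leak (default 0.01).
#' @param alpha_top Maximal activity of the strongest member (default 100).
#' @return A list of [dose_response()] objects, each with a `"truth"`
#'   attribute holding `alpha_max`, `K`, `n`, `beta`.
#' @export
generate_promoter_panel <- function(n_true_range = c(1, 1.3),
                                    activity_range_fold = 150,
                                    n_promoters = 6,
                                    noise = noise_model(),
                                    doses = 10^seq(-2, 2, length.out = 9),
                                    K_true = 1, beta_true = 0.01,
                                    alpha_top = 100) {
  stopifnot(n_promoters >= 1, activity_range_fold >= 1,
            length(n_true_range) == 2L, n_true_range[1] <= n_true_range[2])
  alphas <- if (n_promoters == 1) alpha_top else
    alpha_top / activity_range_fold^(seq(1, 0, length.out = n_promoters))
  .with_seed(noise$seed, {
    n_true <- stats::runif(n_promoters, n_true_range[1], n_true_range[2])
    lapply(seq_len(n_promoters), function(i) {
      truth <- list(alpha_max = alphas[i], K = K_true, n = n_true[i],
                    beta = beta_true)
      signal <- hill_response(doses, truth$alpha_max, truth$K, truth$n,
                              truth$beta)
      reps <- signal * .noise_factors(length(doses), noise)
      out <- dose_response(doses, rowMeans(reps),
                           sds = if (noise$n_reps > 1)
                             apply(reps, 1, stats::sd) else NULL,
                           n_reps = noise$n_reps)
      attr(out, "replicates") <- reps
      attr(out, "truth") <- truth
      out
    })
  })
}
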