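# Circuit dynamics: ODE right-hand side, steady states, step-response
# simulation and fixed-point/stability analysis.

#' Time derivative of the circuit state
#'
#' The two-node model:
#' \deqn{dA/dt = \alpha_1 D(I) H^+(B; K_{BA}, n_{BA}, \beta_{BA}) - \gamma_A A}
#' \deqn{dB/dt = \alpha_2 H^-(A; K_{AB}, n_{AB}, \beta_{AB}) S(B) - \gamma_B B}
#' where `D` is the input drive, `H+`/`H-` the Hill activation/repression
#' kernels and `S` the self-activation factor. The `no_repression` variant
#' pins the repression factor at its unrepressed value `1 + beta_AB`.
#'
#' @param state Named numeric vector `c(A = , B = )`, non-negative.
#' @param input Inducer concentration (uM).
#' @param p A `circuit_parameters` object.
#' @return Named numeric vector `c(A = dA/dt, B = dB/dt)` (a.u./h).
#' @export
dstate_dt <- function(state, input, p) {
  A <- state[["A"]]
  B <- state[["B"]]
  if (!is.finite(A) || !is.finite(B) || A < 0 || B < 0) {
    stop("state must be finite and non-negative", call. = FALSE)
  }
  rep_fac <- if (p$variant == "no_repression") 1 + p$beta_AB else
    hill_repression(A, p$K_AB, p$n_AB, p$beta_AB)
  dA <- p$alpha1 * input_drive(input, p) *
    hill_activation(B, p$K_BA, p$n_BA, p$beta_BA) - p$gammaA * A
  dB <- p$alpha2 * rep_fac * self_activation_factor(B, p) - p$gammaB * B
  c(A = dA, B = dB)
}

#' Jacobian of the circuit vector field
#'
#' Analytic 2x2 Jacobian of [dstate_dt()] with respect to `(A, B)`,
#' used for Newton polishing of steady states and for linear stability.
#'
#' @inheritParams dstate_dt
#' @return A 2x2 numeric matrix.
#' @export
circuit_jacobian <- function(state, input, p) {
  A <- state[["A"]]
  B <- state[["B"]]
  d_rep <- if (p$variant == "no_repression") 0 else
    .d_hill_repression(A, p$K_AB, p$n_AB)
  rep_fac <- if (p$variant == "no_repression") 1 + p$beta_AB else
    hill_repression(A, p$K_AB, p$n_AB, p$beta_AB)
  J <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  J["A", "A"] <- -p$gammaA
  J["A", "B"] <- p$alpha1 * input_drive(input, p) *
    .d_hill_activation(B, p$K_BA, p$n_BA)
  J["B", "A"] <- p$alpha2 * d_rep * self_activation_factor(B, p)
  J["B", "B"] <- p$alpha2 * rep_fac * .d_self_activation(B, p) - p$gammaB
  J
}

.rhs_desolve <- function(t, y, parms) {
  # the integrator may probe marginally negative states near an absorbing
  # boundary (B -> 0); evaluate the field on the clamped state
  list(dstate_dt(c(A = max(y[[1]], 0), B = max(y[[2]], 0)),
                 parms$input, parms$p))
}

.default_init <- function(p) {
  eps <- 1e-3 * p$K_BB
  c(A = eps, B = eps)
}

#' Steady state under constant input
#'
#' Integrates the circuit from `init` under constant `input` until the state
#' stops changing, then polishes the point with damped Newton iterations on
#' the analytic Jacobian. Convergence is declared when the max-norm of the
#' derivatives falls below `tol * (gamma * state + 1e-12)` componentwise, or
#' when the relative state change over a `10/gamma`-hour window drops below
#' 1e-8. Non-convergence within `t_max` is flagged, never silent.
#'
#' @param input Inducer concentration (uM).
#' @param p A `circuit_parameters` object.
#' @param init Initial state; default `(eps, eps)` with `eps = 1e-3 K_BB`
#'   (basal expression; B = 0 is absorbing in the leak-free limit).
#' @param tol Relative derivative tolerance for convergence (default 1e-9).
#' @param t_max Maximum integration horizon in hours (default 500).
#' @param rtol,atol Integrator tolerances (defaults 1e-8 / 1e-10).
#' @return A list with `state` (named vector), `converged` (logical),
#'   `residual` (max-norm of derivatives at the returned state) and `t_used`.
#' @export
steady_state <- function(input, p, init = NULL, tol = 1e-9, t_max = 500,
                         rtol = 1e-8, atol = 1e-10) {
  if (is.null(init)) init <- .default_init(p)
  if (any(init < 0) || any(!is.finite(init))) {
    stop("init must be finite and non-negative", call. = FALSE)
  }
  y <- c(A = init[["A"]], B = init[["B"]])
  gam <- c(p$gammaA, p$gammaB)
  chunk <- max(10 / min(gam), 5)
  t_used <- 0
  converged <- FALSE
  while (t_used < t_max) {
    t_step <- min(chunk, t_max - t_used)
    sol <- deSolve::lsoda(y = y, times = c(0, t_step), func = .rhs_desolve,
                          parms = list(input = input, p = p),
                          rtol = rtol, atol = atol)
    y_new <- pmax(c(A = unname(sol[2, "A"]), B = unname(sol[2, "B"])), 0)
    dy <- dstate_dt(y_new, input, p)
    scale <- gam * y_new + 1e-12
    rel_change <- max(abs(y_new - y) / (abs(y_new) + 1e-12))
    y <- y_new
    t_used <- t_used + t_step
    if (all(abs(dy) < tol * scale) || rel_change < 1e-8) {
      converged <- TRUE
      break
    }
  }
  # Newton polishing (damped; reject steps leaving the positive quadrant)
  if (converged) {
    for (i in 1:50) {
      f <- dstate_dt(y, input, p)
      if (all(abs(f) < tol * (gam * y + 1e-12))) break
      J <- circuit_jacobian(y, input, p)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        y_try <- y + lam * step
        if (all(y_try >= 0)) break
        lam <- lam / 2
        if (lam < 1e-6) { y_try <- y; break }
      }
      if (identical(y_try, y)) break
      y <- y_try
    }
  }
  res <- max(abs(dstate_dt(y, input, p)))
  list(state = y, converged = converged, residual = res, t_used = t_used)
}

#' Step experiment definition
#'
#' Pre-equilibration input level, post-switch input level and the sampling
#' grid (hours, starting at 0 = switch moment).
#'
#' @param input_initial Pre-step inducer concentration (uM, >= 0).
#' @param input_final Post-step inducer concentration (uM, >= 0).
#' @param t_grid Strictly increasing sampling times starting at 0.
#' @return An object of class `step_experiment`.
#' @export
step_experiment <- function(input_initial, input_final,
                            t_grid = seq(0, 24, by = 0.5)) {
  stopifnot(is.numeric(input_initial), length(input_initial) == 1L,
            input_initial >= 0, is.finite(input_initial),
            is.numeric(input_final), length(input_final) == 1L,
            input_final >= 0, is.finite(input_final))
  if (length(t_grid) < 1L || t_grid[1] != 0 ||
      (length(t_grid) > 1L && any(diff(t_grid) <= 0))) {
    stop("t_grid must be strictly increasing and start at 0", call. = FALSE)
  }
  structure(list(input_initial = input_initial, input_final = input_final,
                 t_grid = as.numeric(t_grid)),
            class = "step_experiment")
}

.make_trajectory <- function(experiment, data, series, input_uM) {
  stopifnot(all(data$output >= 0 | is.na(data$output)))
  structure(list(experiment = experiment, data = data,
                 series = series, input_uM = input_uM),
            class = "circuit_trajectory")
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  cat("Circuit trajectory [", x$series, "] at input ", x$input_uM,
      " uM: ", sum(x$data$sampled), " sampled / ", nrow(x$data),
      " dense points over ", max(x$data$time_h), " h\n", sep = "")
  invisible(x)
}

#' Output series of a trajectory
#'
#' @param traj A `circuit_trajectory`.
#' @param sampled_only If `TRUE` (default) return only the sampling-grid
#'   points; otherwise the dense integrator output.
#' @return A data frame with columns `time_h`, `A`, `B`, `output`.
#' @export
trajectory_outputs <- function(traj, sampled_only = TRUE) {
  d <- traj$data
  if (sampled_only) d <- d[d$sampled, , drop = FALSE]
  d[, c("time_h", "A", "B", "output")]
}

#' Simulate a step-input experiment
#'
#' Pre-equilibrates the circuit at `input_initial`, then switches to
#' `input_final` at t = 0 and integrates over the sampling grid, recording a
#' dense trajectory for pulse analysis. A control trajectory held at
#' `input_initial` over the same grid is returned alongside, sharing the
#' pre-equilibrated baseline. The reported observable (`output`) is the
#' node-A concentration: at steady state the repression balance pins A, so A
#' is the adapting readout corresponding to the fluorescent reporter.
#'
#' @param exp A [step_experiment()].
#' @param p A `circuit_parameters` object.
#' @param dense If `TRUE` (default) integrate on a refined grid (resolution
#'   `dense_dt`) in addition to the sampling grid, so transient peaks are
#'   resolved; `FALSE` integrates on the sampling grid only (faster, used
#'   inside fitting loops).
#' @param dense_dt Dense-grid resolution in hours (default 0.02).
#' @param rtol,atol Integrator tolerances (defaults 1e-8 / 1e-10; tighten
#'   when asserting sub-1e-6 agreement with closed forms over long
#'   horizons).
#' @return A list with `stepped` and `control` (`circuit_trajectory`
#'   objects), `baseline` (pre-equilibrated state) and `pre_converged`.
#' @export
simulate_step <- function(exp, p, dense = TRUE, dense_dt = 0.02,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(exp, "step_experiment"))
  ss <- steady_state(exp$input_initial, p, rtol = rtol, atol = atol)
  if (!ss$converged) {
    stop("pre-equilibration at input ", exp$input_initial,
         " uM did not converge within t_max", call. = FALSE)
  }
  t_grid <- exp$t_grid
  t_end <- max(t_grid)
  if (dense && t_end > 0) {
    times <- sort(unique(c(t_grid, seq(0, t_end, by = dense_dt))))
  } else {
    times <- t_grid
  }
  run <- function(input) {
    if (length(times) == 1L) {
      states <- matrix(ss$state, nrow = 1,
                       dimnames = list(NULL, c("A", "B")))
    } else {
      sol <- deSolve::lsoda(y = ss$state, times = times, func = .rhs_desolve,
                            parms = list(input = input, p = p),
                            rtol = rtol, atol = atol)
      if (nrow(sol) < length(times)) {
        stop("integrator failed at input ", input, " uM (stopped at t = ",
             max(sol[, "time"]), " h)", call. = FALSE)
      }
      states <- pmax(sol[, c("A", "B"), drop = FALSE], 0)
    }
    data.frame(time_h = times,
               A = states[, "A"], B = states[, "B"],
               output = states[, "A"],
               sampled = times %in% t_grid)
  }
  stepped <- .make_trajectory(exp, run(exp$input_final), "stepped",
                              exp$input_final)
  control <- .make_trajectory(exp, run(exp$input_initial), "control",
                              exp$input_initial)
  list(stepped = stepped, control = control,
       baseline = ss$state, pre_converged = ss$converged)
}

#' Adapted set-point of the ideal-linear circuit
#'
#' In the weak linear positive-feedback limit with zero B-equation leaks
#' (`beta_AB = beta_BB = 0`) and `alpha2 > gammaB * K_BB`, the B balance
#' forces the repression factor to `gammaB K_BB / alpha2` regardless of
#' input, giving the input-independent output
#' `A* = K_AB (alpha2 / (gammaB K_BB) - 1)^(1/n_AB)`.
#'
#' @param p A `circuit_parameters` object.
#' @return The closed-form adapted output `A*` (a.u.).
#' @export
rpa_setpoint <- function(p) {
  r <- p$alpha2 / (p$gammaB * p$K_BB) - 1
  if (r <= 0) {
    stop("no positive set-point: requires alpha2 > gammaB * K_BB", call. = FALSE)
  }
  p$K_AB * r^(1 / p$n_AB)
}

# Reduced steady-state residual in B: A is eliminated through the A-balance
# A(B) = alpha1 D(I) H+(B) / gammaA, leaving g(B) = dB/dt at (A(B), B).
.reduced_residual <- function(B, input, p) {
  A <- p$alpha1 * input_drive(input, p) *
    hill_activation(B, p$K_BA, p$n_BA, p$beta_BA) / p$gammaA
  rep_fac <- if (p$variant == "no_repression") 1 + p$beta_AB else
    hill_repression(A, p$K_AB, p$n_AB, p$beta_AB)
  p$alpha2 * rep_fac * self_activation_factor(B, p) - p$gammaB * B
}

#' Locate all fixed points of the circuit at a constant input
#'
#' Reduces the steady-state problem to one dimension in B (A eliminated via
#' the A-balance), brackets sign changes of the residual on a logarithmic
#' B grid, polishes each bracket with [stats::uniroot()], and classifies
#' stability from the eigenvalues of the analytic Jacobian. When the leak-free
#' origin is an exact fixed point it is included. If an audit of residual
#' signs suggests the grid is too coarse (adjacent roots closer than the
#' grid spacing), the scan is retried once on a refined grid with a warning.
#'
#' @param input Inducer concentration (uM).
#' @param p A `circuit_parameters` object.
#' @param B_lo,B_hi Grid bounds as multiples of `K_BB`
#'   (defaults `1e-6` and `1e6`).
#' @param n_grid Number of logarithmic grid points (default 600).
#' @return A data frame with one row per fixed point: `A`, `B`, `stable`
#'   (logical), `eig_max` (largest real part of the Jacobian eigenvalues).
#' @export
find_fixed_points <- function(input, p, B_lo = 1e-6, B_hi = 1e6,
                              n_grid = 600) {
  scan <- function(n_pts) {
    Bg <- exp(seq(log(B_lo * p$K_BB), log(B_hi * p$K_BB), length.out = n_pts))
    gv <- vapply(Bg, .reduced_residual, numeric(1), input = input, p = p)
    roots <- numeric(0)
    sgn <- sign(gv)
    for (i in seq_len(n_pts - 1L)) {
      if (gv[i] == 0) roots <- c(roots, Bg[i])
      if (sgn[i] * sgn[i + 1L] < 0) {
        r <- stats::uniroot(.reduced_residual, c(Bg[i], Bg[i + 1L]),
                            input = input, p = p, tol = 1e-14)
        roots <- c(roots, r$root)
      }
    }
    if (gv[n_pts] == 0) roots <- c(roots, Bg[n_pts])
    list(roots = roots, B = Bg, g = gv)
  }
  out <- scan(n_grid)
  # Audit: adjacent located roots separated by less than ~2 grid cells hint
  # that an intervening root may have been stepped over; refine once.
  if (length(out$roots) >= 2L) {
    lr <- sort(log(out$roots[out$roots > 0]))
    cell <- (log(B_hi) - log(B_lo) + 2 * log(p$K_BB) + 1e-12) / n_grid
    if (length(lr) >= 2L && min(diff(lr)) < 2 * abs(cell)) {
      warning("fixed-point grid may be too coarse; retrying refined grid")
      out <- scan(n_grid * 10L)
    }
  }
  roots <- sort(unique(out$roots))
  # de-duplicate near-identical roots
  if (length(roots) > 1L) {
    keep <- c(TRUE, diff(roots) / pmax(roots[-1], 1e-300) > 1e-6)
    roots <- roots[keep]
  }
  # leak-free origin
  if (abs(.reduced_residual(0, input, p)) == 0 &&
      p$alpha1 * input_drive(input, p) *
        hill_activation(0, p$K_BA, p$n_BA, p$beta_BA) == 0) {
    roots <- c(0, roots[roots > 0])
  }
  if (length(roots) == 0L) {
    return(data.frame(A = numeric(0), B = numeric(0),
                      stable = logical(0), eig_max = numeric(0)))
  }
  A_of <- function(B) p$alpha1 * input_drive(input, p) *
    hill_activation(B, p$K_BA, p$n_BA, p$beta_BA) / p$gammaA
  res <- lapply(roots, function(B) {
    st <- c(A = A_of(B), B = B)
    ev <- eigen(circuit_jacobian(st, input, p), only.values = TRUE)$values
    data.frame(A = st[["A"]], B = B,
               stable = max(Re(ev)) < 0, eig_max = max(Re(ev)))
  })
  do.call(rbind, res)
}

#' Which self-activation order permits perfect adaptation?
#'
#' In the weak-feedback, zero-leak limit (`ideal_power` form) the circuit's
#' steady-state output is exactly input-independent only for a linear
#' self-activation. This screen evaluates candidate self-activation Hill
#' coefficients, computing the steady state at several inputs for each, and
#' returns the coefficient whose output is both responsive (positive) and
#' input-independent to `rel_tol`. Candidates whose weak-limit circuit
#' collapses to the extinct state (a dead circuit is trivially constant) are
#' rejected.
#'
#' @param candidates Candidate Hill coefficients (default `c(1, 2, 3)`).
#' @param inputs Inducer levels to compare (default `c(2, 20, 200)` uM).
#' @param p Base parameters (leaks are zeroed, form set to `ideal_power`).
#' @param rel_tol Maximum relative spread of steady-state output across
#'   inputs to count as input-independent (default 1e-6).
#' @return A list with `selected` (the passing coefficient, or `NA` if
#'   none) and `detail` (per-candidate data frame with outputs and spread).
#' @export
select_self_activation_order <- function(candidates = c(1, 2, 3),
                                         inputs = c(2, 20, 200),
                                         p = defaults_v1("ideal_linear",
                                                         leak_free = TRUE),
                                         rel_tol = 1e-6) {
  detail <- lapply(candidates, function(n) {
    q <- update_parameters(p, n_BB = n,
                           beta_RA = 0, beta_BA = 0, beta_AB = 0, beta_BB = 0,
                           self_activation_form = "ideal_power")
    outs <- vapply(inputs, function(inp) {
      ss <- steady_state(inp, q)
      if (!ss$converged) return(NA_real_)
      ss$state[["A"]]
    }, numeric(1))
    responsive <- all(is.finite(outs)) && all(outs > 1e-6)
    spread <- if (responsive) (max(outs) - min(outs)) / mean(outs) else NA_real_
    data.frame(n_BB = n, responsive = responsive, spread = spread,
               t(stats::setNames(outs, paste0("A_at_", inputs))))
  })
  detail <- do.call(rbind, detail)
  passing <- detail$n_BB[detail$responsive & !is.na(detail$spread) &
                           detail$spread < rel_tol]
  list(selected = if (length(passing) == 1L) passing else
         if (length(passing) == 0L) NA_real_ else passing,
       detail = detail)
}
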