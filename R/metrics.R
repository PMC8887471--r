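# Adaptation metrics: the AErr statistic, pulse metrics and the binary
# adaptation classification used by the robustness screen.

#' Adaptation error (AErr)
#'
#' `AErr = |Output1 - Output2| / Output1`, where `Output1` is the settled
#' output of the stepped series and `Output2` the steady output of the
#' unswitched control. Zero means perfect adaptation; values can exceed 1.
#'
#' @param output1 Settled output of the stepped series (a.u., > 0).
#' @param output2 Steady output of the control series (a.u., >= 0).
#' @return Dimensionless adaptation error (>= 0).
#' @export
adaptation_error <- function(output1, output2) {
  if (!is.finite(output1) || output1 <= 0) {
    stop("adaptation error undefined: output1 must be > 0", call. = FALSE)
  }
  if (!is.finite(output2) || output2 < 0) {
    stop("output2 must be finite and >= 0", call. = FALSE)
  }
  abs(output1 - output2) / output1
}

#' Steady outputs of a stepped/control trajectory pair
#'
#' `output1` is the mean of the final `tail_n` sampling-grid points of the
#' stepped series (the last unchanged time-course points); `output2` is the
#' mean over all sampling-grid points of the constant-input control.
#'
#' @param stepped,control `circuit_trajectory` objects from
#'   [simulate_step()] (or built from measured tables).
#' @param tail_n Number of final stepped points to average (2 or 3;
#'   default 3).
#' @return Named numeric vector `c(output1 = , output2 = )`.
#' @export
steady_outputs <- function(stepped, control, tail_n = 3) {
  stopifnot(tail_n >= 1)
  y1 <- trajectory_outputs(stepped)$output
  y2 <- trajectory_outputs(control)$output
  if (length(y1) < tail_n) {
    stop("stepped series has fewer than tail_n = ", tail_n, " points",
         call. = FALSE)
  }
  if (length(y2) < 1L) stop("control series is empty", call. = FALSE)
  c(output1 = mean(utils::tail(y1, tail_n)), output2 = mean(y2))
}

#' Pulse metrics of a stepped trajectory
#'
#' Peak of the transient response, located on the dense integrator output
#' (not only the sampling grid), and its fold-change relative to the
#' control baseline.
#'
#' @param stepped A `circuit_trajectory` (stepped series).
#' @param output2 Control baseline output (a.u., > 0).
#' @return Named vector `c(peak_value = , peak_fold = , peak_time = )`.
#' @export
pulse_metrics <- function(stepped, output2) {
  stopifnot(output2 > 0)
  d <- stepped$data
  if (nrow(d) == 0L) stop("empty trajectory", call. = FALSE)
  i <- which.max(d$output)
  c(peak_value = d$output[i],
    peak_fold = d$output[i] / output2,
    peak_time = d$time_h[i])
}

#' Binary adaptation classification
#'
#' A circuit counts as adapting when it both responds (transient peak at
#' least `sens_min` above baseline, in fold-change terms) and settles back
#' (`AErr <= aerr_max`). The thresholds are free screen parameters and are
#' always reported alongside results.
#'
#' @param aerr Adaptation error.
#' @param peak_fold Peak output relative to baseline.
#' @param sens_min Minimum `peak_fold - 1` to count as responsive
#'   (default 0.5).
#' @param aerr_max Maximum AErr to count as adapted (default 0.1).
#' @return Logical.
#' @export
classify_adaptation <- function(aerr, peak_fold, sens_min = 0.5,
                                aerr_max = 0.1) {
  isTRUE(peak_fold - 1 >= sens_min) && isTRUE(aerr <= aerr_max)
}

#' Full adaptation summary of a step simulation
#'
#' Convenience wrapper combining [steady_outputs()], [adaptation_error()],
#' [pulse_metrics()] and [classify_adaptation()] into one record.
#'
#' @param sim Result of [simulate_step()] (list with `stepped`, `control`).
#' @param tail_n Tail length for `output1` (default 3).
#' @param sens_min,aerr_max Classification thresholds.
#' @return An object of class `adaptation_result`: list with `output1`,
#'   `output2`, `aerr`, `peak_value`, `peak_fold`, `peak_time`, `adapts`,
#'   and the thresholds used.
#' @export
adaptation_result <- function(sim, tail_n = 3, sens_min = 0.5,
                              aerr_max = 0.1) {
  so <- steady_outputs(sim$stepped, sim$control, tail_n = tail_n)
  aerr <- adaptation_error(so[["output1"]], so[["output2"]])
  pm <- pulse_metrics(sim$stepped, so[["output2"]])
  structure(list(output1 = so[["output1"]], output2 = so[["output2"]],
                 aerr = aerr,
                 peak_value = pm[["peak_value"]],
                 peak_fold = pm[["peak_fold"]],
                 peak_time = pm[["peak_time"]],
                 adapts = classify_adaptation(aerr, pm[["peak_fold"]],
                                              sens_min, aerr_max),
                 sens_min = sens_min, aerr_max = aerr_max),
            class = "adaptation_result")
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat(sprintf(paste0("Adaptation summary: AErr = %.4g ",
                     "(output1 = %.4g, output2 = %.4g)\n",
                     "  peak %.4g-fold at t = %.2f h; adapts: %s ",
                     "(sens_min = %g, aerr_max = %g)\n"),
              x$aerr, x$output1, x$output2, x$peak_fold, x$peak_time,
              x$adapts, x$sens_min, x$aerr_max))
  invisible(x)
}
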