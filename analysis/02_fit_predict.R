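#!/usr/bin/env Rscript

# Fit-then-predict workflow: generate noisy step-response time courses from
# the reference circuit, fit the key rates back from the data, then predict
# the response after substituting the buffer-node promoter (alpha2 halved /
# doubled around the fitted value) WITHOUT refitting, and quantify the
# adaptation of each predicted circuit.

suppressPackageStartupMessages(library(rpacirc))
dir.create("results", showWarnings = FALSE)
seed <- 202

# two step experiments into different final inputs, as in the wet
# characterisation, constrain the rates jointly
p_true <- defaults_v1("ideal_linear")
ex <- step_experiment(2, 200, seq(0, 24, by = 1))
ex2 <- step_experiment(2, 20, seq(0, 24, by = 1))
tc <- generate_timecourse(ex, p_true, noise_model(cv = 0.1, n_reps = 3,
                                                  seed = seed))
tc2 <- generate_timecourse(ex2, p_true, noise_model(cv = 0.1, n_reps = 3,
                                                    seed = seed + 1))
write_trajectory_csv(list(
  stepped = trajectory_from_table(tc$stepped, "stepped", 200, ex),
  control = trajectory_from_table(tc$control, "control", 2, ex)),
  "results/timecourse_data.csv")

ds <- list(list(experiment = ex,
                stepped = tc$stepped[, c("time_h", "output", "sd")],
                control = tc$control[, c("time_h", "output", "sd")]),
           list(experiment = ex2,
                stepped = tc2$stepped[, c("time_h", "output", "sd")],
                control = tc2$control[, c("time_h", "output", "sd")]))
free <- c("alpha1", "alpha2", "K_AB")
p_init <- update_parameters(p_true, alpha1 = 20, alpha2 = 3, K_AB = 0.5)
fit <- fit_circuit(ds, p_init, free = free, n_starts = 10, seed = seed)

cat("Circuit fit from noisy triplicate time courses (free: ",
    paste(free, collapse = ", "), "):\n", sep = "")
comp <- data.frame(parameter = free,
                   truth = unlist(unclass(p_true)[free]),
                   fitted = unlist(fit$parameters),
                   spread = fit$covariance_proxy)
print(comp, digits = 3, row.names = FALSE)
write.csv(comp, "results/circuit_fit.csv", row.names = FALSE)
write_parameters(fit$p_fitted, "results/fitted_parameters.yaml")
cat(sprintf(paste0("\nIndividual rates trade off in an output-only fit ",
                   "(note the restart spread), but the identifiable\n",
                   "combination - the adapted set-point ",
                   "K_AB (alpha2/(gammaB K_BB) - 1)^(1/n_AB) - is pinned: ",
                   "fitted %.3f vs true %.3f.\n"),
            rpa_setpoint(fit$p_fitted), rpa_setpoint(p_true)))

# promoter substitution: re-simulate with alpha2 scaled, same other values
subs <- c(weaker = 0.75, fitted = 1, stronger = 2)
rows <- lapply(names(subs), function(nm) {
  a2 <- subs[[nm]] * fit$p_fitted$alpha2
  sim <- predict_substitution(fit$p_fitted, a2, list(ex))[[1]]
  r <- adaptation_result(sim)
  data.frame(substitution = nm, alpha2 = a2, output1 = r$output1,
             output2 = r$output2, aerr = r$aerr, peak_fold = r$peak_fold,
             peak_time = r$peak_time)
})
pred <- do.call(rbind, rows)
write.csv(pred, "results/substitution_predictions.csv", row.names = FALSE)
cat("\nPredicted adaptation under buffer-promoter substitution:\n")
print(pred, digits = 3, row.names = FALSE)
cat("\nAll substituted circuits keep small AErr; the adapted plateau",
    "shifts with the promoter strength, as the set-point formula",
    "K_AB (alpha2/(gammaB K_BB) - 1)^(1/n_AB) dictates.\n")
cat("Wrote results/circuit_fit.csv, results/substitution_predictions.csv\n")
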