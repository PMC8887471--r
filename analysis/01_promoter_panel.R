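#!/usr/bin/env Rscript

# Promoter activation panel: generate a six-member panel of activation
# curves spanning a 150-fold activity range (triplicates, cv = 0.1) and fit
# each with the Hill activation model. The fitted coefficients should stay
# near the generating range 1.0-1.3 — the near-linear activation that makes
# the buffer-node positive feedback effectively linear.

suppressPackageStartupMessages(library(rpacirc))
dir.create("results", showWarnings = FALSE)
seed <- 101

panel <- generate_promoter_panel(n_true_range = c(1, 1.3),
                                 activity_range_fold = 150,
                                 n_promoters = 6,
                                 noise = noise_model(cv = 0.1, n_reps = 3,
                                                     seed = seed))

rows <- lapply(seq_along(panel), function(i) {
  truth <- attr(panel[[i]], "truth")
  fit <- fit_hill(panel[[i]], n_starts = 12, seed = seed + i)
  data.frame(promoter = paste0("pm", i),
             alpha_true = truth$alpha_max, alpha_fit = fit$parameters$alpha_max,
             K_true = truth$K, K_fit = fit$parameters$K,
             n_true = truth$n, n_fit = fit$parameters$n,
             beta_fit = fit$parameters$beta,
             loss = fit$loss, converged = fit$converged)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/promoter_panel_fits.csv", row.names = FALSE)

cat("Promoter panel fits (activity range ",
    round(max(tab$alpha_true) / min(tab$alpha_true)), "-fold):\n", sep = "")
print(tab[, c("promoter", "alpha_true", "alpha_fit", "n_true", "n_fit")],
      digits = 3, row.names = FALSE)
cat(sprintf("\nFitted Hill coefficients span %.2f-%.2f (truth drawn in 1.0-1.3); ",
            min(tab$n_fit), max(tab$n_fit)),
    sprintf("max |n_fit - n_true| = %.3f\n", max(abs(tab$n_fit - tab$n_true))))
cat("Wrote results/promoter_panel_fits.csv\n")
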