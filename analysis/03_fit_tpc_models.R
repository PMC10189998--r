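#!/usr/bin/env Rscript
# Step 3 — thermal performance: fit the five TPC families (gaussian,
# modified gaussian, quadratic, weibull, pawar) to speed vs temperature by
# multistart NLS and rank them by AIC.

library(thermoallo)

tab <- read.csv("results/speeds.csv")
tab <- tab[is.finite(tab$speed), ]

cmp <- compare_models(tab$temperature, tab$speed, n_starts = 250, seed = 42)
print(cmp)

write.csv(as.data.frame(cmp)[, c("model", "n_params", "aic", "delta_aic")],
          "results/tpc_model_comparison.csv", row.names = FALSE)

best <- attr(cmp, "fits")[[cmp$model[1]]]
message(sprintf("best model: %s (AIC %.2f); runner-up dAIC %.2f",
                cmp$model[1], cmp$aic[1], cmp$delta_aic[2]))
message("note: these speeds carry a body-mass signal the pure TPC ignores;")
message("step 4 adds the mass power law")
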