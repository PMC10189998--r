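#!/usr/bin/env Rscript
# Step 5 — prediction surfaces from the fitted model: speed vs temperature at
# three body masses (small / average / large: 10, 105, 303 mg) and speed vs
# mass at three temperatures, the two standard views of the combined model.

library(thermoallo)

est <- read.csv("results/allo_fit.csv")
p <- allo_params(a0 = est$estimate[est$parameter == "a0"],
                 b = est$estimate[est$parameter == "b"],
                 E = est$estimate[est$parameter == "E"],
                 E_h = est$estimate[est$parameter == "E_h"],
                 t_opt = est$estimate[est$parameter == "t_opt"])

grid_t <- predict_grid(p, masses = c(10, 105, 303),
                       temperatures = seq(8, 32, by = 0.25))
grid_m <- predict_grid(p, masses = exp(seq(log(10), log(303), length.out = 60)),
                       temperatures = c(12, 20, 28))

write.csv(as.data.frame(grid_t), "results/prediction_speed_vs_temperature.csv",
          row.names = FALSE)
write.csv(as.data.frame(grid_m), "results/prediction_speed_vs_mass.csv",
          row.names = FALSE)

t_peak <- grid_t$temperatures[apply(grid_t$speeds, 1, which.max)]
message(sprintf("peak speed temperature: %.2f degC at every mass (t_opt = %.2f)",
                t_peak[1], p[["t_opt"]]))
message(sprintf("10-fold mass increase multiplies speed by %.3f (= 10^b)",
                10^p[["b"]]))
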