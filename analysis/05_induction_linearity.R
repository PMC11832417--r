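#!/usr/bin/env Rscript
# Cell-to-cell induction variability and the linearity diagnostic.
#
# When the per-cell methylation rate is much faster than the induction rate
# (exponential delays, 80-min half-time), the population median ORF
# methylation tracks the induced-cell fraction linearly; when per-cell
# kinetics is slow, the linearity breaks. Both regimes are simulated at
# 2,000 cells over five replicates each.

suppressMessages(library(chromflux))
dir.create("results", showWarnings = FALSE)

run <- function(k, seed) {
  sites <- synthetic_sites(60, classes = "ORF", gap = 450)
  ms <- simulate_states(sites, "in_vivo", c(0, 30, 60, 120, 240),
                        n_cells = 2000, rate = k, f0 = 0, half_time = 80,
                        sigma_cell = 0.5, seed = seed)
  med <- apply(realized_fractions(ms), 2, stats::median)
  fit <- induction_linearity(med, induced_fraction(ms))
  data.frame(rate_per_min = k, seed = seed, slope = fit$slope,
             r_squared = fit$r_squared)
}

res <- do.call(rbind, c(lapply(5001:5005, function(sd) run(0.1, sd)),
                        lapply(5001:5005, function(sd) run(0.002, sd))))
utils::write.table(res, "results/induction_linearity.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

fast <- res$r_squared[res$rate_per_min == 0.1]
slow <- res$r_squared[res$rate_per_min == 0.002]
cat("fast per-cell kinetics (k = 0.1/min):  r^2 =",
    paste(round(fast, 4), collapse = ", "), "\n")
cat("slow per-cell kinetics (k = 0.002/min): r^2 =",
    paste(round(slow, 4), collapse = ", "), "\n")
cat("minimum fast r^2:", round(min(fast), 4),
    "(linearity diagnostic r^2 > 0.97)\n")
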