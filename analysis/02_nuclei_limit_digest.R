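#!/usr/bin/env Rscript
# Static-chromatin (nuclei) titration and limit-digest analysis.
#
# Simulates the enzyme titration (0, 0.77, 1.5, 2.9, 5.6 nM) on the site
# census with class-dependent accessible fractions (promoter NDR sites
# accessible in 70% of nuclei, ORF sites in 30%), runs the full fragment
# pipeline (DpnI cutting, sonication, recovery loss, terminal-base removal,
# end counting with the A+G / T+C correction and the 200-bp neighbor
# policy), and fits the limit-digest plateau per region class.
#
# The titration is run twice: once with the short-fragment recovery ramp
# active and once with it disabled. Fragments that end at a cut site are
# shorter on average than fragments that span it, so length-dependent
# recovery depletes the fcut numerator more than its denominator and
# attenuates the fitted plateaus; with recovery disabled the plateaus match
# the generating accessible fractions.

suppressMessages(library(chromflux))

sites <- utils::read.table("results/sites.tsv", header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
cs <- utils::read.table("results/chrom_sizes.tsv", header = TRUE, sep = "\t")
chrom_sizes <- stats::setNames(cs$length, cs$chrom)

conc <- c(0, 0.77, 1.5, 2.9, 5.6)
plateaus <- c(ORF = 0.30, NDR = 0.70, tRNA = 0.75, ARS = 0.35, TEL = 0.30,
              Ty = 0.30, CEN = 0.05, silenced = 0.10, other = 0.40)
n_cells <- 200

ms <- simulate_states(sites, "nuclei", design = conc, n_cells = n_cells,
                      plateau = plateaus, c0 = 0.5, f0 = 0, seed = 2001)

run_titration <- function(frag, tag, frag_seed) {
  frags <- fragmentize(ms, chrom_sizes, frag, seed = frag_seed)
  fcut_list <- lapply(seq_along(conc), function(i) {
    compute_fcut(sites, frags[frags$point == i, c("chrom", "start", "end")],
                 chrom_sizes)
  })
  names(fcut_list) <- paste0("nM_", conc)
  series <- group_series(fcut_list, conc, sites, axis = "conc_nM")
  fits <- do.call(rbind, lapply(unique(series$group), function(g) {
    s <- series[series$group == g, ]
    pf <- fit_plateau(s$conc_nM, s$median_fcut)
    data.frame(recovery = tag, group = g, f_max = pf$f_max, c0 = pf$c0,
               f_bg = pf$f_bg, method = pf$method, truth = plateaus[[g]],
               n_sites = s$n_sites[1])
  }))
  list(frags = frags, fcut_list = fcut_list, series = series, fits = fits)
}

with_ramp <- run_titration(frag_params(350, 100, 300, 0.3), "ramp_100_300",
                           frag_seed = 2002)
no_ramp <- run_titration(frag_params(350, 0, 0, 0.3), "disabled",
                         frag_seed = 2003)

series <- rbind(cbind(recovery = "ramp_100_300", with_ramp$series),
                cbind(recovery = "disabled", no_ramp$series))
fits <- rbind(with_ramp$fits, no_ramp$fits)
utils::write.table(series, "results/nuclei_series.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(fcut_table(with_ramp$fcut_list), "results/nuclei_fcut.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(fits, "results/plateau_fits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("fragments simulated:", nrow(with_ramp$frags), "(ramp) /",
    nrow(no_ramp$frags), "(no ramp) at", n_cells, "cells x", length(conc),
    "concentrations\n")
cat("status mix at the top concentration:\n")
print(table(with_ramp$fcut_list[[length(conc)]]$status))
cat("\nlimit-digest plateaus (fitted vs generating):\n")
wide <- merge(with_ramp$fits[, c("group", "f_max", "truth", "n_sites")],
              no_ramp$fits[, c("group", "f_max")], by = "group",
              suffixes = c("_ramp", "_noramp"))
print(wide[order(-wide$truth),
           c("group", "truth", "f_max_noramp", "f_max_ramp", "n_sites")],
      row.names = FALSE, digits = 3)
cat("\nLength-biased recovery of cut-end fragments attenuates the fitted\n")
cat("plateaus; with recovery disabled the generating fractions are",
    "recovered.\n")
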