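#!/usr/bin/env Rscript
# Nucleosome phasing: dyad-aligned profiles, anti-phase with occupancy,
# remodeler-depletion phenotypes.
#
# Simulates phased arrays (150 genes, CG-density sites, +1 nucleosome
# sharply positioned, downstream jitter growing along the array), builds
# dyad-aligned methylation profiles, and quantifies: (i) anti-phase between
# methylation and nucleosome occupancy; (ii) recovery of a 24-bp
# promoter-ward array shift (the RSC-depletion phenotype); (iii) the decay
# of the downstream disorder index as downstream jitter grows (the
# Isw1/Chd1-depletion phenotype).

suppressMessages(library(chromflux))
dir.create("results", showWarnings = FALSE)

n_genes <- 150
chrom_sizes <- c(chrP = 3000 * (n_genes + 1))
genes <- synthetic_gene_layout(chrom_sizes, pitch = 3000, first_dyad = 2500,
                               strands = "+", seed = 4001)
genome <- synthetic_genome(chrom_sizes, seed = 4002)
sites <- scan_motif_sites(genome, "CG")
pairs <- map_sites_to_genes(sites, genes)
jitter <- c(8, 15, 22, 30, 38)

profile_for <- function(p_open, seed) {
  ms <- simulate_states(sites, "nuclei", design = 10, n_cells = 400,
                        plateau = 0.05 + 0.85 * p_open, c0 = 0.5, seed = seed)
  smooth_profile(dyad_profile(truth_as_fcut(ms)[[1]], pairs,
                              offsets = -300:1000, min_n = 5))
}

p_open <- positional_accessibility(sites, genes, jitter_sd = jitter)
prof <- profile_for(p_open, seed = 4003)
dy <- dyad_density_counts(n_genes, n_draws = 40, jitter_sd = jitter,
                          seed = 4004)
dens <- normalize_density(dy)
occ <- normalize_density(occupancy_track(dy))
r_dyad <- antiphase_score(prof, dens)
r_occ <- antiphase_score(prof, occ)

out <- merge(prof, dens, by = "offset", all.x = TRUE)
out <- merge(out, stats::setNames(occ, c("offset", "occupancy")),
             by = "offset", all.x = TRUE)
utils::write.table(out, "results/phasing_profile.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# RSC-depletion phenotype: whole-array 24-bp promoter-ward shift
genes_b <- genes
genes_b$plus_one_dyad <- genes_b$plus_one_dyad - 24L
prof_b <- profile_for(positional_accessibility(sites, genes_b,
                                               jitter_sd = jitter),
                      seed = 4005)
shift_xcorr <- estimate_shift(prof, prof_b)
shift_p1 <- plus_one_shift(prof, prof_b, band = c(-130, 110))

# Isw1/Chd1-depletion phenotype: downstream jitter sweep
sweep <- vapply(c(5, 15, 30, 60), function(s) {
  po <- positional_accessibility(sites, genes, jitter_sd = c(5, rep(s, 4)))
  disorder_index(profile_for(po, seed = 4006))
}, numeric(1))

metrics <- data.frame(
  metric = c("antiphase_r_vs_dyad_density", "antiphase_r_vs_occupancy",
             "array_shift_bp_xcorr", "plus_one_shift_bp_centroid",
             paste0("disorder_index_jitter_", c(5, 15, 30, 60))),
  value = c(r_dyad, r_occ, shift_xcorr, shift_p1, sweep))
utils::write.table(metrics, "results/phasing_metrics.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("anti-phase correlation, methylation vs dyad density:",
    round(r_dyad, 3), "\n")
cat("anti-phase correlation, methylation vs occupancy:", round(r_occ, 3),
    "\n")
cat("imposed 24-bp promoter-ward dyad shift recovered at:", shift_xcorr,
    "bp (cross-correlation),", round(shift_p1, 1), "bp (+1 centroid)\n")
cat("disorder index across downstream jitter 5/15/30/60 bp:",
    paste(round(sweep, 3), collapse = " > "), "\n")
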