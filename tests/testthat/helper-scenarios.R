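# Shared fixtures: built in code, seeded, reused across test files.

# Brute-force fcut oracle: per-fragment enumeration, independent of the
# difference-array implementation.
oracle_site_fcut <- function(sites, frags) {
  t(vapply(seq_len(nrow(sites)), function(i) {
    s <- sites$start[i]
    f <- frags[frags$chrom == sites$chrom[i], , drop = FALSE]
    cov_g <- sum(f$start <= s & f$end > s)
    cov_c <- sum(f$start <= s + 3 & f$end > s + 3)
    n_right <- sum(f$end %in% c(s + 1, s + 2) & f$start <= s)
    n_left <- sum(f$start %in% c(s + 2, s + 3) & f$end > s + 3)
    c(fcut_right = if (cov_g > 0) n_right / cov_g else NA_real_,
      fcut_left = if (cov_c > 0) n_left / cov_c else NA_real_)
  }, c(fcut_right = 0, fcut_left = 0)))
}

random_chrom <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Phased-chromatin scenario: 150 regularly spaced genes, CG-density sites,
# nucleosome arrays with sharply positioned +1 and increasing downstream
# jitter (built once, cached).
phased_scenario <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    n_genes <- 150
    chrom_sizes <- c(chrP = 3000 * (n_genes + 1))
    genes <- synthetic_gene_layout(chrom_sizes, pitch = 3000,
                                   first_dyad = 2500, strands = "+",
                                   seed = 4101)
    genome <- synthetic_genome(chrom_sizes, seed = 4102)
    sites <- scan_motif_sites(genome, "CG")
    pairs <- map_sites_to_genes(sites, genes)
    jitter <- c(8, 15, 22, 30, 38)
    p_open <- positional_accessibility(sites, genes, jitter_sd = jitter)
    cache <<- list(n_genes = n_genes, chrom_sizes = chrom_sizes,
                   genes = genes, sites = sites, pairs = pairs,
                   jitter = jitter, p_open = p_open)
    cache
  }
})

# Dyad-aligned methylation profile from a nuclei-mode simulation over a
# per-site accessibility vector.
phased_profile <- function(sc, p_open, seed, n_cells = 400) {
  p_site <- 0.05 + 0.85 * p_open
  ms <- simulate_states(sc$sites, "nuclei", design = 10, n_cells = n_cells,
                        plateau = p_site, c0 = 0.5, seed = seed)
  smooth_profile(dyad_profile(truth_as_fcut(ms)[[1]], sc$pairs,
                              offsets = -300:1000, min_n = 5))
}

# A genome whose only CG sites sit at a regular, group-proof spacing.
spaced_cg_genome <- function(n_sites = 50, gap = 25, pad = 100) {
  unit <- paste0("CG", paste(rep("A", gap - 2), collapse = ""))
  seq <- paste0(paste(rep("T", pad), collapse = ""),
                paste(rep(unit, n_sites), collapse = ""),
                paste(rep("T", pad), collapse = ""))
  c(chrL = seq)
}
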