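# Scenario builders: synthetic genomes, gene layouts, region annotations and
# positional (nucleosome-derived) accessibility, used to construct
# ground-truthed study conditions for the simulator.

#' Generate a random synthetic genome
#'
#' Uniform-composition chromosomes at a given GC content (yeast-like 0.38 by
#' default); at that composition GATC occurs about every 300 bp and CG about
#' every 14 bp, comparable to the real site densities probed by Dam and
#' M.SssI.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param gc GC fraction.
#' @param seed Integer seed.
#' @return \code{DNAStringSet}.
#' @export
synthetic_genome <- function(chrom_sizes, gc = 0.38, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(chrom_sizes, function(n) {
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

#' Lay out regularly spaced genes with +1 dyads
#'
#' Genes are placed at a fixed pitch along each chromosome, alternating
#' strand, each with a +1 nucleosome dyad and a log-normal RNA polymerase II
#' signal.
#'
#' @param chrom_sizes Named chromosome lengths.
#' @param pitch Distance between consecutive gene dyads (bp).
#' @param first_dyad Position of the first +1 dyad on each chromosome.
#' @param margin Unused space kept at each chromosome end.
#' @param strands Strand pattern recycled over genes.
#' @param seed Integer seed (for the polII signal draw).
#' @return data.frame \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{plus_one_dyad}, \code{polII_signal}.
#' @export
synthetic_gene_layout <- function(chrom_sizes, pitch = 3000, first_dyad = 2500,
                                  margin = 2500, strands = c("+", "-"),
                                  seed) {
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  rows <- list()
  gi <- 0L
  for (chr in names(chrom_sizes)) {
    dyads <- seq(first_dyad, chrom_sizes[[chr]] - margin, by = pitch)
    if (!length(dyads)) next
    ids <- sprintf("g%04d", gi + seq_along(dyads))
    gi <- gi + length(dyads)
    rows[[chr]] <- data.frame(
      gene_id = ids, chrom = chr,
      strand = rep_len(strands, length(dyads)),
      plus_one_dyad = as.integer(dyads),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$polII_signal <- stats::rlnorm(nrow(out), meanlog = 4, sdlog = 1)
  out
}

#' Build region annotations around a synthetic gene layout
#'
#' Each gene gets an ORF body downstream of its +1 dyad and a promoter NDR
#' just upstream; the remaining inter-gene space hosts a rotating extra
#' class (tRNA, ARS, Ty, silenced). Telomeric intervals cap the chromosome
#' ends and one centromere sits mid-chromosome.
#'
#' @param genes Gene layout from \code{\link{synthetic_gene_layout}}.
#' @param chrom_sizes Named chromosome lengths.
#' @param orf_len ORF length downstream of the dyad (bp).
#' @param ndr_width Promoter NDR width (bp), ending 20 bp upstream of the
#'   dyad.
#' @param tel_len Telomeric interval length at each chromosome end.
#' @param cen_len Centromere length.
#' @param extra_classes Classes rotated through inter-gene gaps (set to
#'   \code{character(0)} for none).
#' @param extra_len Interval length per extra class.
#' @return Region data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{class}).
#' @export
synthetic_regions <- function(genes, chrom_sizes, orf_len = 1400,
                              ndr_width = 140, tel_len = 1500, cen_len = 400,
                              extra_classes = c("tRNA", "ARS", "Ty", "silenced"),
                              extra_len = c(300, 300, 600, 600)) {
  plus <- genes$strand == "+"
  orf <- data.frame(
    chrom = genes$chrom,
    start = ifelse(plus, genes$plus_one_dyad, genes$plus_one_dyad - orf_len),
    end = ifelse(plus, genes$plus_one_dyad + orf_len, genes$plus_one_dyad),
    class = "ORF", stringsAsFactors = FALSE)
  ndr <- data.frame(
    chrom = genes$chrom,
    start = ifelse(plus, genes$plus_one_dyad - 20 - ndr_width,
                   genes$plus_one_dyad + 20),
    end = ifelse(plus, genes$plus_one_dyad - 20,
                 genes$plus_one_dyad + 20 + ndr_width),
    class = "NDR", stringsAsFactors = FALSE)
  out <- rbind(orf, ndr)
  if (length(extra_classes)) {
    extra_len <- rep_len(extra_len, length(extra_classes))
    for (chr in unique(genes$chrom)) {
      g <- genes[genes$chrom == chr, ]
      g <- g[order(g$plus_one_dyad), ]
      if (nrow(g) < 2) next
      for (j in seq_len(nrow(g) - 1)) {
        cls_i <- ((j - 1) %% length(extra_classes)) + 1
        lo <- max(g$plus_one_dyad[j], g$plus_one_dyad[j] +
                    if (g$strand[j] == "+") orf_len else 0) + 100
        hi <- lo + extra_len[cls_i]
        nxt <- g$plus_one_dyad[j + 1] -
          (if (g$strand[j + 1] == "+") ndr_width + 40 else -0) - 50
        if (hi <= nxt)
          out <- rbind(out, data.frame(chrom = chr, start = lo, end = hi,
                                       class = extra_classes[cls_i],
                                       stringsAsFactors = FALSE))
      }
    }
  }
  for (chr in names(chrom_sizes)) {
    n <- chrom_sizes[[chr]]
    out <- rbind(out,
                 data.frame(chrom = chr, start = c(0, n - tel_len),
                            end = c(tel_len, n), class = "TEL",
                            stringsAsFactors = FALSE),
                 data.frame(chrom = chr, start = n %/% 2,
                            end = n %/% 2 + cen_len, class = "CEN",
                            stringsAsFactors = FALSE))
  }
  out$start <- as.integer(pmax(out$start, 0))
  out$end <- as.integer(pmin(out$end, chrom_sizes[out$chrom]))
  rownames(out) <- NULL
  out
}

#' Construct a site table directly (no genome sequence)
#'
#' Convenience for kinetics scenarios where only site classes matter:
#' regularly spaced sites on one chromosome with the requested class
#' composition.
#'
#' @param n_per_class Sites per class.
#' @param classes Region classes.
#' @param gap Spacing between site midpoints (bp); keep >= 400 so the
#'   neighbor policy never triggers.
#' @param chrom Chromosome name.
#' @param motif Motif string (controls the midpoint offset).
#' @param first Position of the first site.
#' @return Site table with \code{region_class} and neighbor gaps.
#' @export
synthetic_sites <- function(n_per_class, classes = REGION_CLASSES, gap = 400,
                            chrom = "chrS", motif = "GATC", first = 1000) {
  n <- n_per_class * length(classes)
  start <- as.integer(first + gap * (seq_len(n) - 1))
  sites <- data.frame(chrom = chrom, start = start, motif = motif,
                      midpoint = start + nchar(motif) %/% 2L,
                      region_class = rep(classes, each = n_per_class),
                      stringsAsFactors = FALSE)
  len <- max(start) + first + nchar(motif)
  neighbor_gaps(sites, stats::setNames(len, chrom))
}

#' Nucleosome-derived per-site open probability
#'
#' For each gene, nucleosomes sit at the +1 dyad and at multiples of
#' \code{spacing} downstream (strand-corrected), each jittered from cell to
#' cell by a Gaussian of sd \code{jitter_sd[j]}. A site is open in a cell
#' when no nucleosome covers it; the returned probability is the exact
#' product over nucleosomes of their non-coverage probabilities. Feed it to
#' \code{\link{simulate_states}} as a per-site \code{plateau} (or scale it
#' into per-site rates) to simulate phased chromatin.
#'
#' @param sites Site table (\code{chrom}, \code{midpoint}).
#' @param genes Gene layout (\code{chrom}, \code{strand},
#'   \code{plus_one_dyad}).
#' @param spacing Nucleosome repeat length (bp).
#' @param n_nuc Nucleosomes per gene (+1 .. +n_nuc).
#' @param jitter_sd Positional jitter sd per nucleosome index (recycled);
#'   0 gives hard-edged footprints.
#' @param halfwidth Nucleosome half-footprint (bp).
#' @return Numeric vector of per-site open probabilities in [0,1].
#' @export
positional_accessibility <- function(sites, genes, spacing = 165, n_nuc = 5,
                                     jitter_sd = 10, halfwidth = 73) {
  jitter_sd <- rep_len(jitter_sd, n_nuc)
  reach <- (n_nuc + 1) * spacing + halfwidth + 6 * max(jitter_sd)
  p_open <- rep(1, nrow(sites))
  for (gi in seq_len(nrow(genes))) {
    dyad <- genes$plus_one_dyad[gi]
    near <- which(sites$chrom == genes$chrom[gi] &
                    abs(sites$midpoint - dyad) <= reach)
    if (!length(near)) next
    m <- sites$midpoint[near]
    dir <- if (genes$strand[gi] == "+") 1 else -1
    for (j in seq_len(n_nuc)) {
      d <- m - (dyad + dir * (j - 1) * spacing)
      s <- jitter_sd[j]
      cov <- if (s > 0) {
        stats::pnorm((d + halfwidth) / s) - stats::pnorm((d - halfwidth) / s)
      } else {
        as.numeric(abs(d) <= halfwidth)
      }
      p_open[near] <- p_open[near] * (1 - cov)
    }
  }
  p_open
}

#' Sample a dyad-density track over dyad-relative offsets
#'
#' Draws per-cell nucleosome dyad positions (offset \code{(j-1)*spacing}
#' plus Gaussian jitter, per gene) and histograms them on the offset grid —
#' the synthetic analogue of an MNase-seq dyad-density track.
#'
#' @param n_genes Number of genes contributing arrays.
#' @param n_draws Cells (array realizations) per gene.
#' @param spacing Nucleosome repeat length (bp).
#' @param n_nuc Nucleosomes per array.
#' @param jitter_sd Jitter sd per nucleosome index (recycled).
#' @param offsets Offset grid.
#' @param seed Integer seed.
#' @return data.frame \code{offset}, \code{count}.
#' @export
dyad_density_counts <- function(n_genes, n_draws = 200, spacing = 165,
                                n_nuc = 5, jitter_sd = 10,
                                offsets = -300:1000, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  jitter_sd <- rep_len(jitter_sd, n_nuc)
  total <- n_genes * n_draws
  pos <- unlist(lapply(seq_len(n_nuc), function(j) {
    round((j - 1) * spacing + stats::rnorm(total, 0, jitter_sd[j]))
  }), use.names = FALSE)
  grid <- seq(min(offsets), max(offsets))
  idx <- pos - min(offsets) + 1L
  idx <- idx[idx >= 1 & idx <= length(grid)]
  data.frame(offset = grid, count = tabulate(idx, length(grid)))
}
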