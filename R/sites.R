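# Motif-site census: scan, neighbor distances, region classes, gene/dyad
# relationships and transcription deciles. All coordinates are 0-based
# half-open internally; BED is ingested natively, GFF start is shifted by -1.

#' Region classes in decreasing precedence
#'
#' When annotation intervals overlap, a site takes the highest-precedence
#' class containing its cut midpoint. Rarer, stronger-signal classes win.
#' @export
REGION_CLASSES <- c("CEN", "silenced", "tRNA", "NDR", "ARS", "TEL", "Ty", "ORF")

#' Scan a genome for a palindromic recognition motif
#'
#' Finds every forward-strand occurrence of \code{motif}. Both assay motifs
#' (GATC for Dam/DpnI, CG for M.SssI) are reverse-complement palindromes, so
#' a forward-strand scan enumerates each methylatable duplex site exactly
#' once; non-palindromic motifs are rejected. Ambiguity codes in the genome
#' never match.
#'
#' @param genome A \code{\link[Biostrings]{DNAStringSet}} or named character
#'   vector of chromosome sequences.
#' @param motif Uppercase ACGT string equal to its own reverse complement.
#' @return data.frame with columns \code{chrom}, \code{start} (0-based
#'   position of the first motif base), \code{motif}, and \code{midpoint}
#'   (0-based blunt-cut boundary, \code{start + nchar(motif)/2}; between the
#'   A and T of GATC, between C and G of CG), sorted by (chrom, start).
#' @export
scan_motif_sites <- function(genome, motif) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)) || anyNA(names(genome)))
    stop("genome sequences must be named")
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif) ||
      !grepl("^[ACGT]+$", motif))
    stop("invalid motif: must be a non-empty uppercase ACGT string")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  if (rc != motif)
    stop("non-palindromic motif '", motif,
         "' not supported (forward-strand scan would miss sites)")
  hits <- Biostrings::vmatchPattern(motif, genome)
  res <- lapply(seq_along(genome), function(i) {
    s <- Biostrings::startIndex(hits)[[i]]
    if (is.null(s) || !length(s)) return(NULL)
    data.frame(chrom = names(genome)[i], start = as.integer(s) - 1L,
               motif = motif, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      motif = character(), stringsAsFactors = FALSE)
  out$midpoint <- out$start + nchar(motif) %/% 2L
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distances to neighboring sites
#'
#' Gaps are measured between the cut midpoints of adjacent same-chromosome
#' sites. The first/last site on a chromosome gets the distance to the
#' chromosome end on its unbounded side, so an end-truncated side (< 200 bp
#' to the end) is treated like a close-neighbor side by the downstream
#' exclusion/substitution policy.
#'
#' @param sites data.frame from \code{\link{scan_motif_sites}}, sorted by
#'   (chrom, start).
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @return \code{sites} with numeric columns \code{left_gap}, \code{right_gap}.
#' @export
neighbor_gaps <- function(sites, chrom_sizes) {
  if (!all(sites$chrom %in% names(chrom_sizes)))
    stop("chrom_sizes missing for: ",
         paste(setdiff(unique(sites$chrom), names(chrom_sizes)), collapse = ", "))
  sites$left_gap <- NA_real_
  sites$right_gap <- NA_real_
  for (chr in unique(sites$chrom)) {
    i <- which(sites$chrom == chr)
    m <- sites$midpoint[i]
    if (is.unsorted(m, strictly = TRUE))
      stop("sites must be strictly sorted within chromosome ", chr)
    d <- diff(m)
    sites$left_gap[i] <- c(m[1], d)
    sites$right_gap[i] <- c(d, unname(chrom_sizes[chr]) - m[length(m)])
  }
  sites
}

#' Assign a genomic region class to each site
#'
#' A site takes the class of the annotation interval containing its cut
#' midpoint; overlaps are resolved by a fixed precedence
#' (\code{REGION_CLASSES}: CEN > silenced > tRNA > NDR > ARS > TEL > Ty >
#' ORF); sites in no interval are classed \code{"other"}.
#'
#' @param sites data.frame with \code{chrom}, \code{midpoint}.
#' @param regions data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and \code{class}, e.g. from \code{\link{read_regions}}.
#' @param precedence Character vector of allowed classes, high to low.
#' @return \code{sites} with a \code{region_class} column.
#' @export
classify_sites <- function(sites, regions, precedence = REGION_CLASSES) {
  bad <- setdiff(unique(regions$class), precedence)
  if (length(bad))
    stop("unknown region class label(s): ", paste(bad, collapse = ", "),
         " (records ", paste(which(regions$class %in% bad), collapse = ","), ")")
  sites$region_class <- "other"
  if (!nrow(regions) || !nrow(sites)) return(sites)
  lev <- union(unique(sites$chrom), unique(regions$chrom))
  gs <- GenomicRanges::GRanges(
    factor(sites$chrom, lev),
    IRanges::IRanges(start = sites$midpoint + 1L, width = 1L))
  gr <- GenomicRanges::GRanges(
    factor(regions$chrom, lev),
    IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  ov <- GenomicRanges::findOverlaps(gs, gr)
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov)
    p <- match(regions$class[S4Vectors::subjectHits(ov)], precedence)
    o <- order(q, p)
    first <- !duplicated(q[o])
    sites$region_class[q[o][first]] <- precedence[p[o][first]]
  }
  sites
}

#' Rank genes into transcription deciles
#'
#' Genes are sorted by descending RNA polymerase II signal and split into 10
#' contiguous rank blocks; decile 1 holds the most active genes. Block sizes
#' are balanced (\code{floor(N/10)} or \code{ceiling(N/10)}, larger blocks
#' first). Ties are broken by lexicographic \code{gene_id} for determinism.
#'
#' @param genes data.frame with \code{gene_id} and numeric
#'   \code{polII_signal} (no missing values).
#' @return \code{genes} with an integer \code{decile} column (1-10).
#' @export
assign_deciles <- function(genes) {
  n <- nrow(genes)
  if (n < 10) stop("need at least 10 genes to form deciles, got ", n)
  if (anyNA(genes$polII_signal)) stop("polII_signal must be present for every gene")
  o <- order(-genes$polII_signal, genes$gene_id)
  sizes <- rep(n %/% 10L, 10L)
  extra <- n %% 10L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  genes$decile <- NA_integer_
  genes$decile[o] <- rep(1:10, times = sizes)
  genes
}

#' Map sites to genes and +1-dyad offsets
#'
#' Each site is assigned to every gene whose dyad window it falls in
#' (multi-assignment: a site between two close genes contributes to both for
#' profile averaging). The signed offset is strand-corrected:
#' \code{midpoint - plus_one_dyad} for \code{+} genes, negated for \code{-}
#' genes, so positive offsets always point into the gene body.
#'
#' @param sites data.frame with \code{chrom}, \code{start}, \code{midpoint}.
#' @param genes data.frame with \code{gene_id}, \code{chrom}, \code{strand}
#'   (\code{+}/\code{-}), \code{plus_one_dyad} (0-based) and optionally
#'   \code{decile}.
#' @param window \code{c(upstream_bp, downstream_bp)} around the dyad.
#' @return data.frame of site rows joined with \code{gene_id},
#'   \code{dyad_offset} (and \code{decile} when available); a site inside
#'   several windows appears once per gene, sites in no window appear once
#'   with \code{NA} gene fields.
#' @export
map_sites_to_genes <- function(sites, genes, window = c(300, 1000)) {
  stopifnot(length(window) == 2, all(window >= 0))
  miss <- is.na(genes$plus_one_dyad)
  if (any(miss)) {
    warning(sum(miss), " gene(s) without a +1 dyad skipped")
    genes <- genes[!miss, , drop = FALSE]
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  lev <- union(unique(sites$chrom), unique(genes$chrom))
  gs <- GenomicRanges::GRanges(
    factor(sites$chrom, lev),
    IRanges::IRanges(start = sites$midpoint + 1L, width = 1L))
  plus <- genes$strand == "+"
  ws <- ifelse(plus, genes$plus_one_dyad - window[1], genes$plus_one_dyad - window[2])
  we <- ifelse(plus, genes$plus_one_dyad + window[2], genes$plus_one_dyad + window[1])
  gg <- GenomicRanges::GRanges(
    factor(genes$chrom, lev),
    IRanges::IRanges(start = ws + 1L, end = we + 1L))
  ov <- GenomicRanges::findOverlaps(gs, gg)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  assigned <- sites[q, , drop = FALSE]
  assigned$gene_id <- genes$gene_id[s]
  raw <- sites$midpoint[q] - genes$plus_one_dyad[s]
  assigned$dyad_offset <- ifelse(plus[s], raw, -raw)
  if ("decile" %in% names(genes)) assigned$decile <- genes$decile[s]
  un <- sites[setdiff(seq_len(nrow(sites)), unique(q)), , drop = FALSE]
  if (nrow(un)) {
    un$gene_id <- NA_character_
    un$dyad_offset <- NA_real_
    if ("decile" %in% names(genes)) un$decile <- NA_integer_
    assigned <- rbind(assigned, un)
  }
  assigned <- assigned[order(assigned$chrom, assigned$start, assigned$gene_id), ,
                       drop = FALSE]
  rownames(assigned) <- NULL
  assigned
}

#' Read region annotations from BED or GFF3
#'
#' BED intervals are used natively (0-based half-open, class in the name
#' field); GFF3 intervals are converted (1-based closed to 0-based half-open,
#' class taken from the feature type, optionally renamed via \code{class_map}).
#'
#' @param path File path.
#' @param format \code{"bed"} or \code{"gff3"}; guessed from the extension by
#'   default.
#' @param class_map Optional named character vector mapping GFF feature types
#'   to region classes.
#' @return data.frame with \code{chrom}, \code{start}, \code{end}, \code{class}.
#' @export
read_regions <- function(path, format = c("auto", "bed", "gff3"),
                         class_map = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "bed"
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  cls <- if (format == "bed") gr$name else as.character(gr$type)
  if (!is.null(class_map)) {
    hit <- cls %in% names(class_map)
    cls[hit] <- class_map[cls[hit]]
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             class = cls, stringsAsFactors = FALSE)
}

#' Read a gene model table
#'
#' Expects a TSV with header columns \code{gene_id}, \code{chrom},
#' \code{strand}, \code{plus_one_dyad}, \code{polII_signal}.
#' @param path File path.
#' @return data.frame of gene models.
#' @export
read_genes <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "chrom", "strand", "plus_one_dyad", "polII_signal")
  missing_cols <- setdiff(need, names(g))
  if (length(missing_cols))
    stop("genes table missing column(s): ", paste(missing_cols, collapse = ", "))
  g
}

#' Write the annotated site table
#'
#' Emits the per-site TSV (location, midpoint, neighbor gaps, region class,
#' owning gene, dyad offset, decile) analogous to the genome-wide GATC census
#' used by the downstream analyses.
#' @param sites data.frame of (possibly gene-mapped) sites.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sites_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
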