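# Nanopolish-dialect long-read CpG methylation call handling: parsing,
# group splitting, log-likelihood-ratio classification and per-site
# frequency aggregation with the relative coverage filter.

#' Parse a Nanopolish-style methylation-call TSV
#'
#' Requires the methylation-call columns (chromosome, strand, start, end,
#' read_name, log_lik_ratio, num_motifs, sequence); malformed rows
#' (non-numeric LLR, missing fields) are skipped and counted.
#'
#' @param path File path (TSV with header).
#' @return data.frame of call records, with attribute \code{n_skipped}.
#' @export
read_cpg_calls <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         comment.char = "", stringsAsFactors = FALSE,
                         colClasses = "character", fill = TRUE)
  need <- c("chromosome", "strand", "start", "end", "read_name",
            "log_lik_ratio", "num_motifs", "sequence")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  start <- suppressWarnings(as.integer(d$start))
  end <- suppressWarnings(as.integer(d$end))
  llr <- suppressWarnings(as.numeric(d$log_lik_ratio))
  nm <- suppressWarnings(as.integer(d$num_motifs))
  bad <- is.na(start) | is.na(end) | is.na(llr) | is.na(nm) | nm < 1 |
    start > end | !nzchar(d$sequence) | !nzchar(d$read_name)
  out <- data.frame(chromosome = d$chromosome[!bad], strand = d$strand[!bad],
                    start = start[!bad], end = end[!bad],
                    read_name = d$read_name[!bad],
                    log_lik_ratio = llr[!bad], num_motifs = nm[!bad],
                    sequence = d$sequence[!bad], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(bad)
  if (any(bad)) message(sum(bad), " malformed row(s) skipped")
  out
}

#' Classify a log-likelihood ratio call
#'
#' LLR >= +threshold is methylated, <= -threshold unmethylated, in between
#' ambiguous (the Nanopolish community default threshold of 2.0 is used
#' because the calls do not publish a cutoff).
#'
#' @param log_lik_ratio Numeric vector of finite LLRs.
#' @param threshold Magnitude cutoff.
#' @return Character vector in \{"methylated", "unmethylated", "ambiguous"\}.
#' @export
classify_call <- function(log_lik_ratio, threshold = 2.0) {
  if (any(!is.finite(log_lik_ratio))) stop("log_lik_ratio must be finite")
  ifelse(log_lik_ratio >= threshold, "methylated",
         ifelse(log_lik_ratio <= -threshold, "unmethylated", "ambiguous"))
}

#' Split grouped calls into one provisional call per CG
#'
#' Nanopolish merges CG sites closer than ~10 bp into one call row; each CG
#' in the group inherits the group's LLR (assigning to the first CG only
#' would distort phasing density). CG positions are recovered from the
#' sequence context: the first CG in the context anchors the record's
#' \code{start}, the rest are placed by relative offset. Records whose
#' context CG count disagrees with \code{num_motifs} are quarantined. Calls
#' are reported on the forward-strand C coordinate regardless of read strand
#' (CpG symmetry).
#'
#' @param calls data.frame from \code{\link{read_cpg_calls}}.
#' @return data.frame \code{chrom}, \code{pos} (0-based C position),
#'   \code{read_name}, \code{log_lik_ratio}; quarantined records are kept in
#'   the \code{quarantined} attribute (with \code{n_quarantined}).
#' @export
split_cpg_groups <- function(calls) {
  useq <- unique(calls$sequence)
  offs <- lapply(gregexpr("CG", useq, fixed = TRUE), function(m) {
    if (m[1] == -1) integer(0) else as.integer(m)
  })
  oi <- match(calls$sequence, useq)
  n_found <- lengths(offs)[oi]
  bad <- n_found != calls$num_motifs
  good <- calls[!bad, , drop = FALSE]
  goff <- offs[oi[!bad]]
  reps <- lengths(goff)
  rel <- unlist(lapply(goff, function(o) o - o[1]), use.names = FALSE)
  out <- data.frame(
    chrom = rep(good$chromosome, reps),
    pos = rep(good$start, reps) + rel,
    read_name = rep(good$read_name, reps),
    log_lik_ratio = rep(good$log_lik_ratio, reps),
    stringsAsFactors = FALSE)
  attr(out, "quarantined") <- calls[bad, , drop = FALSE]
  attr(out, "n_quarantined") <- sum(bad)
  out
}

#' Per-site CpG methylation frequencies with coverage filter
#'
#' Ambiguous calls are excluded from coverage; sites whose coverage falls
#' below \code{min_cov_frac} of the median coverage (over covered sites) are
#' flagged as failing the filter.
#'
#' @param split_calls data.frame from \code{\link{split_cpg_groups}}.
#' @param threshold LLR classification threshold.
#' @param min_cov_frac Relative coverage cutoff (default 10\% of median).
#' @return data.frame \code{chrom}, \code{pos}, \code{n_methylated},
#'   \code{n_unmethylated}, \code{n_ambiguous}, \code{coverage},
#'   \code{frequency}, \code{pass_filter}.
#' @export
cpg_site_frequencies <- function(split_calls, threshold = 2.0,
                                 min_cov_frac = 0.1) {
  if (!nrow(split_calls)) stop("no calls to aggregate")
  cls <- classify_call(split_calls$log_lik_ratio, threshold)
  key <- paste(split_calls$chrom, split_calls$pos)
  uk <- !duplicated(key)
  out <- data.frame(chrom = split_calls$chrom[uk], pos = split_calls$pos[uk],
                    stringsAsFactors = FALSE)
  okey <- paste(out$chrom, out$pos)
  count <- function(what) {
    tb <- table(factor(key[cls == what], levels = okey))
    as.integer(tb)
  }
  out$n_methylated <- count("methylated")
  out$n_unmethylated <- count("unmethylated")
  out$n_ambiguous <- count("ambiguous")
  out$coverage <- out$n_methylated + out$n_unmethylated
  out$frequency <- ifelse(out$coverage > 0,
                          out$n_methylated / out$coverage, NA_real_)
  med <- stats::median(out$coverage[out$coverage > 0])
  out$pass_filter <- out$coverage >= min_cov_frac * med
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Map CpG frequencies onto the common fcut layout
#'
#' Lets the kinetics and phasing stages run unchanged on long-read CG data:
#' frequency becomes \code{fcut}, filter failures become a non-usable
#' status.
#'
#' @param freqs data.frame from \code{\link{cpg_site_frequencies}}.
#' @return fcut-shaped data.frame (\code{chrom}, \code{start},
#'   \code{midpoint}, \code{fcut}, \code{status}).
#' @export
cpg_as_fcut <- function(freqs) {
  data.frame(chrom = freqs$chrom, start = freqs$pos,
             midpoint = freqs$pos + 1L, fcut = freqs$frequency,
             status = ifelse(freqs$pass_filter, "ok", "low_coverage"),
             stringsAsFactors = FALSE)
}
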