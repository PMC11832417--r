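# Per-site fraction-cut (fcut) from aligned fragment coordinates.
#
# fcut estimates the methylated (accessible) fraction of molecules at a GATC
# site from the pileup of fragment ends at the blunt DpnI cut, with a
# correction for stochastic loss of the terminal A/T: for the right end,
# fragments ending on the A *or* the G are counted over the coverage of the
# G; for the left end, fragments starting on the T *or* the C over the
# coverage of the C.

#' Load sequenced fragments
#'
#' BEDPE/BED input: 3+ column TSV of fragment intervals (0-based half-open);
#' a 6+-column file whose columns 4-6 look like a second mate block is merged
#' per row into \code{[min(start), max(end))}, and rows whose mates map to
#' different chromosomes are skipped (counted). BAM input: properly paired
#' alignments; the fragment is taken from the leftmost mate's position and
#' TLEN, matching paired-end sequencing of sonicated DpnI digests.
#'
#' @param path File path.
#' @param format \code{"bedpe"} (also plain BED intervals) or \code{"bam"}.
#' @param max_len Fragments longer than this are dropped (aligner ceiling).
#' @param dedup Remove duplicate intervals? Default \code{FALSE}: cut-site
#'   pileups are signal here, not PCR artifacts.
#' @return data.frame \code{chrom}, \code{start}, \code{end} with attributes
#'   \code{n_dropped_long}, \code{n_skipped_pairs}.
#' @export
load_fragments <- function(path, format = c("bedpe", "bam"), max_len = 5000,
                           dedup = FALSE) {
  format <- match.arg(format)
  n_skipped <- 0L
  if (format == "bedpe") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "")
    if (ncol(tab) >= 6 && is.character(tab[[4]]) &&
        is.numeric(tab[[5]]) && is.numeric(tab[[6]])) {
      same <- tab[[1]] == tab[[4]]
      n_skipped <- sum(!same)
      tab <- tab[same, , drop = FALSE]
      fr <- data.frame(chrom = tab[[1]],
                       start = pmin(tab[[2]], tab[[5]]),
                       end = pmax(tab[[3]], tab[[6]]),
                       stringsAsFactors = FALSE)
    } else {
      fr <- data.frame(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
                       stringsAsFactors = FALSE)
    }
  } else {
    p <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isProperPair = TRUE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE),
      what = c("rname", "pos", "isize"))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    keep <- !is.na(b$isize) & b$isize > 0   # leftmost mate once per pair
    n_skipped <- sum(is.na(b$isize) | b$isize == 0) %/% 2L
    fr <- data.frame(chrom = as.character(b$rname[keep]),
                     start = b$pos[keep] - 1L,
                     end = b$pos[keep] - 1L + b$isize[keep],
                     stringsAsFactors = FALSE)
  }
  too_long <- fr$end - fr$start > max_len
  fr <- fr[!too_long, , drop = FALSE]
  if (dedup) fr <- unique(fr)
  rownames(fr) <- NULL
  attr(fr, "n_dropped_long") <- sum(too_long)
  attr(fr, "n_skipped_pairs") <- n_skipped
  fr
}

#' Exact coverage and fragment-end tracks
#'
#' For each chromosome, \code{coverage[b]} counts fragments containing base
#' b, \code{left_ends[b]} fragments whose first base is b, and
#' \code{right_ends[b]} fragments whose last base is b (all 0-based
#' positions, stored 1-shifted in R vectors). Coverage is accumulated with a
#' difference array, equivalent to per-fragment enumeration.
#'
#' @param frags data.frame \code{chrom}, \code{start}, \code{end}.
#' @param chrom_sizes Named chromosome lengths.
#' @return Named list per chromosome of \code{list(coverage, left_ends,
#'   right_ends)} integer vectors of chromosome length.
#' @export
coverage_and_ends <- function(frags, chrom_sizes) {
  out <- list()
  for (chr in names(chrom_sizes)) {
    n <- as.integer(chrom_sizes[[chr]])
    f <- frags[frags$chrom == chr, , drop = FALSE]
    bad <- which(f$start < 0 | f$end > n | f$start >= f$end)
    if (length(bad))
      stop("out-of-bounds fragment on ", chr, ": [", f$start[bad[1]], ",",
           f$end[bad[1]], ") vs length ", n)
    d <- integer(n + 1L)
    if (nrow(f)) {
      add <- tabulate(f$start + 1L, n + 1L)
      sub <- tabulate(f$end + 1L, n + 1L)
      d <- add - sub
    }
    out[[chr]] <- list(coverage = cumsum(d)[seq_len(n)],
                       left_ends = tabulate(f$start + 1L, n),
                       right_ends = tabulate(f$end, n))
  }
  extra <- setdiff(unique(frags$chrom), names(chrom_sizes))
  if (length(extra))
    stop("fragments on chromosome(s) absent from chrom_sizes: ",
         paste(extra, collapse = ", "))
  out
}

#' Per-site cut statistics
#'
#' For a GATC site with bases (G,A,T,C) at 0-based (s, s+1, s+2, s+3):
#' \code{fcut_right = (ends on A + ends on G) / coverage of G} and
#' \code{fcut_left = (starts on T + starts on C) / coverage of C}. A side
#' with zero coverage is undefined; sides with coverage below
#' \code{min_coverage} are flagged and kept out of the combined value. The
#' site-level \code{fcut} is the mean of the usable sides.
#'
#' @param sites Site table (GATC motif) with \code{chrom}, \code{start}, and
#'   optionally \code{left_gap}/\code{right_gap} (carried through for the
#'   neighbor policy).
#' @param tracks Output of \code{\link{coverage_and_ends}}.
#' @param min_coverage Minimum per-side coverage for a side to be usable.
#' @return data.frame with counts, per-side and combined fcut, and a
#'   \code{status} in \{ok, low_coverage, no_coverage\}; degenerate coverage
#'   produces statuses, never errors.
#' @export
site_fcut <- function(sites, tracks, min_coverage = 8) {
  n <- nrow(sites)
  out <- sites[, intersect(c("chrom", "start", "midpoint", "left_gap",
                             "right_gap", "region_class"), names(sites)),
               drop = FALSE]
  cols <- c("n_right_A", "n_right_G", "n_left_T", "n_left_C", "cov_G", "cov_C")
  for (cl in cols) out[[cl]] <- 0L
  out$fcut_right <- NA_real_
  out$fcut_left <- NA_real_
  for (chr in unique(sites$chrom)) {
    tr <- tracks[[chr]]
    if (is.null(tr)) stop("no tracks for chromosome ", chr)
    i <- which(sites$chrom == chr)
    s <- sites$start[i]                    # 0-based G position
    len <- length(tr$coverage)
    if (any(s + 4L > len)) stop("site beyond chromosome end on ", chr)
    out$n_right_G[i] <- tr$right_ends[s + 1L]
    out$n_right_A[i] <- tr$right_ends[s + 2L]
    out$n_left_T[i] <- tr$left_ends[s + 3L]
    out$n_left_C[i] <- tr$left_ends[s + 4L]
    out$cov_G[i] <- tr$coverage[s + 1L]
    out$cov_C[i] <- tr$coverage[s + 4L]
  }
  rgt <- out$cov_G > 0
  lft <- out$cov_C > 0
  out$fcut_right[rgt] <- (out$n_right_A[rgt] + out$n_right_G[rgt]) / out$cov_G[rgt]
  out$fcut_left[lft] <- (out$n_left_T[lft] + out$n_left_C[lft]) / out$cov_C[lft]
  right_ok <- out$cov_G >= min_coverage
  left_ok <- out$cov_C >= min_coverage
  out$fcut <- ifelse(right_ok & left_ok, (out$fcut_right + out$fcut_left) / 2,
              ifelse(right_ok, out$fcut_right,
              ifelse(left_ok, out$fcut_left, NA_real_)))
  out$status <- ifelse(right_ok | left_ok, "ok",
                ifelse(rgt | lft, "low_coverage", "no_coverage"))
  attr(out, "min_coverage") <- min_coverage
  out
}

#' Apply the 200-bp neighbor proximity policy
#'
#' Fragments shorter than ~200 bp are recovered inefficiently, so a close
#' neighboring site biases the facing side of a site. Sites with neighbors
#' closer than \code{min_gap} on both sides are excluded; with a close
#' neighbor on one side only, that side's fcut is overwritten by the far
#' side's value (status \code{substituted_left}/\code{substituted_right});
#' otherwise the combined fcut is the mean of the usable sides.
#'
#' @param stats Output of \code{\link{site_fcut}} carrying
#'   \code{left_gap}/\code{right_gap}.
#' @param min_gap Proximity threshold in bp.
#' @return \code{stats} with final \code{fcut} and \code{status}.
#' @export
apply_neighbor_policy <- function(stats, min_gap = 200) {
  if (!all(c("left_gap", "right_gap") %in% names(stats)))
    stop("stats must carry left_gap/right_gap (run neighbor_gaps first)")
  min_cov <- attr(stats, "min_coverage")
  if (is.null(min_cov)) min_cov <- 8
  close_l <- stats$left_gap < min_gap
  close_r <- stats$right_gap < min_gap
  right_ok <- stats$cov_G >= min_cov
  left_ok <- stats$cov_C >= min_cov

  both <- close_l & close_r
  stats$status[both] <- "excluded"
  stats$fcut[both] <- NA_real_

  sub_l <- close_l & !close_r & stats$status != "excluded"
  ok_far <- sub_l & right_ok
  stats$fcut_left[ok_far] <- stats$fcut_right[ok_far]
  stats$fcut[ok_far] <- stats$fcut_right[ok_far]
  stats$status[ok_far] <- "substituted_left"
  stats$status[sub_l & !right_ok] <- "excluded"
  stats$fcut[sub_l & !right_ok] <- NA_real_

  sub_r <- close_r & !close_l & stats$status != "excluded" &
    !startsWith(stats$status, "substituted")
  ok_far <- sub_r & left_ok
  stats$fcut_right[ok_far] <- stats$fcut_left[ok_far]
  stats$fcut[ok_far] <- stats$fcut_left[ok_far]
  stats$status[ok_far] <- "substituted_right"
  stats$status[sub_r & !left_ok] <- "excluded"
  stats$fcut[sub_r & !left_ok] <- NA_real_
  stats
}

#' Full fcut pipeline for one sample
#'
#' Coverage/end tracks, per-site statistics, and the neighbor policy in one
#' call.
#'
#' @inheritParams site_fcut
#' @inheritParams coverage_and_ends
#' @inheritParams apply_neighbor_policy
#' @param frags Fragment data.frame.
#' @return Per-site fcut statistics data.frame.
#' @export
compute_fcut <- function(sites, frags, chrom_sizes, min_coverage = 8,
                         min_gap = 200) {
  tracks <- coverage_and_ends(frags, chrom_sizes)
  stats <- site_fcut(sites, tracks, min_coverage = min_coverage)
  if (all(c("left_gap", "right_gap") %in% names(stats)))
    stats <- apply_neighbor_policy(stats, min_gap = min_gap)
  stats
}

#' Join per-sample fcut tables into one wide table
#'
#' @param stats_list Named list of \code{site_fcut} outputs (one per sample
#'   or design point).
#' @param drop_excluded Drop sites whose status is \code{excluded} in every
#'   sample?
#' @return data.frame: site keys plus \code{fcut_<sample>} and
#'   \code{status_<sample>} column blocks.
#' @export
fcut_table <- function(stats_list, drop_excluded = FALSE) {
  nm <- names(stats_list)
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("stats_list must have unique non-empty names (sample column collision)")
  out <- stats_list[[1]][, c("chrom", "start"), drop = FALSE]
  for (s in nm) {
    m <- stats_list[[s]]
    i <- match(paste(out$chrom, out$start), paste(m$chrom, m$start))
    if (anyNA(i)) stop("site keys differ between samples")
    out[[paste0("fcut_", s)]] <- m$fcut[i]
    out[[paste0("status_", s)]] <- m$status[i]
  }
  if (drop_excluded) {
    st <- as.matrix(out[, paste0("status_", nm), drop = FALSE])
    out <- out[rowSums(st != "excluded") > 0, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
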