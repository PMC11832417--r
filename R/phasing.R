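# Dyad-aligned nucleosome-phasing profiles and derived metrics.
#
# Methylation is averaged at each signed offset from the +1 nucleosome dyad
# over all (site, gene) pairs, smoothed with a centered boxcar, and compared
# with a nucleosome dyad-density track: phased chromatin gives a methylation
# profile exactly out of phase with dyad density (high in linkers, low at
# dyads).

#' Build a dyad-aligned methylation profile
#'
#' At each offset, the mean fcut over all (site, gene) pairs landing there;
#' a site near two genes contributes to both. Offsets supported by fewer
#' than \code{min_n} pairs are masked before smoothing (motif sparsity
#' guard; GATC is ~25-fold sparser than CG).
#'
#' @param fcut fcut table (columns \code{chrom}, \code{start}, \code{fcut},
#'   \code{status}).
#' @param pairs Site-gene pairs from \code{\link{map_sites_to_genes}} with
#'   \code{dyad_offset}.
#' @param offsets Integer offset grid (bp relative to the +1 dyad).
#' @param min_n Minimum contributing pairs per offset.
#' @param good_status Statuses retained.
#' @return data.frame \code{offset}, \code{mean} (NA where undefined or
#'   masked), \code{n}.
#' @export
dyad_profile <- function(fcut, pairs, offsets = -300:1000, min_n = 20,
                         good_status = c("ok", "substituted_left",
                                         "substituted_right")) {
  if (!length(offsets)) stop("empty offset window")
  i <- match(paste(pairs$chrom, pairs$start), paste(fcut$chrom, fcut$start))
  keep <- !is.na(i) & !is.na(pairs$dyad_offset) &
    fcut$status[i] %in% good_status & !is.na(fcut$fcut[i])
  off <- as.integer(round(pairs$dyad_offset[keep]))
  val <- fcut$fcut[i[keep]]
  inw <- off >= min(offsets) & off <= max(offsets)
  off <- off[inw]; val <- val[inw]
  idx <- off - min(offsets) + 1L
  ng <- max(offsets) - min(offsets) + 1L
  n <- tabulate(idx, ng)
  s <- rep(0, ng)
  if (length(idx)) {
    agg <- rowsum(val, idx)
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  m <- ifelse(n > 0, s / n, NA_real_)
  m[n < min_n] <- NA_real_
  grid <- seq(min(offsets), max(offsets))
  data.frame(offset = grid, mean = m, n = n)[grid %in% offsets, ]
}

#' Smooth a profile with a centered moving average
#'
#' Boxcar of width \code{w} bp (odd); at the edges the window shrinks to the
#' available points, and undefined offsets are skipped, not zero-filled.
#' Smoothed values stay within the range of the input and are reported only
#' where the input is defined.
#'
#' @param profile data.frame with \code{offset} and \code{mean} (or an
#'   existing \code{smoothed} column to re-smooth from \code{mean}).
#' @param w Window width in bp, odd; 21 by default, \code{w = 1} is the
#'   identity.
#' @return \code{profile} with a \code{smoothed} column.
#' @export
smooth_profile <- function(profile, w = 21) {
  if (w %% 2 != 1 || w < 1) stop("smoothing window must be odd and >= 1")
  v <- profile$mean
  ok <- !is.na(v)
  cs <- cumsum(c(0, ifelse(ok, v, 0)))
  cn <- cumsum(c(0, as.numeric(ok)))
  h <- (w - 1) / 2
  n <- length(v)
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  num <- cs[hi + 1] - cs[lo]
  den <- cn[hi + 1] - cn[lo]
  sm <- ifelse(den > 0, num / den, NA_real_)
  sm[!ok] <- NA_real_
  profile$smoothed <- sm
  profile
}

#' Normalize a dyad-density track to a 0.1 maximum
#'
#' Scales nonnegative dyad counts by \code{0.1 / max} so the nucleosome
#' track fits under fcut curves on a 0-1 axis; peak offsets are preserved.
#'
#' @param track data.frame \code{offset}, \code{count} (nonnegative, not all
#'   zero).
#' @return data.frame \code{offset}, \code{density} with maximum exactly 0.1.
#' @export
normalize_density <- function(track) {
  if (any(track$count < 0)) stop("dyad counts must be nonnegative")
  mx <- max(track$count)
  if (mx == 0) stop("all-zero dyad track cannot be normalized")
  data.frame(offset = track$offset, density = track$count * (0.1 / mx))
}

.profile_values <- function(p) if ("smoothed" %in% names(p)) p$smoothed else p$mean

#' Convolve a dyad-density track into a nucleosome-occupancy track
#'
#' A base is occupied when a nucleosome dyad lies within half a footprint of
#' it, so occupancy is the dyad density summed over a footprint-wide window.
#' Occupancy, not raw dyad density, is the quantity directly anti-correlated
#' with methyltransferase accessibility; raw dyad peaks are much narrower
#' than the footprints they imply.
#'
#' @param track data.frame \code{offset}, \code{count} (raw dyad counts).
#' @param footprint Nucleosome footprint width in bp (odd).
#' @return data.frame \code{offset}, \code{count} of occupancy-weighted
#'   counts (suitable for \code{\link{normalize_density}}).
#' @export
occupancy_track <- function(track, footprint = 147) {
  if (footprint %% 2 != 1 || footprint < 1) stop("footprint must be odd and >= 1")
  cs <- cumsum(c(0, track$count))
  h <- (footprint - 1) / 2
  n <- length(track$count)
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  data.frame(offset = track$offset, count = cs[hi + 1] - cs[lo])
}

#' Anti-phase score between methylation and nucleosome density
#'
#' Pearson correlation over shared offsets; strongly negative for phased
#' chromatin (methylation high in linkers, low at dyads).
#'
#' @param profile Methylation profile (smoothed values used when present).
#' @param density Normalized dyad-density track.
#' @param min_shared Minimum shared defined offsets.
#' @return Pearson r.
#' @export
antiphase_score <- function(profile, density, min_shared = 50) {
  i <- match(profile$offset, density$offset)
  v <- .profile_values(profile)
  d <- density$density[i]
  keep <- !is.na(i) & !is.na(v) & !is.na(d)
  if (sum(keep) < min_shared)
    stop("only ", sum(keep), " shared offsets (need >= ", min_shared, ")")
  if (stats::var(v[keep]) == 0 || stats::var(d[keep]) == 0)
    stop("degenerate variance")
  stats::cor(v[keep], d[keep])
}

#' Estimate the nucleosome-array shift between two profiles
#'
#' Integer lag in \code{[-max_lag, max_lag]} maximizing the Pearson
#' correlation of the overlapping segments inside \code{range} (the genic
#' array; all phased peaks are used rather than the +1 peak alone). Ties go
#' to the smallest |lag|. Sign convention: negative means profile B is
#' shifted toward the promoter relative to profile A.
#'
#' @param a,b Smoothed profiles on a common offset grid.
#' @param max_lag Maximum |lag| in bp.
#' @param range Offsets considered, default \code{c(0, 500)}.
#' @param min_overlap Minimum overlapping defined offsets per lag.
#' @return Integer shift in bp.
#' @export
estimate_shift <- function(a, b, max_lag = 60, range = c(0, 500),
                           min_overlap = 30) {
  grid <- seq(range[1], range[2])
  va <- .profile_values(a)[match(grid, a$offset)]
  vb <- .profile_values(b)[match(grid, b$offset)]
  n <- length(grid)
  lags <- seq(-max_lag, max_lag)
  lags <- lags[order(abs(lags), lags)]
  best <- -Inf
  best_lag <- NA_integer_
  for (l in lags) {
    i <- seq_len(n)
    i <- i[i + l >= 1 & i + l <= n]
    x <- va[i + l]
    y <- vb[i]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_overlap) next
    if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) next
    r <- stats::cor(x[ok], y[ok])
    if (r > best + 1e-12) {
      best <- r
      best_lag <- l
    }
  }
  if (is.na(best_lag)) stop("insufficient overlap between profiles")
  -best_lag
}

#' +1-trough shift between two profiles
#'
#' Secondary, peak-tracking estimate: the difference in the centroid of the
#' +1 nucleosome methylation trough within \code{band} (depth-weighted mean
#' offset, robust to the flat bottom of a hard nucleosomal footprint);
#' negative means B's +1 nucleosome sits closer to the promoter.
#'
#' @param a,b Smoothed profiles.
#' @param band Offset band searched for the +1 trough.
#' @return Shift in bp.
#' @export
plus_one_shift <- function(a, b, band = c(-82, 82)) {
  loc <- function(p) {
    v <- .profile_values(p)
    keep <- p$offset >= band[1] & p$offset <= band[2] & !is.na(v)
    if (!any(keep)) stop("no defined offsets in the +1 band")
    depth <- max(v[keep]) - v[keep]
    if (sum(depth) == 0) return(mean(p$offset[keep]))
    sum(p$offset[keep] * depth) / sum(depth)
  }
  loc(b) - loc(a)
}

#' Downstream phasing disorder index
#'
#' Ratio of the peak-to-trough amplitude in the +2..+4 nucleosome band to
#' the amplitude in the +1 band: about 1 for well-phased arrays, falling
#' toward 0 as downstream phasing dissolves while the +1 peak persists.
#'
#' @param profile Smoothed profile covering 0..+700 (with default spacing).
#' @param spacing Nucleosome repeat length (bp).
#' @return Amplitude ratio.
#' @export
disorder_index <- function(profile, spacing = 165) {
  v <- .profile_values(profile)
  amp <- function(lo, hi) {
    keep <- profile$offset >= lo & profile$offset <= hi & !is.na(v)
    if (!any(keep)) return(NA_real_)
    diff(range(v[keep]))
  }
  a1 <- amp(-spacing / 2, spacing / 2)
  ad <- amp(1.5 * spacing, 4.5 * spacing)
  if (is.na(a1) || a1 == 0) stop("undefined +1 amplitude")
  if (is.na(ad)) return(NA_real_)
  ad / a1
}
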