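# Ground-truthed synthetic chromatin / methylation simulator.
#
# Two probing regimes are modeled:
#   nuclei  — static chromatin: each site is accessible in a fixed fraction p
#             of nuclei; accessible sites saturate with enzyme concentration
#             as 1 - exp(-c/c0) (limit digest).
#   in_vivo — dynamic chromatin: after an exponentially distributed induction
#             delay (half-time T1/2) each cell methylates a site as a
#             first-order process with rate k (per minute) scaled by a
#             log-normal per-cell enzyme level; within a cell methylation is
#             monotone in time (once methylated, stays methylated).
#
# All draws are made cell by cell in a fixed order so that increasing
# n_cells leaves the states of earlier cells unchanged under the same seed.

.per_site_param <- function(x, sites, what) {
  n <- nrow(sites)
  if (is.null(x)) stop("parameter '", what, "' is required for this mode")
  if (length(x) == n && is.null(names(x))) return(as.numeric(x))
  if (!is.null(names(x))) {
    cls <- unique(sites$region_class)
    missing_cls <- setdiff(cls, names(x))
    if (length(missing_cls))
      stop("no '", what, "' for class(es): ", paste(missing_cls, collapse = ", "))
    return(as.numeric(x[sites$region_class]))
  }
  if (length(x) == 1L) return(rep(as.numeric(x), n))
  stop("'", what, "' must be a scalar, a per-site vector, ",
       "or a named per-class vector")
}

#' Simulate per-cell methylation states
#'
#' Draws cell-by-site methylation indicators across a design axis
#' (concentrations for static nuclei, minutes after induction in vivo) with
#' exact per-site ground truth.
#'
#' In nuclei mode a (cell, site) pair is accessible with probability
#' \code{plateau}; an accessible site is methylated at concentration c with
#' probability \code{1 - exp(-c/c0)}; inaccessible sites are never methylated.
#' In vivo, a cell's induction delay is Exponential(\code{log(2)/half_time}),
#' its enzyme level multiplier is log-normal (\code{sdlog = sigma_cell},
#' median 1), and a site is methylated by time t with probability
#' \code{f0 + (1-f0) * (1 - exp(-k * lambda * max(0, t - tau)))}.
#' Methylation is monotone along the design axis within every cell.
#'
#' @param sites Site table (needs \code{chrom}, \code{start}, \code{midpoint};
#'   \code{region_class} if per-class parameters are given).
#' @param mode \code{"in_vivo"} or \code{"nuclei"}.
#' @param design Strictly increasing design axis: minutes (in vivo) or nM
#'   (nuclei).
#' @param n_cells Number of cells (>= 1).
#' @param rate Per-minute methylation rate k: scalar, per-site vector, or
#'   named per-class vector (in vivo mode).
#' @param plateau Accessible fraction p in [0,1], same shapes (nuclei mode).
#' @param c0 Saturation scale (nM) of the concentration response.
#' @param f0 Pre-induction background methylated fraction, scalar or
#'   per-class.
#' @param half_time Induction half-time T1/2 (minutes); 0 means instant
#'   induction.
#' @param sigma_cell sdlog of the per-cell enzyme-level multiplier; 0 turns
#'   cell-to-cell variation off.
#' @param seed Integer seed (mandatory: every stochastic stage is seeded).
#' @return An object of class \code{meth_states}: list with \code{states}
#'   (logical array cell x site x design point), \code{truth} (site x point
#'   matrix of expected methylated fractions, conditional on the drawn cell
#'   parameters in vivo), \code{sites}, \code{design}, \code{axis},
#'   \code{cells} (per-cell \code{tau}, \code{lambda} in vivo), \code{params},
#'   \code{seed}.
#' @export
simulate_states <- function(sites, mode = c("in_vivo", "nuclei"), design,
                            n_cells, rate = NULL, plateau = NULL, c0 = 0.5,
                            f0 = 0, half_time = 80, sigma_cell = 0.5, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("an explicit seed is required")
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (length(design) < 1 || is.unsorted(design, strictly = TRUE))
    stop("design must be strictly increasing")
  ns <- nrow(sites)
  nd <- length(design)
  f0s <- .per_site_param(f0, sites, "f0")
  if (any(f0s < 0 | f0s >= 1)) stop("f0 must satisfy 0 <= f0 < 1")
  set.seed(seed)
  states <- array(FALSE, dim = c(n_cells, ns, nd))
  cells <- data.frame(tau = rep(NA_real_, n_cells), lambda = NA_real_)

  if (mode == "in_vivo") {
    k <- .per_site_param(rate, sites, "rate")
    if (any(k < 0)) stop("rates must be >= 0")
    if (half_time < 0) stop("half_time must be >= 0")
    ind_rate <- if (half_time > 0) log(2) / half_time else Inf
    thr <- matrix(NA_real_, n_cells, ns)  # absolute methylation time
    pre <- matrix(FALSE, n_cells, ns)
    for (ci in seq_len(n_cells)) {
      tau <- if (is.finite(ind_rate)) stats::rexp(1, ind_rate) else 0
      lam <- exp(stats::rnorm(1, 0, max(sigma_cell, 0)))
      thr[ci, ] <- tau + stats::rexp(ns) / (k * lam)
      pre[ci, ] <- stats::runif(ns) < f0s
      cells$tau[ci] <- tau
      cells$lambda[ci] <- lam
    }
    truth <- matrix(NA_real_, ns, nd)
    for (i in seq_len(nd)) {
      states[, , i] <- pre | (thr <= design[i])
      dt <- pmax(design[i] - cells$tau, 0) * cells$lambda
      m <- 1 - exp(-outer(dt, k))                    # cells x sites
      truth[, i] <- f0s + (1 - f0s) * colMeans(m)
    }
  } else {
    p <- .per_site_param(plateau, sites, "plateau")
    if (any(p < 0 | p > 1)) stop("plateau must lie in [0,1]")
    if (c0 <= 0) stop("c0 must be > 0")
    thr <- matrix(NA_real_, n_cells, ns)  # concentration at which methylated
    pre <- matrix(FALSE, n_cells, ns)
    for (ci in seq_len(n_cells)) {
      acc <- stats::runif(ns) < p
      cthr <- c0 * stats::rexp(ns)
      cthr[!acc] <- Inf
      thr[ci, ] <- cthr
      pre[ci, ] <- stats::runif(ns) < f0s
    }
    truth <- matrix(NA_real_, ns, nd)
    for (i in seq_len(nd)) {
      states[, , i] <- pre | (thr <= design[i])
      truth[, i] <- f0s + (1 - f0s) * p * (1 - exp(-design[i] / c0))
    }
  }
  structure(list(mode = mode, states = states, truth = truth, sites = sites,
                 design = design,
                 axis = if (mode == "in_vivo") "time_min" else "conc_nM",
                 cells = cells,
                 params = list(rate = rate, plateau = plateau, c0 = c0, f0 = f0,
                               half_time = half_time, sigma_cell = sigma_cell),
                 seed = seed),
            class = "meth_states")
}

#' @export
print.meth_states <- function(x, ...) {
  cat("<meth_states> mode:", x$mode, "|", dim(x$states)[1], "cells x",
      dim(x$states)[2], "sites x", dim(x$states)[3], "design points (",
      x$axis, ":", paste(x$design, collapse = ", "), ")\n")
  invisible(x)
}

#' Realized per-site methylated fractions
#'
#' @param ms A \code{meth_states} object.
#' @return Matrix site x design point: methylated cells / n_cells.
#' @export
realized_fractions <- function(ms) {
  d <- dim(ms$states)
  out <- vapply(seq_len(d[3]),
                function(i) colMeans(matrix(ms$states[, , i], d[1], d[2])),
                numeric(d[2]))
  out <- matrix(out, d[2], d[3])
  colnames(out) <- as.character(ms$design)
  out
}

#' Ground-truth table of true methylated fractions
#'
#' @param ms A \code{meth_states} object.
#' @return data.frame: site keys plus one \code{frac_<design>} column per
#'   design point with the realized methylated fraction.
#' @export
ground_truth_table <- function(ms) {
  fr <- realized_fractions(ms)
  out <- ms$sites[, c("chrom", "start", "midpoint")]
  for (i in seq_len(ncol(fr)))
    out[[paste0("frac_", colnames(fr)[i])]] <- fr[, i]
  out
}

#' Use simulated methylated fractions as fcut tables
#'
#' Convenience glue: packages the simulator's per-site fractions (realized by
#' default, expected optionally) as one fcut table per design point so that
#' the kinetics and phasing stages can be driven directly from ground truth.
#'
#' @param ms A \code{meth_states} object.
#' @param which \code{"realized"} or \code{"expected"}.
#' @return List (one per design point) of data.frames with \code{chrom},
#'   \code{start}, \code{midpoint}, \code{fcut}, \code{status = "ok"}.
#' @export
truth_as_fcut <- function(ms, which = c("realized", "expected")) {
  which <- match.arg(which)
  fr <- if (which == "realized") realized_fractions(ms) else ms$truth
  lapply(seq_len(ncol(fr)), function(i) {
    data.frame(chrom = ms$sites$chrom, start = ms$sites$start,
               midpoint = ms$sites$midpoint, fcut = fr[, i],
               status = "ok", stringsAsFactors = FALSE)
  })
}

#' Fragmentation parameters
#'
#' @param mean_len Mean sonication fragment length L (bp); sonication
#'   breakpoints fall at each inter-base boundary independently with
#'   probability 1/L (discrete Poisson process).
#' @param recover_lo,recover_hi Recovery ramp (bp): retention probability
#'   rises linearly from 0 at \code{recover_lo} to 1 at \code{recover_hi}
#'   (defaults give ~50\% recovery at 200 bp, emulating inefficient recovery
#'   of short fragments). Set both to 0 to retain everything.
#' @param term_loss Probability q that a DpnI-cut end loses its terminal base
#'   (the A of the left fragment / the T of the right fragment) during
#'   library preparation; applied independently per end, never at sonication
#'   ends.
#' @return List of class \code{frag_params}.
#' @export
frag_params <- function(mean_len = 350, recover_lo = 100, recover_hi = 300,
                        term_loss = 0.3) {
  if (mean_len <= 0) stop("mean_len must be > 0")
  if (term_loss < 0 || term_loss > 1) stop("term_loss must be in [0,1]")
  if (recover_lo > recover_hi) stop("recover_lo must be <= recover_hi")
  structure(list(mean_len = mean_len, recover_lo = recover_lo,
                 recover_hi = recover_hi, term_loss = term_loss),
            class = "frag_params")
}

.recovery_prob <- function(len, lo, hi) {
  if (hi <= 0) return(rep(1, length(len)))
  if (hi == lo) return(as.numeric(len >= hi))
  pmin(1, pmax(0, (len - lo) / (hi - lo)))
}

.sonication_breaks <- function(len, mean_len) {
  # independent break at each of the len-1 inter-base boundaries with
  # probability 1/L: equivalently a binomial count with uniform positions
  p <- min(1 / mean_len, 1)
  nb <- stats::rbinom(1, len - 1L, p)
  if (nb == 0) return(integer(0))
  sort(sample.int(len - 1L, nb))
}

#' Fragment simulated molecules by DpnI cutting and sonication
#'
#' One molecule per (cell, chromosome, design point): the molecule is cut at
#' the blunt boundary (between A and T) of every methylated GATC, then broken
#' by sonication at rate \code{1/mean_len}; each fragment is retained with a
#' probability from the recovery ramp, and each DpnI end independently loses
#' its terminal base with probability \code{term_loss} (left fragments then
#' end on the G, right fragments start on the C).
#'
#' @param ms A \code{meth_states} object.
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param frag \code{\link{frag_params}}.
#' @param points Design-point indices to fragment (default all).
#' @param cells Cell indices to fragment (default all).
#' @param seed Integer seed.
#' @return data.frame with \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open), \code{cell}, \code{point} (design-point index); warns and
#'   returns zero rows if nothing is retained.
#' @export
fragmentize <- function(ms, chrom_sizes, frag = frag_params(),
                        points = seq_along(ms$design),
                        cells = seq_len(dim(ms$states)[1]), seed) {
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  points <- as.integer(points)
  cells <- as.integer(cells)
  site_idx <- split(seq_len(nrow(ms$sites)), ms$sites$chrom)
  q <- frag$term_loss
  acc <- vector("list", length(points) * length(cells) * length(site_idx))
  k <- 0L
  for (i in points) {
    for (ci in cells) {
      for (chr in names(site_idx)) {
        len <- unname(chrom_sizes[chr])
        if (is.na(len)) stop("chrom_sizes missing for ", chr)
        idx <- site_idx[[chr]]
        cuts <- ms$sites$midpoint[idx][ms$states[ci, idx, i]]
        son <- .sonication_breaks(len, frag$mean_len)
        b <- sort(unique(c(0, son, cuts, len)))
        is_cut <- b %in% cuts
        st <- b[-length(b)]
        en <- b[-1]
        right_is_dpn <- is_cut[-1]
        left_is_dpn <- is_cut[-length(b)]
        if (q > 0) {
          en <- en - as.integer(right_is_dpn & stats::runif(length(en)) < q)
          st <- st + as.integer(left_is_dpn & stats::runif(length(st)) < q)
        }
        flen <- en - st
        keep <- flen >= 1 &
          stats::runif(length(st)) < .recovery_prob(flen, frag$recover_lo,
                                                    frag$recover_hi)
        if (any(keep)) {
          k <- k + 1L
          acc[[k]] <- list(chrom = chr, start = as.integer(st[keep]),
                           end = as.integer(en[keep]), cell = ci, point = i)
        }
      }
    }
  }
  if (k == 0L) {
    warning("no fragments retained")
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      cell = integer(), point = integer()))
  }
  acc <- acc[seq_len(k)]
  nfr <- vapply(acc, function(a) length(a$start), integer(1))
  data.frame(
    chrom = rep(vapply(acc, `[[`, character(1), "chrom"), nfr),
    start = unlist(lapply(acc, `[[`, "start"), use.names = FALSE),
    end = unlist(lapply(acc, `[[`, "end"), use.names = FALSE),
    cell = rep(vapply(acc, `[[`, integer(1), "cell"), nfr),
    point = rep(vapply(acc, `[[`, integer(1), "point"), nfr),
    stringsAsFactors = FALSE)
}

#' Write fragments as degenerate BEDPE
#'
#' Both mate blocks carry the full fragment interval.
#' @param frags data.frame with \code{chrom}, \code{start}, \code{end}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bedpe <- function(frags, path) {
  utils::write.table(
    data.frame(frags$chrom, frags$start, frags$end,
               frags$chrom, frags$start, frags$end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Emit Nanopolish-style per-read CpG methylation calls
#'
#' One long read per (cell, chromosome) at one design point. CG sites closer
#' than \code{group_gap} bp are merged into one call row (num_motifs > 1),
#' mirroring proximity grouping in Nanopolish output. A group is called from
#' the majority state of its member CGs on that molecule; the log-likelihood
#' ratio magnitude is |Normal(llr_scale, 1)|, positive for methylated truth,
#' and the sign is flipped with probability \code{error_rate}.
#'
#' @param ms A \code{meth_states} object over CG sites.
#' @param genome \code{DNAStringSet} (or named character) used for the
#'   sequence-context column.
#' @param point Design-point index.
#' @param llr_scale Mean |log-likelihood ratio|.
#' @param error_rate Probability of flipping a call's sign.
#' @param group_gap CG sites with C positions closer than this are grouped.
#' @param seed Integer seed.
#' @return data.frame in Nanopolish methylation-call layout: chromosome,
#'   strand, start, end, read_name, log_lik_ratio, log_lik_methylated,
#'   log_lik_unmethylated, num_calling_strands, num_motifs, sequence.
#' @export
emit_longread_calls <- function(ms, genome, point = 1, llr_scale = 5,
                                error_rate = 0, group_gap = 10, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (!all(ms$sites$motif == "CG"))
    stop("long-read call emission requires CG sites")
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  set.seed(seed)
  n_cells <- dim(ms$states)[1]
  site_idx <- split(seq_len(nrow(ms$sites)), ms$sites$chrom)
  rows <- list()
  r <- 0L
  for (chr in names(site_idx)) {
    idx <- site_idx[[chr]]
    pos <- ms$sites$start[idx]                       # 0-based C positions
    grp <- cumsum(c(1L, as.integer(diff(pos) >= group_gap)))
    g_first <- tapply(pos, grp, min)
    g_last <- tapply(pos, grp, max)
    g_n <- as.integer(table(grp))
    chr_str <- as.character(genome[[chr]])
    ctx <- substring(chr_str,
                     pmax(g_first + 1L - 5L, 1L),
                     pmin(g_last + 2L + 5L, nchar(chr_str)))
    members <- split(idx, grp)
    for (ci in seq_len(n_cells)) {
      meth <- vapply(members, function(m) mean(ms$states[ci, m, point]) >= 0.5,
                     logical(1))
      mag <- abs(stats::rnorm(length(meth), llr_scale, 1))
      sgn <- ifelse(meth, 1, -1)
      flip <- stats::runif(length(meth)) < error_rate
      sgn[flip] <- -sgn[flip]
      llr <- sgn * mag
      r <- r + 1L
      rows[[r]] <- data.frame(
        chromosome = chr, strand = "+",
        start = as.integer(g_first), end = as.integer(g_last),
        read_name = sprintf("sim_p%d_c%05d_%s", point, ci, chr),
        log_lik_ratio = llr,
        log_lik_methylated = llr / 2, log_lik_unmethylated = -llr / 2,
        num_calling_strands = 1L, num_motifs = g_n,
        sequence = ctx, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
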