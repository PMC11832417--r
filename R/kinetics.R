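# Group-level methylation series, first-order rate fits, limit-digest
# plateau fits, replicate concordance and the induction-linearity check.
#
# The apparent rate constant k of a site group is the negative slope of
# ln(median unmethylated fraction) against time; the limit digest is the
# plateau of median fcut against enzyme concentration.

.GOOD_STATUS <- c("ok", "substituted_left", "substituted_right")

#' Aggregate fcut into a group-level methylation series
#'
#' At each design point, the median and quartiles (linear interpolation,
#' type 7) of fcut are taken over the non-excluded sites of each group.
#'
#' @param fcut_list List of per-design-point fcut tables (columns
#'   \code{chrom}, \code{start}, \code{fcut}, \code{status}).
#' @param design Design-axis values, same length as \code{fcut_list}.
#' @param sites Site table carrying the grouping column.
#' @param group_by Column of \code{sites} to group by (e.g.
#'   \code{"region_class"}, \code{"decile"}, \code{"gene_id"}).
#' @param axis Name for the design axis column (\code{"time_min"} or
#'   \code{"conc_nM"}).
#' @param good_status Statuses retained.
#' @return data.frame: \code{group}, axis value, \code{median_fcut},
#'   \code{q25}, \code{q75}, \code{n_sites}, \code{u = 1 - median_fcut}.
#' @export
group_series <- function(fcut_list, design, sites, group_by = "region_class",
                         axis = "time_min", good_status = .GOOD_STATUS) {
  stopifnot(length(fcut_list) == length(design))
  if (!group_by %in% names(sites))
    stop("sites has no column '", group_by, "'")
  key <- paste(sites$chrom, sites$start)
  rows <- list()
  for (i in seq_along(design)) {
    f <- fcut_list[[i]]
    j <- match(paste(f$chrom, f$start), key)
    keep <- !is.na(j) & f$status %in% good_status & !is.na(f$fcut)
    g <- as.character(sites[[group_by]][j[keep]])
    v <- f$fcut[keep]
    keep2 <- !is.na(g)
    g <- g[keep2]; v <- v[keep2]
    if (!length(v)) next
    med <- tapply(v, g, stats::median)
    q25 <- tapply(v, g, stats::quantile, probs = 0.25, names = FALSE)
    q75 <- tapply(v, g, stats::quantile, probs = 0.75, names = FALSE)
    n <- tapply(v, g, length)
    rows[[i]] <- data.frame(group = names(med), axis_value = design[i],
                            median_fcut = as.numeric(med),
                            q25 = as.numeric(q25), q75 = as.numeric(q75),
                            n_sites = as.integer(n), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable sites in any design point")
  names(out)[names(out) == "axis_value"] <- axis
  out$u <- 1 - out$median_fcut
  rownames(out) <- NULL
  out
}

#' Fit an apparent first-order methylation rate constant
#'
#' Ordinary least squares of \code{ln(u)} on time over the retained points;
#' \code{k} is the negative slope (per minute). Points with \code{u} below
#' \code{u_min} are excluded (log blow-up near complete methylation);
#' non-positive \code{u} at a retained point is dropped with a warning.
#'
#' @param time Time in minutes.
#' @param u Unmethylated fraction (1 - median fcut).
#' @param u_min Retention threshold on \code{u}.
#' @return List of class \code{rate_fit}: \code{k}, \code{se_k},
#'   \code{intercept}, \code{r_squared}, \code{n_points}.
#' @export
fit_rate <- function(time, u, u_min = 0.05) {
  stopifnot(length(time) == length(u))
  keep <- !is.na(u) & u >= u_min
  if (any(u[keep] <= 0)) {
    warning("dropping point(s) with non-positive unmethylated fraction")
    keep <- keep & u > 0
  }
  if (sum(keep) < 3)
    stop("need at least 3 usable points to fit a rate, got ", sum(keep))
  t <- time[keep]
  y <- log(u[keep])
  fit <- stats::lm(y ~ t)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))  # noiseless series fit exactly
  r2 <- if (stats::var(y) > 0) sm$r.squared else NA_real_
  structure(list(k = -unname(cf[2]), se_k = unname(sm$coefficients[2, 2]),
                 intercept = unname(cf[1]), r_squared = r2,
                 n_points = sum(keep)),
            class = "rate_fit")
}

#' Fit rates for every group of a time series
#'
#' @param series Output of \code{\link{group_series}} with a
#'   \code{time_min} axis.
#' @param u_min Passed to \code{\link{fit_rate}}.
#' @return data.frame: \code{group}, \code{k}, \code{se_k},
#'   \code{intercept}, \code{r_squared}, \code{n_points}.
#' @export
fit_rates <- function(series, u_min = 0.05) {
  if (!"time_min" %in% names(series)) stop("series must have a time_min axis")
  groups <- unique(series$group)
  rows <- lapply(groups, function(g) {
    s <- series[series$group == g, ]
    f <- fit_rate(s$time_min, s$u, u_min = u_min)
    data.frame(group = g, k = f$k, se_k = f$se_k, intercept = f$intercept,
               r_squared = f$r_squared, n_points = f$n_points,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ratio of two apparent rate constants
#'
#' Standard error by first-order (delta-method) propagation:
#' \code{(kA/kB) * sqrt((seA/kA)^2 + (seB/kB)^2)}.
#'
#' @param fit_a,fit_b \code{rate_fit} objects (numerator / denominator).
#' @return List with \code{ratio} and \code{se}.
#' @export
rate_ratio <- function(fit_a, fit_b) {
  if (fit_b$k == 0) stop("undefined ratio: denominator rate is zero")
  ratio <- fit_a$k / fit_b$k
  se <- abs(ratio) * sqrt((fit_a$se_k / fit_a$k)^2 + (fit_b$se_k / fit_b$k)^2)
  list(ratio = ratio, se = se)
}

#' Fit a limit-digest plateau to a concentration series
#'
#' Nonlinear least squares of the saturating exponential
#' \code{f(c) = f_bg + (f_max - f_bg) * (1 - exp(-c/c0))} with bounds
#' \code{0 <= f_bg, f_max <= 1}; on non-convergence (or a series decreasing
#' beyond \code{noise_tol}) the plateau falls back to the mean of the two
#' highest-concentration values, with the method recorded.
#'
#' @param conc Concentrations (nM), at least 4 including 0.
#' @param f Median fcut at each concentration.
#' @param noise_tol Allowed non-monotonicity before warning + fallback.
#' @return List of class \code{plateau_fit}: \code{f_max}, \code{c0},
#'   \code{f_bg}, \code{method} (\code{"nls"} or \code{"top2_mean"}),
#'   \code{resid_norm}.
#' @export
fit_plateau <- function(conc, f, noise_tol = 0.05) {
  stopifnot(length(conc) == length(f))
  if (length(conc) < 4) stop("need at least 4 concentrations")
  if (!any(conc == 0)) stop("the concentration series must include 0")
  o <- order(conc)
  fallback <- function() {
    top <- order(conc, decreasing = TRUE)[1:2]
    structure(list(f_max = mean(f[top]), c0 = NA_real_,
                   f_bg = f[which.min(conc)], method = "top2_mean",
                   resid_norm = NA_real_),
              class = "plateau_fit")
  }
  if (any(diff(f[o]) < -noise_tol)) {
    warning("series decreases beyond noise tolerance; using top2_mean fallback")
    return(fallback())
  }
  st <- list(f_bg = max(f[which.min(conc)], 1e-4),
             f_max = max(f), c0 = max(mean(conc[conc > 0]) / 3, 1e-3))
  fit <- try(minpack.lm::nlsLM(
    f ~ f_bg + (f_max - f_bg) * (1 - exp(-conc / c0)),
    start = st, lower = c(0, 0, 1e-9), upper = c(1, 1, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) return(fallback())
  cf <- stats::coef(fit)
  if (cf["f_bg"] > cf["f_max"]) return(fallback())
  structure(list(f_max = unname(cf["f_max"]), c0 = unname(cf["c0"]),
                 f_bg = unname(cf["f_bg"]), method = "nls",
                 resid_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "plateau_fit")
}

#' Pearson concordance between replicate fcut tables
#'
#' @param a,b fcut tables (columns \code{chrom}, \code{start}, \code{fcut},
#'   \code{status}).
#' @param good_status Statuses retained in both replicates.
#' @param min_shared Minimum number of shared usable sites.
#' @return List with \code{r} and \code{n}.
#' @export
replicate_concordance <- function(a, b, good_status = .GOOD_STATUS,
                                  min_shared = 100) {
  i <- match(paste(a$chrom, a$start), paste(b$chrom, b$start))
  keep <- !is.na(i) & a$status %in% good_status &
    b$status[i] %in% good_status & !is.na(a$fcut) & !is.na(b$fcut[i])
  x <- a$fcut[keep]
  y <- b$fcut[i[keep]]
  if (length(x) < min_shared)
    stop("only ", length(x), " shared usable sites (need >= ", min_shared, ")")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate variance in one replicate")
  list(r = stats::cor(x, y), n = length(x))
}

#' Regress population methylation on the induced-cell fraction
#'
#' When per-cell methylation is much faster than induction, the population
#' median methylation is directly proportional to the fraction of induced
#' (enzyme-positive) cells; slow per-cell kinetics breaks the linearity.
#'
#' @param median_fcut Population median methylation per timepoint.
#' @param induced_fraction Fraction of induced cells at matched timepoints.
#' @return List with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{n}.
#' @export
induction_linearity <- function(median_fcut, induced_fraction) {
  stopifnot(length(median_fcut) == length(induced_fraction))
  if (length(median_fcut) < 3) stop("need at least 3 matched timepoints")
  fit <- stats::lm(median_fcut ~ induced_fraction)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       r_squared = suppressWarnings(summary(fit))$r.squared,
       n = length(median_fcut))
}

#' Empirical induced-cell fraction of a simulation
#'
#' @param ms An in-vivo \code{meth_states} object.
#' @param times Timepoints (minutes), default the design axis.
#' @return Fraction of cells whose induction delay is at most each time.
#' @export
induced_fraction <- function(ms, times = ms$design) {
  if (ms$mode != "in_vivo") stop("induced_fraction requires an in-vivo simulation")
  vapply(times, function(t) mean(ms$cells$tau <= t), numeric(1))
}
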