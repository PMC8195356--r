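# DIP-rate analysis of cFP datasets. The drug-induced proliferation (DIP)
# rate is the stable slope of log2 cell count vs time reached after
# extended drug exposure; per-colony DIP rates compiled over a cFP assay
# form the clonal drug-response distribution.

count_at_treatment <- function(trace, treatment_time) {
  idx <- which(trace$times <= treatment_time)
  if (length(idx) == 0L) {
    stop(sprintf("colony %s has no sample at or before treatment time",
                 trace$colony_id), call. = FALSE)
  }
  trace$counts[max(idx)]
}

#' Filter colonies by size at treatment
#'
#' Retains colonies with at least `min_cells` cells at the time of
#' treatment (the study's quality-control threshold of 50 cells), using the
#' count at the nearest sampled time at or before `treatment_time`.
#'
#' @param dataset a [cfp_dataset()].
#' @param min_cells threshold, default 50.
#' @return A filtered [cfp_dataset()] preserving order and metadata.
#' @export
filter_colonies <- function(dataset, min_cells = 50) {
  stopifnot(inherits(dataset, "cfp_dataset"))
  keep <- vapply(dataset$traces, function(tr) {
    count_at_treatment(tr, dataset$treatment_time) >= min_cells
  }, logical(1))
  out <- dataset
  out$traces <- dataset$traces[keep]
  out$metadata$n_filtered_out <-
    (dataset$metadata$n_filtered_out %||% 0L) + sum(!keep)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# OLS of log2(count) on time over [wstart, wend]. Zero counts inside the
# window truncate it at the last positive count (an extinct colony has no
# log2 count to regress on); fewer than 2 positive points flags a
# missing-value estimate rather than failing.
dip_ols <- function(times, counts, wstart, wend) {
  sel <- which(times >= wstart & times <= wend)
  if (length(sel) >= 2L) {
    z <- which(counts[sel] <= 0)
    if (length(z) > 0L) sel <- sel[seq_len(min(z) - 1L)]
  }
  if (length(sel) < 2L) {
    return(list(dip_rate = NA_real_, intercept = NA_real_,
                stderr = NA_real_, n_points = length(sel), ok = FALSE))
  }
  x <- times[sel]
  y <- log2(counts[sel])
  n <- length(sel)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  se <- if (n > 2L) sqrt(sum(res^2) / (n - 2L) / sxx) else NA_real_
  list(dip_rate = slope, intercept = intercept, stderr = se,
       n_points = n, ok = TRUE)
}

#' Estimate the DIP rate of one colony
#'
#' Ordinary least-squares slope of `log2(count)` versus time over the
#' requested window, in log2 cells per hour.
#'
#' @param trace a [colony_trace()].
#' @param window_start,window_end regression window in hours.
#' @return A `dip_estimate`: colony_id, dip_rate, intercept, stderr,
#'   window, n_points, and `ok = FALSE` when fewer than two positive counts
#'   remain in the window.
#' @export
estimate_dip <- function(trace, window_start, window_end) {
  stopifnot(inherits(trace, "colony_trace"), window_start < window_end)
  fit <- dip_ols(trace$times, trace$counts, window_start, window_end)
  structure(c(list(colony_id = trace$colony_id,
                   window = c(window_start, window_end)), fit),
            class = "dip_estimate")
}

#' Per-colony DIP rates of a cFP dataset
#'
#' One DIP rate per colony. The `"simulated"` window rule regresses from
#' the time of drug addition to the end of the series (the in-silico
#' convention); the `"experimental"` rule starts 48 h post-treatment, when
#' the transient response has settled. Colonies with fewer than two
#' positive counts in the window are dropped and counted.
#'
#' @param dataset a (typically filtered) [cfp_dataset()].
#' @param window_rule `"simulated"` or `"experimental"`.
#' @param group_label label for the distribution; defaults to dataset
#'   metadata, else "group".
#' @param post_treatment_lag lag of the experimental window, default 48 h.
#' @return A [dip_distribution()].
#' @export
compile_dip_distribution <- function(dataset,
                                     window_rule = c("simulated",
                                                     "experimental"),
                                     group_label = NULL,
                                     post_treatment_lag = 48) {
  stopifnot(inherits(dataset, "cfp_dataset"))
  window_rule <- match.arg(window_rule)
  if (length(dataset$traces) == 0L) {
    stop("empty dataset: no colonies to compile", call. = FALSE)
  }
  wstart <- dataset$treatment_time +
    if (window_rule == "experimental") post_treatment_lag else 0
  rates <- vapply(dataset$traces, function(tr) {
    dip_ols(tr$times, tr$counts, wstart, max(tr$times))$dip_rate
  }, numeric(1))
  ids <- vapply(dataset$traces, `[[`, character(1), "colony_id")
  ok <- !is.na(rates)
  dip_distribution(rates[ok],
                   group_label = group_label %||%
                     (dataset$metadata$group_label %||% "group"),
                   colony_ids = ids[ok], n_dropped = sum(!ok))
}

#' DIP-rate distribution for one group
#'
#' @param dip_rates numeric vector of per-colony DIP rates (log2/h).
#' @param group_label group identifier.
#' @param colony_ids optional per-rate colony identifiers.
#' @param n_dropped number of colonies dropped as unestimable.
#' @return A `dip_distribution` object.
#' @export
dip_distribution <- function(dip_rates, group_label = "group",
                             colony_ids = NULL, n_dropped = 0L) {
  stopifnot(is.numeric(dip_rates), length(dip_rates) >= 1L,
            all(is.finite(dip_rates)))
  structure(list(group_label = group_label,
                 dip_rates = as.numeric(dip_rates),
                 colony_ids = colony_ids,
                 n_dropped = n_dropped),
            class = "dip_distribution")
}

#' @export
print.dip_distribution <- function(x, ...) {
  cat(sprintf("<dip_distribution> %s: n = %d, median = %.4g log2/h\n",
              x$group_label, length(x$dip_rates), median(x$dip_rates)))
  invisible(x)
}

#' @export
length.dip_distribution <- function(x) length(x$dip_rates)

#' Gaussian kernel density estimate of a DIP-rate distribution
#'
#' Evaluates a Gaussian-kernel density on an even grid spanning the data
#' plus/minus three bandwidths. The default bandwidth is Silverman's rule
#' of thumb.
#'
#' @param dist a [dip_distribution()].
#' @param bandwidth numeric bandwidth or a rule name accepted by
#'   [stats::density()] (default `"nrd0"`, Silverman).
#' @param n grid size, default 512.
#' @return A `density_curve`: grid, density, bandwidth.
#' @export
kde_dip <- function(dist, bandwidth = "nrd0", n = 512) {
  stopifnot(inherits(dist, "dip_distribution"))
  x <- dist$dip_rates
  if (length(x) < 2L) stop("need at least 2 values for a KDE", call. = FALSE)
  if (diff(range(x)) == 0) {
    stop("all DIP rates identical; use a rug or histogram instead",
         call. = FALSE)
  }
  d <- density(x, bw = bandwidth, kernel = "gaussian", n = n, cut = 3)
  structure(list(grid = d$x, density = d$y, bandwidth = d$bw),
            class = "density_curve")
}

#' Count local maxima of a density curve
#'
#' Convenience for bimodality checks on compiled DIP distributions.
#'
#' @param curve a `density_curve` from [kde_dip()].
#' @return Integer number of interior local maxima.
#' @export
n_modes <- function(curve) {
  y <- curve$density
  sum(diff(sign(diff(y))) == -2)
}

#' Population-level growth summary across replicate wells
#'
#' Per time point, the mean across replicates of
#' `log2(count / count_at_treatment)` with a Student-t 95% confidence
#' interval, mirroring population-level DIP rate assays where each
#' replicate is a whole well seeded with thousands of cells.
#'
#' @param replicates list of [colony_trace()] objects sharing one time grid.
#' @param treatment_time normalization time in hours.
#' @param conf confidence level, default 0.95.
#' @return A data.frame: time_h, mean_log2norm, ci_lo, ci_hi, n.
#' @export
population_growth_summary <- function(replicates, treatment_time,
                                      conf = 0.95) {
  stopifnot(is.list(replicates), length(replicates) >= 1L,
            all(vapply(replicates, inherits, logical(1), "colony_trace")))
  times <- replicates[[1L]]$times
  same <- vapply(replicates, function(tr) identical(tr$times, times),
                 logical(1))
  if (!all(same)) stop("replicates must share sampling times", call. = FALSE)
  it <- which(times <= treatment_time)
  if (length(it) == 0L) stop("no sample at or before treatment", call. = FALSE)
  it <- max(it)
  norm <- vapply(replicates, function(tr) {
    log2(tr$counts / tr$counts[it])
  }, numeric(length(times)))
  norm <- matrix(norm, nrow = length(times))
  m <- rowMeans(norm)
  n <- ncol(norm)
  se <- if (n > 1L) apply(norm, 1L, sd) / sqrt(n) else rep(0, length(times))
  tq <- if (n > 1L) qt(1 - (1 - conf) / 2, df = n - 1L) else 0
  data.frame(time_h = times, mean_log2norm = m,
             ci_lo = m - tq * se, ci_hi = m + tq * se, n = n)
}

#' Mood's median test across DIP-rate distributions
#'
#' Nonparametric test of equal medians: counts per group strictly above
#' versus at-or-below the pooled grand median, compared by a Pearson
#' chi-square without continuity correction on the 2 x k table
#' (df = k - 1). Ties at the grand median stay in the lower cell.
#'
#' @param groups list of [dip_distribution()] objects or numeric vectors.
#' @return A list: statistic (chi-square), df, p_value, grand_median,
#'   table.
#' @export
moods_median_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  vals <- lapply(groups, function(g) {
    if (inherits(g, "dip_distribution")) g$dip_rates else as.numeric(g)
  })
  if (any(lengths(vals) == 0L)) stop("empty group", call. = FALSE)
  gm <- median(unlist(vals))
  above <- vapply(vals, function(v) sum(v > gm), numeric(1))
  below <- lengths(vals) - above
  tab <- rbind(above = above, at_or_below = below)
  if (any(rowSums(tab) == 0)) {
    stop("degenerate table: all values on one side of the grand median",
         call. = FALSE)
  }
  if (any(above == 0 & below == 0)) stop("empty group", call. = FALSE)
  if (any(above == lengths(vals)) || any(above == 0)) {
    # a group entirely on one side of the grand median is legitimate but
    # worth flagging: expected counts may be small
    if (any(vapply(vals, function(v) all(v == gm), logical(1)))) {
      warning("a group lies entirely at the grand median", call. = FALSE)
    }
  }
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- ncol(tab) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       grand_median = gm, table = tab)
}
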