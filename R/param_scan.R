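# Parameter scans: in-silico cFP batteries over grids of post-treatment
# division/death rate constants, each cell compared to an experimental
# DIP-rate distribution with the bootstrapped Anderson-Darling rule
# <p> - sdev(p) > alpha. Pre-treatment rates stay at the untreated values;
# treatment is modeled purely as a change in rate constants.

#' Untreated proliferation rate constants
#'
#' The vehicle-control (drug-free) division and death rate constants used
#' for the expansion phase of every in-silico cFP assay:
#' `k_div = 0.04 * ln(2)`, `k_dth = 0.005 * ln(2)` per hour (net growth
#' 0.035 log2/h).
#'
#' @param label state label, default "untreated".
#' @return A [bd_state()].
#' @export
untreated_state <- function(label = "untreated") {
  bd_state(label, k_div = 0.04 * log(2), k_dth = 0.005 * log(2))
}

#' Default rate-constant grid for parameter scans
#'
#' Physiologically plausible division/death rate constants: 0 to
#' `0.06 * ln(2)` per hour in steps of `step * ln(2)` (default 0.0025,
#' i.e. a 25-point axis).
#'
#' @param step grid step in units of ln(2) per hour.
#' @param max upper bound in units of ln(2) per hour.
#' @return Numeric vector of rate constants (h^-1).
#' @export
default_rate_grid <- function(step = 0.0025, max = 0.06) {
  seq(0, max, by = step) * log(2)
}

# Deterministic cell seed derived from the cell's rate constants (not its
# position in the grid), so identical parameter combinations get identical
# streams across differently-shaped scans.
cell_counter <- function(rates) {
  enc <- round(rates / log(2) * 1e4)
  stopifnot(all(enc >= 0), all(enc < 4096))
  r <- c(enc, numeric(4L - length(enc)))
  ((r[1] * 4096 + r[2]) * 4096 + r[3]) * 4096 + r[4]
}

net_dip <- function(k_div, k_dth) (k_div - k_dth) / log(2)

# Simulate, filter, compile and compare one scan cell.
evaluate_scan_cell <- function(pre_states, post_states, founder_fractions,
                               protocol, n_colonies, exp_rates,
                               n_resamples, alpha, min_cells, cell_seed) {
  model <- bd_model(pre_states, founder_fractions)
  protocol$treatment_model <- bd_model(post_states, founder_fractions)
  sim <- battery_matrix(model, protocol, n_colonies, cell_seed)
  times <- protocol$sampling_times
  t_treat <- protocol$expansion_hours
  it <- max(which(times <= t_treat))
  keep <- which(sim$counts[it, ] >= min_cells)
  dips <- vapply(keep, function(j) {
    dip_ols(times, sim$counts[, j], t_treat, max(times))$dip_rate
  }, numeric(1))
  dips <- dips[!is.na(dips)]
  if (length(dips) < 2L) {
    return(list(p_mean = NA_real_, p_sd = NA_real_, passed = FALSE,
                evaluable = FALSE, n_sim = length(dips)))
  }
  bc <- bootstrap_ad(dips, exp_rates, n_resamples = n_resamples,
                     alpha = alpha, seed = derive_seed(cell_seed, 1))
  list(p_mean = bc$p_mean, p_sd = bc$p_sd, passed = bc$passed,
       evaluable = TRUE, n_sim = length(dips))
}

exp_rates_of <- function(experimental) {
  if (inherits(experimental, "dip_distribution")) {
    experimental$dip_rates
  } else {
    as.numeric(experimental)
  }
}

#' One-state parameter scan against an experimental DIP distribution
#'
#' For every `(k_div, k_dth)` combination: run a cFP battery with the same
#' number of colonies as the experiment, filter colonies (>= `min_cells`
#' at treatment), compile simulated-window DIP rates, and compare to the
#' experimental distribution with [bootstrap_ad()]. Cells whose battery
#' yields fewer than two usable colonies are marked unevaluable, a state
#' distinct from failed.
#'
#' @param experimental a [dip_distribution()] (or numeric vector) of
#'   experimental DIP rates.
#' @param kdiv_grid,kdth_grid post-treatment rate-constant grids (h^-1).
#' @param protocol a [sim_protocol()]; its `treatment_model` is set per
#'   cell. Default: the standard 8-day expansion / 7-day treatment
#'   protocol.
#' @param seed master seed; every cell derives its own substream.
#' @param n_colonies colonies per cell; default the experimental count.
#' @param n_resamples,alpha bootstrap settings, see [bootstrap_ad()].
#' @param min_cells colony-size filter at treatment, default 50.
#' @param pretreatment_state [bd_state()] used before treatment for all
#'   cells, default [untreated_state()].
#' @return A `scan_grid` whose `cells` data.frame has columns k_div,
#'   k_dth, net_dip, p_mean, p_sd, passed, evaluable, n_sim.
#' @export
scan_one_state <- function(experimental,
                           kdiv_grid = default_rate_grid(),
                           kdth_grid = default_rate_grid(),
                           protocol = sim_protocol(),
                           seed = 1,
                           n_colonies = NULL,
                           n_resamples = 100, alpha = 0.05,
                           min_cells = 50,
                           pretreatment_state = untreated_state()) {
  exp_rates <- exp_rates_of(experimental)
  stopifnot(length(exp_rates) >= 2L,
            length(kdiv_grid) >= 1L, length(kdth_grid) >= 1L)
  n_colonies <- n_colonies %||% length(exp_rates)
  cells <- expand.grid(k_div = kdiv_grid, k_dth = kdth_grid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(r) {
    kd <- cells$k_div[r]; kt <- cells$k_dth[r]
    cs <- derive_seed(seed, cell_counter(c(kd, kt)))
    pre <- pretreatment_state
    pre$label <- "s1"
    evaluate_scan_cell(list(pre), list(bd_state("s1", kd, kt)), 1,
                       protocol, n_colonies, exp_rates,
                       n_resamples, alpha, min_cells, cs)
  })
  cells$net_dip <- net_dip(cells$k_div, cells$k_dth)
  for (col in c("p_mean", "p_sd")) {
    cells[[col]] <- vapply(res, `[[`, numeric(1), col)
  }
  cells$passed <- vapply(res, `[[`, logical(1), "passed")
  cells$evaluable <- vapply(res, `[[`, logical(1), "evaluable")
  cells$n_sim <- vapply(res, `[[`, numeric(1), "n_sim")
  structure(list(cells = cells, type = "one_state",
                 axes = list(k_div = kdiv_grid, k_dth = kdth_grid),
                 n_colonies = n_colonies, seed = seed,
                 n_resamples = n_resamples, alpha = alpha,
                 protocol = protocol),
            class = "scan_grid")
}

#' Two-state (4D) parameter scan with mode-range constraint
#'
#' Scans two post-treatment `(k_div, k_dth)` pairs jointly, restricted to
#' combinations whose per-state net DIP rate `(k_div - k_dth)/ln 2` lies
#' in its mode's DIP-rate range (one disjoint interval per mode of a
#' bimodal experimental distribution). Batteries mix founders between the
#' two states with probability `founder_fraction` for state 1.
#'
#' @inheritParams scan_one_state
#' @param kdiv1_grid,kdth1_grid,kdiv2_grid,kdth2_grid rate grids (h^-1).
#' @param mode_ranges list of two disjoint numeric intervals (log2/h),
#'   one per DIP-distribution mode.
#' @param founder_fraction probability a founder is state 1, default 0.5.
#' @return A `scan_grid` with columns k_div1, k_dth1, k_div2, k_dth2 plus
#'   the comparison columns of [scan_one_state()].
#' @export
scan_two_state <- function(experimental,
                           kdiv1_grid = default_rate_grid(),
                           kdth1_grid = default_rate_grid(),
                           kdiv2_grid = default_rate_grid(),
                           kdth2_grid = default_rate_grid(),
                           mode_ranges,
                           founder_fraction = 0.5,
                           protocol = sim_protocol(),
                           seed = 1,
                           n_colonies = NULL,
                           n_resamples = 100, alpha = 0.05,
                           min_cells = 50,
                           pretreatment_state = untreated_state()) {
  stopifnot(is.list(mode_ranges), length(mode_ranges) == 2L,
            lengths(mode_ranges) == c(2L, 2L),
            founder_fraction >= 0, founder_fraction <= 1)
  r1 <- sort(mode_ranges[[1L]]); r2 <- sort(mode_ranges[[2L]])
  if (max(min(r1), min(r2)) <= min(max(r1), max(r2))) {
    stop("mode_ranges must be disjoint", call. = FALSE)
  }
  exp_rates <- exp_rates_of(experimental)
  n_colonies <- n_colonies %||% length(exp_rates)
  in_range <- function(nd, r) nd >= r[1] & nd <= r[2]
  p1 <- expand.grid(k_div1 = kdiv1_grid, k_dth1 = kdth1_grid,
                    KEEP.OUT.ATTRS = FALSE)
  p1 <- p1[in_range(net_dip(p1$k_div1, p1$k_dth1), r1), , drop = FALSE]
  p2 <- expand.grid(k_div2 = kdiv2_grid, k_dth2 = kdth2_grid,
                    KEEP.OUT.ATTRS = FALSE)
  p2 <- p2[in_range(net_dip(p2$k_div2, p2$k_dth2), r2), , drop = FALSE]
  if (nrow(p1) == 0L || nrow(p2) == 0L) {
    stop("no grid combinations fall inside the mode ranges", call. = FALSE)
  }
  cells <- merge(p1, p2, by = NULL)  # Cartesian product of allowed pairs
  pre1 <- pretreatment_state; pre1$label <- "s1"
  pre2 <- pretreatment_state; pre2$label <- "s2"
  ff <- c(founder_fraction, 1 - founder_fraction)
  res <- lapply(seq_len(nrow(cells)), function(r) {
    rates <- c(cells$k_div1[r], cells$k_dth1[r],
               cells$k_div2[r], cells$k_dth2[r])
    cs <- derive_seed(seed, cell_counter(rates))
    post <- list(bd_state("s1", rates[1], rates[2]),
                 bd_state("s2", rates[3], rates[4]))
    evaluate_scan_cell(list(pre1, pre2), post, ff, protocol, n_colonies,
                       exp_rates, n_resamples, alpha, min_cells, cs)
  })
  for (col in c("p_mean", "p_sd")) {
    cells[[col]] <- vapply(res, `[[`, numeric(1), col)
  }
  cells$passed <- vapply(res, `[[`, logical(1), "passed")
  cells$evaluable <- vapply(res, `[[`, logical(1), "evaluable")
  cells$n_sim <- vapply(res, `[[`, numeric(1), "n_sim")
  structure(list(cells = cells, type = "two_state",
                 axes = list(k_div1 = kdiv1_grid, k_dth1 = kdth1_grid,
                             k_div2 = kdiv2_grid, k_dth2 = kdth2_grid),
                 mode_ranges = list(r1, r2),
                 founder_fraction = founder_fraction,
                 n_colonies = n_colonies, seed = seed,
                 n_resamples = n_resamples, alpha = alpha,
                 protocol = protocol),
            class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("<scan_grid> %s: %d cells, %d passed, %d unevaluable\n",
              x$type, nrow(x$cells), sum(x$cells$passed),
              sum(!x$cells$evaluable)))
  invisible(x)
}

#' Project a two-state scan into two dimensions
#'
#' Each distinct `(k_div, k_dth)` pair appearing in either state role is
#' marked passed when at least one full 4D combination containing it
#' passed, mirroring how 4D scans are displayed as 2D heatmaps.
#'
#' @param scan a two-state `scan_grid`.
#' @return A data.frame: k_div, k_dth, passed.
#' @export
scan_projection <- function(scan) {
  stopifnot(inherits(scan, "scan_grid"))
  if (scan$type != "two_state") {
    stop("projection applies to two-state scans", call. = FALSE)
  }
  cells <- scan$cells
  pairs <- rbind(
    data.frame(k_div = cells$k_div1, k_dth = cells$k_dth1,
               passed = cells$passed),
    data.frame(k_div = cells$k_div2, k_dth = cells$k_dth2,
               passed = cells$passed))
  agg <- aggregate(passed ~ k_div + k_dth, data = pairs, FUN = any)
  agg[order(agg$k_div, agg$k_dth), , drop = FALSE]
}

#' Accepted region of a parameter scan
#'
#' The subset of evaluated cells that passed the `<p> - sdev(p) > alpha`
#' rule, with a count and per-axis bounding box. These are the rate
#' constants producing DIP-rate distributions statistically
#' indistinguishable from the experimental one.
#'
#' @param scan a `scan_grid`.
#' @return A list: cells (data.frame of passing cells), n, bounding_box.
#' @export
accepted_region <- function(scan) {
  stopifnot(inherits(scan, "scan_grid"))
  ok <- scan$cells[scan$cells$passed & scan$cells$evaluable, , drop = FALSE]
  axes <- intersect(c("k_div", "k_dth", "k_div1", "k_dth1",
                      "k_div2", "k_dth2"), names(ok))
  bbox <- if (nrow(ok) > 0L) {
    lapply(setNames(axes, axes), function(a) range(ok[[a]]))
  } else {
    NULL
  }
  list(cells = ok, n = nrow(ok), bounding_box = bbox)
}
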