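make_dataset <- function(counts_at_treat) {
  traces <- lapply(seq_along(counts_at_treat), function(i) {
    colony_trace(sprintf("c%d", i), c(0, 192, 216),
                 c(1, counts_at_treat[i], counts_at_treat[i]))
  })
  cfp_dataset(traces, treatment_time = 192)
}

test_that("colony filter applies the >= min_cells rule at treatment", {
  ds <- make_dataset(c(49, 50, 51))
  expect_equal(length(filter_colonies(ds)), 2L)
  expect_equal(length(filter_colonies(ds, min_cells = 0)), 3L)
  # monotonicity: raising the threshold never retains more colonies
  ds2 <- make_dataset(round(runif(40, 0, 200)))
  kept <- vapply(c(0, 25, 50, 100, 1000), function(m) {
    length(filter_colonies(ds2, min_cells = m))
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
  # count at nearest sampled time <= treatment is used
  late <- cfp_dataset(list(colony_trace("c1", c(0, 180, 240), c(1, 60, 10))),
                      treatment_time = 192)
  expect_equal(length(filter_colonies(late)), 1L)
  none <- cfp_dataset(list(colony_trace("c1", c(200, 240), c(60, 70))),
                      treatment_time = 192)
  expect_error(filter_colonies(none), "c1")
})

test_that("DIP estimation recovers exact slopes of exponential traces", {
  times <- seq(0, 168, 24)
  # counts 100 * 2^(t/24): exact powers of two, slope exactly 1/24
  tr <- colony_trace("c1", times, 100 * 2^(times / 24))
  est <- estimate_dip(tr, 0, 168)
  expect_equal(est$dip_rate, 1 / 24, tolerance = 1e-12)
  expect_equal(est$stderr, 0, tolerance = 1e-9)
  expect_equal(est$n_points, 8L)
  flat <- estimate_dip(colony_trace("c2", times, rep(500, 8)), 0, 168)
  expect_equal(flat$dip_rate, 0)
  for (r in c(-0.01, 0.02, 0.035)) {
    e <- estimate_dip(exp_trace(r, times), 0, 168)
    expect_equal(e$dip_rate, r, tolerance = 1e-5)
  }
})

test_that("zero counts truncate the regression window", {
  times <- seq(0, 96, 24)
  tr <- colony_trace("c1", times, c(100, 50, 0, 0, 25))
  est <- estimate_dip(tr, 0, 96)
  expect_true(est$ok)
  expect_equal(est$n_points, 2L)
  expect_equal(est$dip_rate, -1 / 24, tolerance = 1e-12)
  dead <- estimate_dip(colony_trace("c2", times, c(100, 0, 0, 0, 0)), 0, 96)
  expect_false(dead$ok)
  expect_true(is.na(dead$dip_rate))
})

test_that("compile_dip_distribution applies the window rules", {
  times <- seq(0, 360, 24)
  slopes <- c(-0.01, 0, 0.02)
  traces <- lapply(seq_along(slopes), function(i) {
    exp_trace(slopes[i], times, id = sprintf("c%d", i))
  })
  ds <- cfp_dataset(traces, treatment_time = 0)
  dd <- compile_dip_distribution(ds)
  expect_equal(dd$dip_rates, slopes, tolerance = 1e-5)
  # simulated and experimental rules agree on a pure exponential
  ds192 <- cfp_dataset(list(exp_trace(1 / 24, times, n0 = 100)),
                       treatment_time = 192)
  sim <- compile_dip_distribution(ds192, "simulated")
  ex <- compile_dip_distribution(ds192, "experimental")
  expect_equal(sim$dip_rates, ex$dip_rates, tolerance = 1e-12)
  # a kink at treatment + 48 h: the experimental window sees only the
  # late slope, the simulated window mixes both
  kink <- 240
  counts <- ifelse(times <= kink, 1e6 * 2^(0.02 * times),
                   1e6 * 2^(0.02 * kink - 0.01 * (times - kink)))
  kds <- cfp_dataset(list(colony_trace("c1", times, round(counts))),
                     treatment_time = 192)
  late <- compile_dip_distribution(kds, "experimental")
  expect_equal(late$dip_rates, -0.01, tolerance = 1e-5)
  mixed <- compile_dip_distribution(kds, "simulated")
  expect_gt(mixed$dip_rates, -0.01)
  # dropped colonies are counted; empty dataset errors
  ds_dead <- cfp_dataset(list(exp_trace(0.01, times),
                              colony_trace("cd", times,
                                           c(5, rep(0, 15)))),
                         treatment_time = 0)
  dd2 <- compile_dip_distribution(ds_dead)
  expect_equal(dd2$n_dropped, 1L)
  expect_error(compile_dip_distribution(cfp_dataset(list(),
                                                    treatment_time = 0)),
               "empty")
})

test_that("mean DIP of a filtered battery matches (k_div - k_dth)/ln 2", {
  dd <- quick_experiment(0.04 * ln2, 0.005 * ln2, n_colonies = 900,
                         seed = 21)
  dr <- dd$dip_rates[seq_len(500)]
  expect_lt(abs(mean(dr) - 0.035), 3 * sd(dr) / sqrt(length(dr)))
})

test_that("DIP bias shrinks with founding population size", {
  bias <- vapply(c(1, 20, 400), function(n0) {
    proto <- std_protocol(0.02 * ln2, 0.03 * ln2, initial_cells = n0)
    truth <- cfp_ground_truth(one_state_model(0.04 * ln2, 0.005 * ln2),
                              proto, n_colonies = 300, seed = 17)
    dd <- compile_dip_distribution(
      filter_colonies(generate_cfp_experiment(truth), min_cells = 1))
    abs(mean(dd$dip_rates) - (-0.01))
  }, numeric(1))
  expect_lt(bias[3], bias[1])
  expect_lt(bias[3], 5e-4)
})

test_that("KDE is a normalized Gaussian density on the data +/- 3 bw", {
  sym <- kde_dip(dip_distribution(c(-1, 0, 1)))
  f <- approxfun(sym$grid, sym$density)
  xs <- seq(0, 0.9, by = 0.1)
  expect_lt(max(abs(f(xs) - f(-xs))), 1e-9)
  integral <- sum(diff(sym$grid) *
                    (head(sym$density, -1) + sym$density[-1]) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  expect_equal(max(sym$grid), 1 + 3 * sym$bandwidth, tolerance = 1e-8)
  # well-separated mixture (DS8-like bimodal) has >= 2 modes
  set.seed(5)
  bim <- dip_distribution(c(rnorm(150, -0.01, 0.002),
                            rnorm(100, 0.02, 0.002)))
  expect_gte(n_modes(kde_dip(bim)), 2L)
  expect_error(kde_dip(dip_distribution(rep(0.01, 10))), "identical")
})

test_that("population growth summary normalizes at treatment", {
  times <- seq(0, 240, 24)
  tr <- exp_trace(0.02, times)
  same <- population_growth_summary(list(tr, tr, tr), treatment_time = 48)
  expect_equal(same$ci_lo, same$ci_hi)  # zero-width CI for identical wells
  at <- same[same$time_h == 48, ]
  expect_equal(at$mean_log2norm, 0)
  reps <- generate_population_assay(one_state_model(0.04 * ln2, 0.005 * ln2),
                                    n_replicates = 4, n0 = 2500,
                                    sampling_times = seq(0, 240, 12),
                                    treatment_time = 24, seed = 31)
  ps <- population_growth_summary(reps, treatment_time = 24)
  slope <- coef(lm(mean_log2norm ~ time_h,
                   data = ps[ps$time_h >= 24, ]))[["time_h"]]
  expect_equal(slope, 0.035, tolerance = 0.01)
  bad <- colony_trace("b", seq(0, 240, 48), rep(10, 6))
  expect_error(population_growth_summary(list(tr, bad), 24),
               "share sampling times")
})

test_that("Mood's median test matches the contingency-table oracle", {
  m <- moods_median_test(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(m$statistic, 6)
  expect_equal(m$df, 1L)
  expect_equal(m$p_value, 0.0143, tolerance = 1e-3)
  expect_equal(unname(m$table[1, ]), c(0, 3))
  expect_equal(unname(m$table[2, ]), c(3, 0))
  same <- moods_median_test(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  for (case in 1:100) {
    set.seed(case + 300)
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(i) {
      round(rnorm(sample(6:25, 1)), 1)  # rounding forces ties
    })
    got <- moods_median_test(groups)
    want <- oracle_moods(groups)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})
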