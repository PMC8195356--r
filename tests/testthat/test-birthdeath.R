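test_that("constructors reject invalid models and protocols", {
  expect_error(bd_state("s1", -0.1, 0), "non-negative")
  expect_error(bd_state("s1", 0.1, -1e-9), "non-negative")
  expect_error(bd_model(list(bd_state("a", 1, 0), bd_state("b", 1, 0)),
                        c(0.7, 0.7)), "sum to 1")
  expect_error(sim_protocol(sampling_times = numeric(0)), "non-empty")
  expect_error(sim_protocol(sampling_times = c(0, 48, 48)),
               "strictly increasing")
  expect_error(sim_protocol(expansion_hours = 500,
                            sampling_times = seq(0, 360, 24)),
               "outside sampling range")
  expect_error(simulate_ssa(one_state_model(1, 0), "nope",
                            std_protocol(1, 0), seed = 1),
               "founder_state")
  expect_error(simulate_cfp_battery(one_state_model(1, 0),
                                    sim_protocol(NULL), 5, seed = 1),
               "treatment_model")
})

test_that("closed-form oracles evaluate their formulas", {
  st <- untreated_state()
  # E[N(t)] = 2^(0.035 t): ~105.5 cells after the 8-day expansion
  expect_equal(expected_count(st, 1, 192), 2^(0.035 * 192))
  expect_equal(expected_count(st, 1, 192), 105.4, tolerance = 1e-3)
  expect_equal(expected_count(st, 7, 0), 7)
  eq <- bd_state("eq", 0.3, 0.3)
  expect_equal(expected_count(eq, 5, 123), 5)
  # extinction: alpha(t) and its t = Inf limit k_dth / k_div
  expect_equal(extinction_prob(st, 1, Inf), 0.125)
  kd <- st$k_div; km <- st$k_dth; r <- kd - km
  alpha192 <- km * (exp(r * 192) - 1) / (kd * exp(r * 192) - km)
  expect_equal(extinction_prob(st, 1, 192), alpha192)
  expect_equal(alpha192, 0.124, tolerance = 1e-3)
  expect_equal(extinction_prob(st, 3, Inf), 0.125^3)
  expect_equal(extinction_prob(bd_state("i", 0.2, 0), 1, 1e6), 0)
  expect_equal(extinction_prob(bd_state("c", 0.1, 0.1), 1, 10),
               1 / (1 + 1 / (0.1 * 10)))
  expect_error(expected_count(st, 1, -5), "non-negative")
})

test_that("degenerate dynamics: frozen and pure-death colonies", {
  frozen <- simulate_ssa(one_state_model(0, 0), "s1", std_protocol(0, 0),
                         seed = 3)
  expect_true(all(frozen$counts == 1L))
  ds <- simulate_cfp_battery(one_state_model(0, 0), std_protocol(0, 0),
                             100, seed = 4)
  expect_true(all(vapply(ds$traces, function(tr) all(tr$counts == 1L),
                         logical(1))))
  # pure death: non-increasing, absorbing at zero
  proto <- sim_protocol(one_state_model(0, 0.05),
                        sampling_times = seq(0, 360, 12))
  for (s in 1:50) {
    tr <- simulate_ssa(one_state_model(0, 0.05), "s1", proto, seed = s)
    expect_true(all(diff(tr$counts) <= 0))
    z <- which(tr$counts == 0L)
    if (length(z) > 0L) expect_true(all(tr$counts[min(z):length(tr$counts)] == 0L))
  }
})

test_that("SSA matches closed-form mean, variance and extinction", {
  n <- 2000
  settings <- list(c(0.04, 0.005), c(0.02, 0.03), c(0.05, 0.01))
  for (rates in settings) {
    st <- bd_state("s1", rates[1] * ln2, rates[2] * ln2)
    proto <- std_protocol(st$k_div, st$k_dth)
    ds <- simulate_cfp_battery(bd_model(st), proto, n,
                               seed = round(1e3 * sum(rates)))
    for (tq in c(96, 192)) {
      it <- match(tq, proto$sampling_times)
      counts <- vapply(ds$traces, function(tr) tr$counts[it], numeric(1))
      mu <- expected_count(st, 1, tq)
      expect_lt(abs(mean(counts) - mu), 3 * sd(counts) / sqrt(n))
      v <- count_variance(st, 1, tq)
      expect_gt(var(counts) / v, 0.75)
      expect_lt(var(counts) / v, 1.35)
      a <- extinction_prob(st, 1, tq)
      expect_lt(abs(mean(counts == 0) - a),
                3 * sqrt(a * (1 - a) / n) + 1e-12)
    }
  }
})

test_that("founder assignment follows founder_fractions; lineages are pure", {
  m2 <- bd_model(list(bd_state("a", 0, 0), bd_state("b", 0, 0)),
                 c(0.5, 0.5))
  proto <- sim_protocol(m2, sampling_times = c(0, 192, 360))
  ds <- simulate_cfp_battery(m2, proto, 10000, seed = 8)
  founders <- vapply(ds$traces, `[[`, character(1), "founder_state")
  expect_true(all(founders %in% c("a", "b")))
  n_a <- sum(founders == "a")
  expect_lt(abs(n_a - 5000), 3 * sqrt(10000 * 0.25))
  # degenerate mixture: every founder is the unit-probability state
  m10 <- bd_model(list(bd_state("a", 0, 0), bd_state("b", 0, 0)), c(1, 0))
  ds10 <- simulate_cfp_battery(m10, proto, 200, seed = 9)
  expect_true(all(vapply(ds10$traces, `[[`, character(1),
                         "founder_state") == "a"))
})

test_that("identical (model, protocol, seed) gives identical results", {
  m <- one_state_model(0.04 * ln2, 0.005 * ln2)
  proto <- std_protocol(0.02 * ln2, 0.03 * ln2)
  d1 <- simulate_cfp_battery(m, proto, 50, seed = 42)
  d2 <- simulate_cfp_battery(m, proto, 50, seed = 42)
  expect_identical(d1$traces, d2$traces)
  d3 <- simulate_cfp_battery(m, proto, 50, seed = 43)
  expect_false(identical(d1$traces, d3$traces))
  t1 <- simulate_ssa(m, "s1", proto, seed = 7)
  t2 <- simulate_ssa(m, "s1", proto, seed = 7)
  expect_identical(t1, t2)
})

test_that("population cap halts and holds", {
  # explosive growth from many founders hits the cap and stays there
  proto <- sim_protocol(one_state_model(0.2, 0), initial_cells = 100,
                        expansion_hours = 0,
                        sampling_times = seq(0, 360, 24),
                        population_cap = 5000)
  tr <- simulate_ssa(one_state_model(0.2, 0), "s1", proto, seed = 2)
  expect_true(any(tr$counts == 5000L))
  first <- min(which(tr$counts == 5000L))
  expect_true(all(tr$counts[first:length(tr$counts)] == 5000L))
  expect_true(all(tr$counts <= 5000L))
})
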