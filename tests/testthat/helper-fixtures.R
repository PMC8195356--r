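# Fixture builders shared across test files. All data is constructed in
# code; no files are read.

ln2 <- log(2)

one_state_model <- function(k_div, k_dth, label = "s1") {
  bd_model(bd_state(label, k_div, k_dth))
}

# protocol whose post-treatment model is a single state with these rates
std_protocol <- function(post_k_div, post_k_dth, ...) {
  sim_protocol(one_state_model(post_k_div, post_k_dth), ...)
}

# deterministic exponential trace: counts = round(n0 * 2^(rate * t)).
# With n0 = 1e6 the rounding error on log2 counts is < 2e-6, so slopes
# recover essentially exactly.
exp_trace <- function(rate, times, n0 = 1e6, id = "c1") {
  colony_trace(id, times, round(n0 * 2^(rate * times)))
}

# quick synthetic experiment: one-state truth, filtered, compiled
quick_experiment <- function(post_k_div, post_k_dth, n_colonies = 200,
                             seed = 1) {
  truth <- cfp_ground_truth(one_state_model(0.04 * ln2, 0.005 * ln2),
                            std_protocol(post_k_div, post_k_dth),
                            n_colonies = n_colonies, seed = seed)
  compile_dip_distribution(filter_colonies(generate_cfp_experiment(truth)))
}

# tiny chain DAG R <- A <- B <- C (is_a)
chain_dag <- function() {
  term_dag(data.frame(child = c("A", "B", "C"),
                      parent = c("R", "A", "B"),
                      relation = "is_a"))
}
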