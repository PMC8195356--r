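test_that("generators are pure functions of (parameters, seed)", {
  truth <- cfp_ground_truth(one_state_model(0.04 * ln2, 0.005 * ln2),
                            std_protocol(0.02 * ln2, 0.03 * ln2),
                            n_colonies = 30, seed = 61)
  expect_identical(generate_cfp_experiment(truth)$traces,
                   generate_cfp_experiment(truth)$traces)
  r1 <- generate_population_assay(n_replicates = 3, seed = 62,
                                  sampling_times = seq(0, 120, 12),
                                  treatment_time = 24)
  r2 <- generate_population_assay(n_replicates = 3, seed = 62,
                                  sampling_times = seq(0, 120, 12),
                                  treatment_time = 24)
  expect_identical(r1, r2)
  og <- ontology_ground_truth(n_terms = 60, n_genes = 50, branch_size = 8,
                              len_mut = 12, len_expr = 15)
  f1 <- generate_ontology_fixture(og, seed = 63)
  f2 <- generate_ontology_fixture(og, seed = 63)
  expect_identical(f1$dag$edges, f2$dag$edges)
  expect_identical(f1$annotation, f2$annotation)
  expect_identical(f1$mut_genes, f2$mut_genes)
})

test_that("empty experiment is valid; founder labels stay in the sidecar", {
  truth <- cfp_ground_truth(one_state_model(1, 0), std_protocol(1, 0),
                            n_colonies = 0, seed = 1)
  empty <- generate_cfp_experiment(truth)
  expect_s3_class(empty, "cfp_dataset")
  expect_equal(length(empty), 0L)
  expect_equal(empty$treatment_time, 192)
  truth2 <- cfp_ground_truth(one_state_model(0.02, 0.01),
                             std_protocol(0.02, 0.01),
                             n_colonies = 5, seed = 2)
  ds <- generate_cfp_experiment(truth2)
  expect_true(all(vapply(ds$traces, function(tr) {
    !is.null(tr$founder_state)
  }, logical(1))))
  # the default CSV omits the ground-truth labels
  csv <- file.path(tempdir(), "traces.csv")
  write_cfp_csv(ds, csv)
  back <- read_cfp_csv(csv)
  expect_true(all(vapply(back$traces, function(tr) {
    is.null(tr$founder_state)
  }, logical(1))))
  # and retains them on request
  write_cfp_csv(ds, csv, include_founder = TRUE)
  back2 <- read_cfp_csv(csv)
  expect_equal(vapply(back2$traces, `[[`, character(1), "founder_state"),
               vapply(ds$traces, `[[`, character(1), "founder_state"))
})

test_that("CSV/TSV round-trips are bit-exact", {
  truth <- cfp_ground_truth(one_state_model(0.04 * ln2, 0.005 * ln2),
                            std_protocol(0.02 * ln2, 0.03 * ln2),
                            n_colonies = 12, seed = 64)
  ds <- generate_cfp_experiment(truth)
  csv <- file.path(tempdir(), "rt.csv")
  write_cfp_csv(ds, csv, include_founder = TRUE)
  back <- read_cfp_csv(csv)
  expect_identical(back$treatment_time, ds$treatment_time)
  for (j in seq_along(ds$traces)) {
    expect_identical(back$traces[[j]]$times, ds$traces[[j]]$times)
    expect_identical(back$traces[[j]]$counts, ds$traces[[j]]$counts)
  }
  # DIP rates are doubles; %.17g must round-trip them exactly
  dd <- quick_experiment(0.03 * ln2, 0.035 * ln2, n_colonies = 40,
                         seed = 65)
  dcsv <- file.path(tempdir(), "dips.csv")
  write_dip_csv(dd, dcsv)
  dback <- read_dip_csv(dcsv)[[1]]
  expect_identical(dback$dip_rates, dd$dip_rates)
  # ontology edge lists and annotations
  fx <- generate_ontology_fixture(
    ontology_ground_truth(n_terms = 50, n_genes = 40, branch_size = 6,
                          len_mut = 10, len_expr = 12),
    seed = 66)
  tsv <- file.path(tempdir(), "dag.tsv")
  write_term_dag_tsv(fx$dag, tsv)
  dag2 <- read_term_dag_tsv(tsv)
  expect_identical(dag2$edges, fx$dag$edges)
  atsv <- file.path(tempdir(), "ann.tsv")
  write_annotation_tsv(fx$annotation, atsv)
  ann2 <- read_annotation_tsv(atsv)
  expect_identical(ann2$gene, fx$annotation$gene)
  expect_identical(ann2$term, fx$annotation$term)
})

test_that("generated ontologies are acyclic with a single root", {
  for (s in 1:30) {
    fx <- generate_ontology_fixture(
      ontology_ground_truth(n_terms = 40, n_genes = 30, branch_size = 6,
                            len_mut = 10, len_expr = 12),
      seed = s)  # term_dag() errors on any cycle
    roots <- setdiff(fx$dag$terms, fx$dag$edges$child)
    expect_equal(roots, "T0001")
  }
})

test_that("planted signal draws gene lists from the branch pool", {
  fx <- generate_ontology_fixture(
    ontology_ground_truth(overlap_fraction = 1), seed = 71)
  pool <- unique(fx$annotation$gene[fx$annotation$term %in%
                                      fx$planted_terms])
  expect_true(all(fx$mut_genes %in% pool))
  expect_true(all(fx$expr_genes %in% pool))
  expect_true(all(fx$planted_terms %in% fx$dag$terms))
  # and pure-noise lists ignore the branch
  fx0 <- generate_ontology_fixture(
    ontology_ground_truth(overlap_fraction = 0), seed = 71)
  expect_false(all(fx0$mut_genes %in% pool))
  # infeasible signal is an error, not a silent shortfall
  expect_error(
    generate_ontology_fixture(
      ontology_ground_truth(n_terms = 50, n_genes = 30, branch_size = 5,
                            annotation_density = 1, overlap_fraction = 1,
                            len_mut = 25, len_expr = 25),
      seed = 72),
    "incompatible")
})

test_that("population assay with k_div = k_dth stays flat on average", {
  m <- one_state_model(0.02 * ln2, 0.02 * ln2)
  reps <- generate_population_assay(m, n_replicates = 4, n0 = 2500,
                                    sampling_times = seq(0, 200, 12),
                                    treatment_time = 24, seed = 73)
  ps <- population_growth_summary(reps, treatment_time = 24)
  expect_lt(max(abs(ps$mean_log2norm)), 0.15)
})
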