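# cfptools

Tools for asking whether the drug-response variability of single
cell-derived cancer sublines is genetic, epigenetic, or just stochastic.
The package re-implements, as a tested reusable pipeline, the computational
analysis behind that question for EGFR-inhibitor-treated NSCLC (PC9-like)
sublines:

* an **exact Gillespie simulator** of linear birth-death cell populations
  (`Cell -> 2 Cell` at rate `k_div * N`, `Cell -> 0` at `k_dth * N`, no
  state switching) and the in-silico **clonal fractional proliferation
  (cFP)** protocol: single-cell founders, 8 days of drug-free expansion, a
  rate switch at treatment, daily sampling for 7 days;
* **DIP-rate analysis**: the drug-induced proliferation rate is the OLS
  slope of log2 cell count vs time (log2/h) over the post-treatment window;
  colony filtering (>= 50 cells at treatment), kernel-density summaries,
  population-level growth summaries, and Mood's median test;
* the **bootstrapped Anderson-Darling acceptance rule**: the two-sample
  Scholz-Stephens AD test (midrank variant, p clipped to [0.001, 0.25]),
  with the p-value bootstrapped over 100 resamples of the experimental
  distribution and a parameter set kept when `<p> - sdev(p) > 0.05`;
* **parameter scans** of post-treatment division/death rate constants, 2D
  for one-state models and constrained 4D (projected to 2D) for two-state
  models -- the logic that shows a bimodal subline *requires* a second cell
  state;
* the **GO semantic-similarity comparison** of mutation-derived vs
  expression-derived term lists: hypergeometric enrichment, randomized term
  selection (keep a term when a uniform draw exceeds its p-value), Wang
  graph similarity, top-1000 median aggregation, and normalization against
  random gene lists of matched lengths (relative score =
  observed / (median + 1 sd of simulated));
* a **synthetic-data module** (first-class, tested) that generates cFP
  datasets with known birth-death ground truth and toy ontologies with a
  planted cross-modality signal, so every stage is testable offline.

## Worked example

Simulate a synthetic cFP "experiment" from a known truth (untreated rates
`k_div = 0.04 ln2`, `k_dth = 0.005 ln2` per hour; treated rates
`(0.030, 0.035) ln2`, i.e. a net DIP rate of -0.005 log2/h), then scan for
the rate constants that reproduce it:

```r
library(cfptools)
ln2 <- log(2)

pre  <- bd_model(bd_state("s1", 0.040 * ln2, 0.005 * ln2))
post <- bd_model(bd_state("s1", 0.030 * ln2, 0.035 * ln2))
truth <- cfp_ground_truth(pre, sim_protocol(post), n_colonies = 200,
                          seed = 101)
cfp <- filter_colonies(generate_cfp_experiment(truth), min_cells = 50)
#> <cfp_dataset> 105 colonies, treatment at 192 h
dips <- compile_dip_distribution(cfp, group_label = "DS-sim")
#> <dip_distribution> DS-sim: n = 105, median = -0.004933 log2/h

scan <- scan_one_state(dips, default_rate_grid(step = 0.005),
                       default_rate_grid(step = 0.005), seed = 1)
#> <scan_grid> one_state: 169 cells, 7 passed, 0 unevaluable
accepted_region(scan)$cells[, c("k_div", "k_dth", "net_dip",
                                "p_mean", "p_sd")]
#>      k_div  k_dth net_dip p_mean   p_sd
#> 84  0.0173 0.0208  -0.005 0.1303 0.0764
#> 98  0.0208 0.0243  -0.005 0.2164 0.0588   <- the generating rates
#> 112 0.0243 0.0277  -0.005 0.2229 0.0548
#> 126 0.0277 0.0312  -0.005 0.1554 0.0682
#> 140 0.0312 0.0347  -0.005 0.1955 0.0738
#> 154 0.0347 0.0381  -0.005 0.1619 0.0859
#> 168 0.0381 0.0416  -0.005 0.1402 0.0708
```

The accepted region is the diagonal band of rate pairs whose net DIP rate
`(k_div - k_dth)/ln 2` matches the data (-0.005 log2/h): clonal DIP-rate
distributions constrain the *difference* of the rate constants tightly and
their magnitudes only weakly -- exactly the structure seen in the original
heatmaps. Note that individual cells of the band flicker across seeds (the
keep rule accepts a true-null comparison with probability ~0.83; see the
methods vignette), while the band itself is stable.

Comparing two DIP distributions:

```r
moods_median_test(list(c(1, 2, 3), c(4, 5, 6)))
#> chi-square = 6, df = 1, p = 0.0143
```

For the ontology side, `generate_ontology_fixture()` +
`go_similarity_pipeline()` + `baseline_relative_score()` produce relative
semantic-similarity scores: ~1 for unrelated gene lists, > 1 when both
modalities are enriched for the same planted branch.

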