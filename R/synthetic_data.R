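# Synthetic-data generators: cFP datasets with known birth-death ground
# truth, population-level replicate assays, and toy ontologies with a
# planted cross-modality enrichment signal. Every generator is a pure
# function of (parameters, seed).

#' Ground truth for a synthetic cFP experiment
#'
#' Bundles the pre-treatment model, protocol (carrying the post-treatment
#' model), colony count and seed that define a synthetic experiment.
#' Defaults mirror the experimental assay: single-cell founders, 8 days of
#' drug-free expansion, daily imaging for 7 days of treatment, and a
#' colony count inside the study's 160-280 replicate range.
#'
#' @param model pre-treatment [bd_model()]; default one untreated state.
#' @param protocol a [sim_protocol()] with a `treatment_model`.
#' @param n_colonies number of colonies, default 200.
#' @param seed integer seed.
#' @return A `cfp_ground_truth` object.
#' @export
cfp_ground_truth <- function(model = bd_model(untreated_state("s1")),
                             protocol, n_colonies = 200, seed = 1) {
  stopifnot(inherits(model, "bd_model"), inherits(protocol, "sim_protocol"),
            n_colonies >= 0)
  structure(list(model = model, protocol = protocol,
                 n_colonies = n_colonies, seed = seed),
            class = "cfp_ground_truth")
}

#' Generate a synthetic cFP experiment
#'
#' Runs the in-silico cFP battery defined by the ground truth. Traces
#' retain their founder-state labels (the sidecar ground truth); analysis
#' stages never read them, and the CSV writer omits them by default.
#'
#' @param truth a [cfp_ground_truth()].
#' @return A [cfp_dataset()] (empty but valid when `n_colonies = 0`).
#' @export
generate_cfp_experiment <- function(truth) {
  stopifnot(inherits(truth, "cfp_ground_truth"))
  if (truth$n_colonies == 0L) {
    return(cfp_dataset(list(),
                       treatment_time = truth$protocol$expansion_hours,
                       metadata = list(seed = truth$seed, n_colonies = 0L,
                                       source = "generate_cfp_experiment")))
  }
  ds <- simulate_cfp_battery(truth$model, truth$protocol,
                             truth$n_colonies, truth$seed)
  ds$metadata$source <- "generate_cfp_experiment"
  ds
}

#' Generate a population-level proliferation assay
#'
#' Independent whole-well replicates, each founded by thousands of cells
#' (default 2,500) and sampled twice daily out to 500 h, emulating
#' population-level DIP rate assays. Drug addition defaults to 24 h after
#' seeding.
#'
#' @param model pre-treatment one-state [bd_model()].
#' @param treatment_model post-treatment [bd_model()]; default equal to
#'   `model` (untreated wells).
#' @param n_replicates number of wells, default 6.
#' @param n0 founding cells per well, default 2500.
#' @param sampling_times hours; default twice daily to 500 h.
#' @param treatment_time drug addition time, default 24 h.
#' @param population_cap confluency surrogate, default 1e7 (wells start
#'   large, so the single-colony cap would truncate immediately).
#' @param seed integer seed.
#' @return A list of [colony_trace()] replicates.
#' @export
generate_population_assay <- function(model = bd_model(untreated_state("s1")),
                                      treatment_model = model,
                                      n_replicates = 6,
                                      n0 = 2500,
                                      sampling_times = seq(0, 500, by = 12),
                                      treatment_time = 24,
                                      population_cap = 1e7,
                                      seed = 1) {
  proto <- sim_protocol(treatment_model, initial_cells = n0,
                        expansion_hours = treatment_time,
                        sampling_times = sampling_times,
                        population_cap = population_cap)
  ds <- simulate_cfp_battery(model, proto, n_replicates, seed)
  for (j in seq_along(ds$traces)) {
    ds$traces[[j]]$colony_id <- sprintf("well%02d", j)
  }
  ds$traces
}

#' Ground truth for a synthetic ontology fixture
#'
#' Parameters of a random term DAG plus gene annotations with a planted
#' subtree ("branch") enriched in both modalities. `overlap_fraction`
#' controls how much of each modality's gene list is drawn from genes
#' annotated to the planted branch (0 = pure noise, 1 = full signal).
#'
#' @param n_terms number of terms (>= 3), default 500. Real GO namespaces
#'   are far larger (thousands of terms), which is what makes the top-k
#'   score range an extreme tail of mostly-unrelated pairs; the defaults
#'   are sized so selected term lists stay a small fraction of the graph
#'   and top-1000 aggregation behaves the same way.
#' @param n_genes annotation universe size, default 1000.
#' @param annotation_density mean terms annotated per gene, default 2
#'   (low density keeps terms specific, so a random gene list leaves most
#'   terms at p = 1 exactly as with real GO annotations).
#' @param relation_mix probability an edge is `is_a` (vs `part_of`),
#'   default 0.8.
#' @param extra_parent_prob probability a term gets a second parent
#'   (makes the graph a DAG rather than a tree), default 0.2.
#' @param branch_size number of terms in the planted branch (a tight
#'   family of sibling terms under one deep branch root, like the
#'   specific sub-terms of one biological process), default 60.
#' @param branch_depth target depth of the branch root, default 4.
#' @param overlap_fraction fraction of each gene list drawn from the
#'   planted branch, in \[0, 1\].
#' @param len_mut,len_expr gene-list lengths, defaults 40 and 50.
#' @return An `ontology_ground_truth` object.
#' @export
ontology_ground_truth <- function(n_terms = 500, n_genes = 1000,
                                  annotation_density = 2,
                                  relation_mix = 0.8,
                                  extra_parent_prob = 0.2,
                                  branch_size = 60,
                                  branch_depth = 4,
                                  overlap_fraction = 0,
                                  len_mut = 40, len_expr = 50) {
  stopifnot(n_terms >= 3, n_genes >= 1, annotation_density >= 1,
            overlap_fraction >= 0, overlap_fraction <= 1,
            branch_size >= 2, n_terms > branch_size + 2,
            len_mut >= 1, len_expr >= 1,
            len_mut <= n_genes, len_expr <= n_genes)
  structure(list(n_terms = n_terms, n_genes = n_genes,
                 annotation_density = annotation_density,
                 relation_mix = relation_mix,
                 extra_parent_prob = extra_parent_prob,
                 branch_size = branch_size,
                 branch_depth = branch_depth,
                 overlap_fraction = overlap_fraction,
                 len_mut = len_mut, len_expr = len_expr),
            class = "ontology_ground_truth")
}

#' Generate an ontology fixture with planted cross-modality signal
#'
#' Builds a random acyclic term DAG (single root, preferential-attachment
#' parentage for realistic depth variation), a gene-to-term annotation
#' table, and mutation/expression gene lists in which a fraction
#' `overlap_fraction` of each list is drawn from genes annotated to the
#' planted branch.
#'
#' @param truth an [ontology_ground_truth()].
#' @param seed integer seed.
#' @return A list: dag ([term_dag()]), annotation (data.frame gene/term),
#'   universe, mut_genes, expr_genes, planted_branch,
#'   planted_terms.
#' @export
generate_ontology_fixture <- function(truth, seed) {
  stopifnot(inherits(truth, "ontology_ground_truth"))
  set.seed(seed)
  n <- truth$n_terms
  n_core <- n - truth$branch_size
  ids <- sprintf("T%04d", seq_len(n))
  # depth-weighted preferential attachment: parents always have a lower
  # index than children (acyclic by construction), and deeper candidates
  # are favoured so the graph develops GO-like depth variation rather
  # than a few shallow hubs
  depth <- numeric(n)
  parent1 <- integer(n)
  edges <- vector("list", 2L * n)
  ne <- 0L
  rel_draw <- function() {
    if (runif(1) < truth$relation_mix) "is_a" else "part_of"
  }
  for (i in 2:n_core) {
    w <- (depth[seq_len(i - 1L)] + 1)^2
    p <- sample.int(i - 1L, 1L, prob = w)
    parent1[i] <- p
    depth[i] <- depth[p] + 1
    ne <- ne + 1L
    edges[[ne]] <- data.frame(child = ids[i], parent = ids[p],
                              relation = rel_draw())
    if (i > 2L && runif(1) < truth$extra_parent_prob) {
      p2 <- sample.int(i - 1L, 1L)
      if (p2 != p) {
        ne <- ne + 1L
        edges[[ne]] <- data.frame(child = ids[i], parent = ids[p2],
                                  relation = rel_draw())
      }
    }
  }
  # plant a tight branch: a branch root attached at moderate depth, with
  # the remaining branch terms as its direct children (a family of
  # specific sibling terms, which is what gives within-branch Wang
  # similarity its contrast against unrelated-term pairs)
  core <- seq_len(n_core)[-1L]
  attach_at <- core[which.min(abs(depth[core] - truth$branch_depth))]
  broot <- n_core + 1L
  parent1[broot] <- attach_at
  depth[broot] <- depth[attach_at] + 1
  ne <- ne + 1L
  edges[[ne]] <- data.frame(child = ids[broot], parent = ids[attach_at],
                            relation = "is_a")
  for (i in seq(broot + 1L, length.out = truth$branch_size - 1L)) {
    parent1[i] <- broot
    depth[i] <- depth[broot] + 1
    ne <- ne + 1L
    edges[[ne]] <- data.frame(child = ids[i], parent = ids[broot],
                              relation = rel_draw())
  }
  edge_df <- do.call(rbind, edges[seq_len(ne)])
  dag <- term_dag(edge_df)
  planted_terms <- ids[broot:n]
  branch <- broot

  genes <- sprintf("g%04d", seq_len(truth$n_genes))
  ann <- do.call(rbind, lapply(seq_len(truth$n_genes), function(g) {
    kt <- sample.int(n, min(truth$annotation_density, n))
    data.frame(gene = genes[g], term = ids[kt])
  }))
  ann <- unique(ann)

  planted_genes <- unique(ann$gene[ann$term %in% planted_terms])
  n_plant_mut <- round(truth$overlap_fraction * truth$len_mut)
  n_plant_expr <- round(truth$overlap_fraction * truth$len_expr)
  if (length(planted_genes) < max(n_plant_mut, n_plant_expr)) {
    stop("annotation density incompatible with requested planted signal",
         call. = FALSE)
  }
  draw_list <- function(n_plant, len) {
    base <- sample(planted_genes, n_plant)
    rest <- sample(setdiff(genes, base), len - n_plant)
    sample(c(base, rest))
  }
  list(dag = dag, annotation = ann, universe = genes,
       mut_genes = draw_list(n_plant_mut, truth$len_mut),
       expr_genes = draw_list(n_plant_expr, truth$len_expr),
       planted_branch = ids[branch], planted_terms = planted_terms)
}
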