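# Graph-based ontology semantic similarity (Wang method) and the
# mutation-vs-expression comparison pipeline: hypergeometric enrichment,
# randomized term selection, top-k similarity aggregation, and a
# random-gene-list baseline that normalizes away list-length effects.

#' Ontology term DAG with typed relations
#'
#' Directed acyclic graph of ontology terms; edges point child -> parent.
#' Each relation type contributes a semantic weight (Wang's defaults:
#' `is_a` 0.8, `part_of` 0.6). Terms in different namespaces are
#' incomparable by contract; no virtual super-root is added.
#'
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @param namespaces optional named character vector term -> namespace;
#'   default all `"BP"`.
#' @param relation_weights named numeric weights in (0, 1) per relation
#'   type.
#' @return A `term_dag` object (with an internal S-value cache).
#' @export
term_dag <- function(edges,
                     namespaces = NULL,
                     relation_weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(is.data.frame(edges),
            all(c("child", "parent", "relation") %in% names(edges)))
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  edges$relation <- as.character(edges$relation)
  if (!all(edges$relation %in% names(relation_weights))) {
    stop("edge with unknown relation type", call. = FALSE)
  }
  if (!all(relation_weights > 0 & relation_weights < 1)) {
    stop("relation weights must lie in (0, 1)", call. = FALSE)
  }
  terms <- sort(unique(c(edges$child, edges$parent)))
  if (is.null(namespaces)) {
    namespaces <- setNames(rep("BP", length(terms)), terms)
  }
  if (!all(terms %in% names(namespaces))) {
    stop("namespaces must cover every term", call. = FALSE)
  }
  order <- topo_sort(terms, edges)  # children before parents; errors on cycle
  edges$w <- unname(relation_weights[edges$relation])
  # integer index structures for fast S-value recursion
  idx <- setNames(seq_along(terms), terms)
  ci <- unname(idx[edges$child])
  pi <- unname(idx[edges$parent])
  parents_of <- vector("list", length(terms))
  children_of <- vector("list", length(terms))
  w_parents <- vector("list", length(terms))
  w_children <- vector("list", length(terms))
  for (e in seq_along(ci)) {
    parents_of[[ci[e]]] <- c(parents_of[[ci[e]]], pi[e])
    w_parents[[ci[e]]] <- c(w_parents[[ci[e]]], edges$w[e])
    children_of[[pi[e]]] <- c(children_of[[pi[e]]], ci[e])
    w_children[[pi[e]]] <- c(w_children[[pi[e]]], edges$w[e])
  }
  obj <- list(terms = terms, edges = edges,
              namespaces = namespaces[terms],
              relation_weights = relation_weights,
              topo = order, topo_idx = unname(idx[order]),
              parents_of = parents_of, children_of = children_of,
              w_children = w_children,
              cache = new.env(parent = emptyenv()))
  class(obj) <- "term_dag"
  obj
}

#' @export
print.term_dag <- function(x, ...) {
  cat(sprintf("<term_dag> %d terms, %d edges, namespaces: %s\n",
              length(x$terms), nrow(x$edges),
              paste(unique(x$namespaces), collapse = ", ")))
  invisible(x)
}

# Kahn's algorithm on child -> parent edges; returns terms ordered with
# every child before all of its parents. Errors on a cycle.
topo_sort <- function(terms, edges) {
  idx <- setNames(seq_along(terms), terms)
  n <- length(terms)
  # out-neighbours of a child are its parents
  parents <- split(idx[edges$parent], idx[edges$child])
  indeg <- integer(n)  # number of children pointing at each term
  tab <- table(idx[edges$parent])
  indeg[as.integer(names(tab))] <- as.integer(tab)
  queue <- which(indeg == 0L)  # leaves first
  out <- integer(0)
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, v)
    for (p in parents[[as.character(v)]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(out) != n) stop("ontology graph contains a cycle", call. = FALSE)
  terms[out]
}

# S-values of term A over its ancestor sub-DAG T_A:
#   S_A(A) = 1;  S_A(t) = max over children t' of t within T_A of
#   w(t' -> t) * S_A(t').
# Returns a named vector over T_A; cached per term on the dag object.
svalues <- function(dag, term) {
  cached <- get0(term, envir = dag$cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  a <- match(term, dag$terms)
  if (is.na(a)) stop(sprintf("unknown term %s", term), call. = FALSE)
  n <- length(dag$terms)
  in_anc <- logical(n)
  in_anc[a] <- TRUE
  frontier <- a
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(dag$parents_of[frontier]))
    nxt <- nxt[!in_anc[nxt]]
    in_anc[nxt] <- TRUE
    frontier <- nxt
  }
  s <- rep(NA_real_, n)
  s[a] <- 1
  for (t in dag$topo_idx) {
    if (!in_anc[t] || t == a) next
    ch <- dag$children_of[[t]]
    keep <- in_anc[ch]
    s[t] <- max(dag$w_children[[t]][keep] * s[ch[keep]])
  }
  out <- setNames(s[in_anc], dag$terms[in_anc])
  assign(term, out, envir = dag$cache)
  out
}

#' Wang semantic similarity between two ontology terms
#'
#' Each term's ancestor sub-DAG gets semantic contributions
#' (S-values) that decay along edges by the relation weight; the semantic
#' value `SV(A)` is the sum of S-values. The similarity is the sum of both
#' terms' S-values over their shared ancestors divided by `SV(A) + SV(B)`.
#' Always in (0, 1] for comparable terms, symmetric, and 1 for identical
#' terms.
#'
#' @param dag a [term_dag()].
#' @param a,b term identifiers in the same namespace.
#' @return Similarity score in (0, 1].
#' @examples
#' d <- term_dag(data.frame(child = c("A", "B"), parent = "R",
#'                          relation = "is_a"))
#' wang_similarity(d, "A", "B")  # (0.8 + 0.8) / (1.8 + 1.8)
#' @export
wang_similarity <- function(dag, a, b) {
  stopifnot(inherits(dag, "term_dag"))
  if (dag$namespaces[[a]] != dag$namespaces[[b]]) {
    stop("terms belong to different namespaces", call. = FALSE)
  }
  sa <- svalues(dag, a)
  sb <- svalues(dag, b)
  common <- intersect(names(sa), names(sb))
  (sum(sa[common]) + sum(sb[common])) / (sum(sa) + sum(sb))
}

# All-pairs Wang similarity between two term lists (S-values cached).
# Vectorized: with S the terms-by-ancestors S-value matrix and I = (S > 0)
# its indicator, the shared-ancestor sums of all pairs are
# S1 I2' + I1 S2', and the denominator is the outer sum of semantic values.
wang_similarity_matrix <- function(dag, terms1, terms2) {
  all_terms <- dag$terms
  smat <- function(terms) {
    m <- matrix(0, length(terms), length(all_terms),
                dimnames = list(terms, all_terms))
    for (i in seq_along(terms)) {
      s <- svalues(dag, terms[[i]])
      m[i, names(s)] <- s
    }
    m
  }
  s1 <- smat(terms1)
  s2 <- smat(terms2)
  num <- s1 %*% t(s2 > 0) + (s1 > 0) %*% t(s2)
  den <- outer(rowSums(s1), rowSums(s2), "+")
  num / den
}

#' Hypergeometric term enrichment of a gene list
#'
#' Upper-tail hypergeometric p-value for the overlap between `gene_list`
#' and each term's annotated gene set within `universe` (a fully
#' specified, offline stand-in for server-side enrichment tools).
#'
#' @param gene_list character vector of genes, a subset of `universe`.
#' @param annotation data.frame with columns `gene`, `term`.
#' @param universe character vector of all assayable genes.
#' @param modality label stored with the result (e.g. "mutation",
#'   "expression").
#' @param sample optional sample label.
#' @return data.frame: term, p_value, overlap, term_size, modality,
#'   sample.
#' @export
hypergeom_enrich <- function(gene_list, annotation, universe,
                             modality = "mutation", sample = NA_character_) {
  stopifnot(is.data.frame(annotation),
            all(c("gene", "term") %in% names(annotation)))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (!all(gene_list %in% universe)) {
    stop("gene_list must be a subset of the universe", call. = FALSE)
  }
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("gene", "term")])
  term_genes <- split(ann$gene, ann$term)
  Nu <- length(unique(universe))
  K <- length(unique(gene_list))
  res <- vapply(term_genes, function(g) {
    m <- length(g)
    x <- sum(gene_list %in% g)
    c(p = phyper(x - 1, m, Nu - m, K, lower.tail = FALSE),
      overlap = x, size = m)
  }, numeric(3))
  data.frame(term = colnames(res), p_value = res["p", ],
             overlap = res["overlap", ], term_size = res["size", ],
             modality = modality, sample = sample,
             row.names = NULL)
}

#' Randomized term selection by enrichment p-value
#'
#' A term is kept when an independent uniform draw exceeds its enrichment
#' p-value, so strongly enriched terms are almost always kept and terms
#' near a significance cutoff are kept probabilistically rather than
#' dismissed outright.
#'
#' @param enrichments data.frame with columns `term`, `p_value`.
#' @param seed integer seed.
#' @return Character vector of selected terms.
#' @export
select_terms <- function(enrichments, seed) {
  stopifnot(is.data.frame(enrichments),
            all(c("term", "p_value") %in% names(enrichments)))
  set.seed(seed)
  u <- runif(nrow(enrichments))
  enrichments$term[u > enrichments$p_value]
}

#' Top-k aggregate of pairwise semantic similarities
#'
#' Computes the full pairwise Wang similarity matrix between two term
#' lists, takes the top `min(k, #pairs)` scores (the similarity
#' distribution is heavily skewed toward low values by graph distance, so
#' only the maximum range of scores is informative), and summarizes them
#' by their median with a nonparametric bootstrap 95% confidence interval.
#'
#' @param list_mut,list_expr non-empty character vectors of term ids.
#' @param dag a [term_dag()].
#' @param k number of top scores, default 1000.
#' @param n_boot bootstrap resamples for the CI, default 1000; `0` skips
#'   the CI (used for baseline replicates, where only the median matters).
#' @param seed seed for the CI bootstrap.
#' @return A `similarity_aggregate`: top_k_scores, median, ci95, k_used,
#'   baseline (NA until [baseline_relative_score()]), relative_score.
#' @export
aggregate_similarity <- function(list_mut, list_expr, dag, k = 1000,
                                 n_boot = 1000, seed = 1) {
  if (length(list_mut) == 0L || length(list_expr) == 0L) {
    stop("term lists must be non-empty", call. = FALSE)
  }
  m <- wang_similarity_matrix(dag, list_mut, list_expr)
  scores <- sort(as.numeric(m), decreasing = TRUE)
  k_used <- min(k, length(scores))
  top <- scores[seq_len(k_used)]
  med <- median(top)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(i) {
      median(top[sample.int(k_used, k_used, replace = TRUE)])
    }, numeric(1))
    ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  structure(list(top_k_scores = top, median = med, ci95 = ci,
                 k_used = k_used, baseline = NA_real_,
                 relative_score = NA_real_),
            class = "similarity_aggregate")
}

#' @export
print.similarity_aggregate <- function(x, ...) {
  cat(sprintf("<similarity_aggregate> median = %.4f [%.4f, %.4f] (k = %d)",
              x$median, x$ci95[1], x$ci95[2], x$k_used))
  if (!is.na(x$relative_score)) {
    cat(sprintf(", relative = %.3f (baseline %.4f)",
                x$relative_score, x$baseline))
  }
  cat("\n")
  invisible(x)
}

#' Full similarity pipeline for one pair of gene lists
#'
#' Enrich both modalities, select terms with the randomized rule, and
#' aggregate pairwise Wang similarities. The building block for both the
#' observed comparison and the random-list baseline.
#'
#' @param mut_genes,expr_genes gene lists (mutation- and
#'   expression-derived).
#' @param dag a [term_dag()].
#' @param annotation,universe see [hypergeom_enrich()].
#' @param k top-score count, see [aggregate_similarity()].
#' @param n_boot CI bootstrap resamples, see [aggregate_similarity()].
#' @param seed master seed (term selection and CI derive substreams).
#' @return A `similarity_aggregate`, or `NULL` when a selection came back
#'   empty (possible for tiny fixtures).
#' @export
go_similarity_pipeline <- function(mut_genes, expr_genes, dag, annotation,
                                   universe, k = 1000, n_boot = 1000,
                                   seed = 1) {
  e_mut <- hypergeom_enrich(mut_genes, annotation, universe, "mutation")
  e_expr <- hypergeom_enrich(expr_genes, annotation, universe, "expression")
  t_mut <- select_terms(e_mut, derive_seed(seed, 1))
  t_expr <- select_terms(e_expr, derive_seed(seed, 2))
  if (length(t_mut) == 0L || length(t_expr) == 0L) return(NULL)
  aggregate_similarity(t_mut, t_expr, dag, k = k, n_boot = n_boot,
                       seed = derive_seed(seed, 3))
}

#' Baseline-normalized relative semantic similarity
#'
#' Semantic-similarity aggregates scale with gene-list length, so the
#' observed top-k median is normalized against random gene lists of the
#' same lengths run through the identical pipeline: the baseline is the
#' median plus one standard deviation of the simulated medians, and the
#' relative score is `observed / baseline`. A relative score above 1
#' indicates more cross-modality similarity than length alone explains.
#'
#' @param observed a `similarity_aggregate` from the real lists.
#' @param random_lists_generator function(seed) returning
#'   `list(mut = ..., expr = ...)` random gene lists of the observed
#'   lengths (see [random_gene_list_generator()]).
#' @param dag,annotation,universe,k pipeline context, as in
#'   [go_similarity_pipeline()].
#' @param n_random number of random-list replicates, default 20.
#' @param seed master seed.
#' @return The `observed` aggregate with `baseline` and `relative_score`
#'   filled in, plus `baseline_medians`.
#' @export
baseline_relative_score <- function(observed, random_lists_generator,
                                    dag, annotation, universe,
                                    k = 1000, n_random = 20, seed = 1) {
  stopifnot(inherits(observed, "similarity_aggregate"), n_random >= 2L)
  meds <- rep(NA_real_, n_random)
  for (r in seq_len(n_random)) {
    sr <- derive_seed(seed, 100 + r)
    gl <- random_lists_generator(sr)
    agg <- go_similarity_pipeline(gl$mut, gl$expr, dag, annotation,
                                  universe, k = k, n_boot = 0L,
                                  seed = derive_seed(sr, 1))
    if (!is.null(agg)) meds[r] <- agg$median
  }
  meds <- meds[!is.na(meds)]
  if (length(meds) < 2L) {
    stop("too few successful baseline replicates", call. = FALSE)
  }
  baseline <- median(meds) + sd(meds)
  if (!is.finite(baseline) || baseline <= 0) {
    stop("degenerate baseline (zero or non-finite)", call. = FALSE)
  }
  observed$baseline <- baseline
  observed$relative_score <- observed$median / baseline
  observed$baseline_medians <- meds
  observed
}

#' Generator of random gene lists of fixed lengths
#'
#' @param universe gene universe to draw from.
#' @param len_mut,len_expr list lengths to match.
#' @return A function(seed) returning `list(mut, expr)`.
#' @export
random_gene_list_generator <- function(universe, len_mut, len_expr) {
  force(universe); force(len_mut); force(len_expr)
  function(seed) {
    set.seed(seed)
    list(mut = sample(universe, len_mut),
         expr = sample(universe, len_expr))
  }
}

#' Cross-modality correlation of enrichment significance
#'
#' For terms significantly enriched in both modalities, correlates
#' `-log10(p)` across modalities (Spearman by default; Pearson available).
#' Extreme outlier terms (`-log10(p) > outlier_cut` on either axis) are
#' excluded, and no coefficient is computed when fewer than `min_shared`
#' terms remain -- non-computation is a valid result.
#'
#' @param shared data.frame with columns `term`, `p_mut`, `p_expr`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha per-modality significance cutoff, default 0.05.
#' @param min_shared minimum usable shared terms, default 5.
#' @param outlier_cut `-log10(p)` exclusion threshold, default 10.
#' @return A `correlation_result`: coefficient, n_shared_terms,
#'   excluded_outliers, computed, method.
#' @export
correlate_modalities <- function(shared,
                                 method = c("spearman", "pearson"),
                                 alpha = 0.05, min_shared = 5,
                                 outlier_cut = 10) {
  method <- match.arg(method)
  stopifnot(is.data.frame(shared),
            all(c("term", "p_mut", "p_expr") %in% names(shared)))
  sig <- shared[shared$p_mut < alpha & shared$p_expr < alpha, , drop = FALSE]
  lm10 <- function(p) -log10(p)
  out <- lm10(sig$p_mut) > outlier_cut | lm10(sig$p_expr) > outlier_cut
  excluded <- sig$term[out]
  use <- sig[!out, , drop = FALSE]
  if (nrow(use) < min_shared) {
    res <- list(coefficient = NA_real_, n_shared_terms = nrow(use),
                excluded_outliers = excluded, computed = FALSE,
                method = method)
  } else {
    res <- list(coefficient = cor(lm10(use$p_mut), lm10(use$p_expr),
                                  method = method),
                n_shared_terms = nrow(use),
                excluded_outliers = excluded, computed = TRUE,
                method = method)
  }
  structure(res, class = "correlation_result")
}
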