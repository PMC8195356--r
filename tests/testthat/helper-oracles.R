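# Independent oracles: naive transliterations kept deliberately separate
# from the package implementations they check.

# k-sample Anderson-Darling (midrank variant), scalar loops straight from
# the discrete definition: B_j and M_ij as "count below + half the count
# equal" at each distinct pooled value.
oracle_ad_A2akN <- function(x, y) {
  samples <- list(x, y)
  N <- length(x) + length(y)
  z <- sort(c(x, y))
  zstar <- unique(z)
  total <- 0
  for (i in 1:2) {
    xi <- samples[[i]]
    ni <- length(xi)
    inner <- 0
    for (zj in zstar) {
      lj <- sum(z == zj)
      Bj <- sum(z < zj) + lj / 2
      Mij <- sum(xi < zj) + sum(xi == zj) / 2
      inner <- inner + (lj / N) * (N * Mij - ni * Bj)^2 /
        (Bj * (N - Bj) - N * lj / 4)
    }
    total <- total + inner / ni
  }
  (N - 1) / N * total
}

# null sd of the raw statistic via the direct double sum for g
oracle_ad_T <- function(x, y) {
  k <- 2
  n_i <- c(length(x), length(y))
  N <- sum(n_i)
  H <- sum(1 / n_i)
  h <- sum(1 / seq_len(N - 1))
  g <- 0
  for (i in seq_len(N - 2)) {
    for (j in (i + 1):(N - 1)) g <- g + 1 / ((N - i) * j)
  }
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H -
    8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k +
    (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  sigma2 <- (a * N^3 + b * N^2 + cc * N + d) /
    ((N - 1) * (N - 2) * (N - 3))
  (oracle_ad_A2akN(x, y) - (k - 1)) / sqrt(sigma2)
}

# Mood's median test by explicit contingency-table construction
oracle_moods <- function(groups) {
  gm <- median(unlist(groups))
  k <- length(groups)
  tab <- matrix(0, 2, k)
  for (i in seq_len(k)) {
    tab[1, i] <- sum(groups[[i]] > gm)
    tab[2, i] <- sum(groups[[i]] <= gm)
  }
  stat <- 0
  for (r in 1:2) {
    for (i in seq_len(k)) {
      e <- sum(tab[r, ]) * sum(tab[, i]) / sum(tab)
      stat <- stat + (tab[r, i] - e)^2 / e
    }
  }
  list(statistic = stat, df = k - 1,
       p_value = pchisq(stat, k - 1, lower.tail = FALSE))
}

# Wang S-values by max-path-product relaxation (value propagation from the
# focal term upward), a different algorithm from the package's topological
# sweep.
oracle_wang_svalues <- function(edges, weights, term) {
  s <- setNames(1, term)
  queue <- term
  while (length(queue) > 0L) {
    c0 <- queue[[1L]]
    queue <- queue[-1L]
    pe <- edges[edges$child == c0, , drop = FALSE]
    for (r in seq_len(nrow(pe))) {
      p <- pe$parent[r]
      val <- weights[[pe$relation[r]]] * s[[c0]]
      if (is.na(s[p]) || val > s[[p]]) {
        s[p] <- val
        queue <- c(queue, p)
      }
    }
  }
  s
}

oracle_wang_sim <- function(edges, weights, a, b) {
  sa <- oracle_wang_svalues(edges, weights, a)
  sb <- oracle_wang_svalues(edges, weights, b)
  common <- intersect(names(sa), names(sb))
  (sum(sa[common]) + sum(sb[common])) / (sum(sa) + sum(sb))
}
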