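# Two-sample Anderson-Darling comparison (Scholz-Stephens k-sample form,
# k = 2, midrank/tie-adjusted variant) with a bootstrapped p-value and the
# acceptance rule <p> - sdev(p) > alpha used to keep simulations whose DIP
# distributions are statistically indistinguishable from experiment.

# Critical values of the standardized statistic T_m for m = k - 1 = 1 at
# the published significance levels, from the interpolation formula
# t_m = b0 + b1 / sqrt(m) + b2 / m of Scholz & Stephens.
.ad_sig <- c(0.25, 0.10, 0.05, 0.025, 0.01, 0.005, 0.001)
.ad_b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326, 2.573, 3.085)
.ad_b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822, 2.364, 3.615)
.ad_b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396, -0.345, -0.154)
.ad_tm <- .ad_b0 + .ad_b1 + .ad_b2

#' Two-sample Anderson-Darling test (k-sample form, midrank variant)
#'
#' Computes the tie-adjusted (midrank) k-sample Anderson-Darling statistic
#' for k = 2, its standardized version, and an interpolated p-value.
#' The p-value is obtained by piecewise-linear interpolation of
#' log-significance against the published critical values of the
#' standardized statistic and clipped to `[0.001, 0.25]`; the acceptance
#' rule used downstream only needs resolution around 0.05, well inside the
#' reliable interpolation range.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return An `ad_result`: `statistic` (standardized), `A2akN` (raw
#'   midrank statistic), `p_value`, and sample sizes.
#' @examples
#' set.seed(1)
#' ad_2sample(rnorm(50), rnorm(50))$p_value
#' @export
ad_2sample <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 2L, length(y) >= 2L,
            all(is.finite(x)), all(is.finite(y)))
  samples <- list(x, y)
  k <- 2L
  n_i <- lengths(samples)
  N <- sum(n_i)
  pooled <- sort(c(x, y))
  zstar <- unique(pooled)
  L <- length(zstar)
  if (L < 2L) {
    stop("degenerate input: pooled sample has a single distinct value",
         call. = FALSE)
  }
  lj <- tabulate(match(pooled, zstar), nbins = L)
  Bj <- cumsum(lj) - lj / 2
  inner <- 0
  for (i in seq_len(k)) {
    fij <- tabulate(match(samples[[i]], zstar), nbins = L)
    Maij <- cumsum(fij) - fij / 2
    num <- (N * Maij - n_i[i] * Bj)^2
    den <- Bj * (N - Bj) - N * lj / 4
    inner <- inner + sum(lj / N * num / den) / n_i[i]
  }
  A2akN <- (N - 1) / N * inner
  # null standard deviation of the raw statistic (Scholz & Stephens)
  H <- sum(1 / n_i)
  hs <- cumsum(1 / seq_len(N - 1))
  h <- hs[N - 1]
  i <- seq_len(N - 2)
  g <- sum((hs[N - 1] - hs[i]) / (N - i))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H -
    8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k +
    (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  sigma2 <- (a * N^3 + b * N^2 + cc * N + d) /
    ((N - 1) * (N - 2) * (N - 3))
  Tstat <- (A2akN - (k - 1)) / sqrt(sigma2)
  p <- exp(approx(.ad_tm, log(.ad_sig), xout = Tstat, rule = 2)$y)
  structure(list(statistic = Tstat, A2akN = A2akN, p_value = p,
                 n = n_i),
            class = "ad_result")
}

#' Bootstrapped Anderson-Darling comparison with the acceptance rule
#'
#' The p-value of a simulated-vs-experimental DIP distribution comparison
#' is bootstrapped over `n_resamples` resamples (with replacement, at the
#' experimental sample size) of the experimental distribution; each
#' resample is tested against the full simulated distribution. The
#' comparison passes when `mean(p) - sd(p) > alpha`, i.e. the simulation is
#' kept only when the null of a common distribution cannot be rejected
#' robustly across resamples.
#'
#' @param simulated,experimental [dip_distribution()] objects or numeric
#'   vectors.
#' @param n_resamples number of bootstrap resamples, default 100.
#' @param alpha acceptance threshold, default 0.05.
#' @param seed integer seed for the resampling.
#' @return A `bootstrap_comparison`: p_values, p_mean, p_sd, n_resamples,
#'   passed.
#' @export
bootstrap_ad <- function(simulated, experimental, n_resamples = 100,
                         alpha = 0.05, seed = 1) {
  sim <- if (inherits(simulated, "dip_distribution")) {
    simulated$dip_rates
  } else as.numeric(simulated)
  ex <- if (inherits(experimental, "dip_distribution")) {
    experimental$dip_rates
  } else as.numeric(experimental)
  stopifnot(length(sim) >= 2L, length(ex) >= 2L)
  if (n_resamples < 2L) {
    stop("n_resamples must be >= 2 (sd undefined otherwise)", call. = FALSE)
  }
  set.seed(seed)
  ne <- length(ex)
  p <- vapply(seq_len(n_resamples), function(r) {
    ad_2sample(sim, ex[sample.int(ne, ne, replace = TRUE)])$p_value
  }, numeric(1))
  pm <- mean(p)
  ps <- sd(p)
  structure(list(p_values = p, p_mean = pm, p_sd = ps,
                 n_resamples = n_resamples, alpha = alpha,
                 passed = (pm - ps) > alpha),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_comparison> <p> = %.4f, sdev(p) = %.4f, passed = %s\n",
    x$p_mean, x$p_sd, x$passed))
  invisible(x)
}
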