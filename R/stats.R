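#' Friedman rank test for repeated measures across sleep stages
#'
#' Rank-based omnibus test for differences between k related conditions
#' (stages) measured on n subjects. Values are ranked within each subject
#' (average ranks for ties) and the chi-square statistic
#' `12/(n k (k+1)) * sum(R_j^2) - 3 n (k+1)` is divided by the standard tie
#' correction `1 - sum(t^3 - t) / (n (k^3 - k))`. If every subject's row is
#' constant the statistic is 0 with p = 1. The p-value comes from the
#' chi-square distribution with k - 1 degrees of freedom.
#'
#' @param table numeric subjects x conditions matrix (>= 2 subjects,
#'   >= 3 conditions), e.g. a [subject_stage_tables()] element.
#' @return List with `statistic`, `df`, `p`.
#' @export
friedman_rank_test <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  if (n < 2 || k < 3) stop("need >= 2 subjects and >= 3 conditions")
  if (any(!is.finite(table))) stop("table contains non-finite values")
  R <- t(apply(table, 1, rank))
  Rj <- colSums(R)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- apply(table, 1, function(row) {
    t_sizes <- table(row)
    sum(t_sizes^3 - t_sizes)
  })
  corr <- 1 - sum(ties) / (n * (k^3 - k))
  if (corr <= 0) {
    return(list(statistic = 0, df = k - 1, p = 1))
  }
  stat <- stat / corr
  list(statistic = stat, df = k - 1, p = pchisq(stat, k - 1, lower.tail = FALSE))
}

#' Nemenyi post-hoc test after a Friedman omnibus test
#'
#' All-pairs comparison of conditions via the studentized-range distribution
#' applied to mean-rank differences: for conditions a, b the statistic is
#' `q = |Rbar_a - Rbar_b| / sqrt(k (k+1) / (6 n))` and the p-value is
#' `P(Q_{k, Inf} >= q * sqrt(2))`, which controls the family-wise error over
#' the k(k-1)/2 comparisons. Critical values are taken from
#' [stats::ptukey()], not from a lookup table.
#'
#' @inheritParams friedman_rank_test
#' @return Symmetric k x k matrix of p-values with unit diagonal.
#' @export
nemenyi_test <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  if (n < 2 || k < 3) stop("need >= 2 subjects and >= 3 conditions")
  R <- t(apply(table, 1, rank))
  rbar <- colMeans(R)
  se <- sqrt(k * (k + 1) / (6 * n))
  P <- matrix(1, k, k, dimnames = list(colnames(table), colnames(table)))
  for (a in seq_len(k - 1)) for (b in seq.int(a + 1, k)) {
    q <- abs(rbar[a] - rbar[b]) / se
    p <- ptukey(q * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
    P[a, b] <- P[b, a] <- p
  }
  P
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha nominal family-wise error rate (default 0.05).
#' @param m number of tests in the family (`>= 1`); the full stage-difference
#'   battery has 6 metrics x 4 bands = 24 tests, giving 0.05/24 = 0.002083.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Shapiro-Wilk normality screen
#'
#' Gate for the nonparametric branch of the analysis: the pooled values of
#' one FC parameter are screened for normality and the pipeline proceeds
#' with rank-based tests when normality is rejected (as it is for phase
#' coupling coefficients, which are bounded and skewed). Backed by
#' [stats::shapiro.test()]; samples above its 5000-value limit are
#' subsampled deterministically.
#'
#' @param values numeric vector, `n >= 3`; must not be constant.
#' @return The Shapiro-Wilk p-value.
#' @export
normality_screen <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 finite values")
  if (length(unique(values)) == 1) stop("constant sample: normality test undefined")
  if (length(values) > 5000) {
    values <- values[round(seq(1, length(values), length.out = 5000))]
  }
  shapiro.test(values)$p.value
}

#' Stage-difference test battery over all metrics and bands
#'
#' Runs one Friedman omnibus test per metric x band family on the
#' subject-by-stage tables, controls the family-wise error rate across the
#' battery by Bonferroni (threshold `alpha / m` with m = metrics x bands;
#' 0.05/24 for the full battery), and computes Nemenyi post-hoc pairwise
#' stage comparisons only where the omnibus test is significant.
#'
#' @param fc an `fc_features` object containing all metrics to be tested.
#' @param metrics metrics to include (default: all present in `fc`).
#' @param alpha nominal family-wise error rate.
#' @return Data frame with one row per metric x band: `metric`, `band`,
#'   `friedman_chi2`, `p`, `significant`, and six pairwise Nemenyi p-value
#'   columns (`W_N1`, `W_N2`, `W_N3`, `N1_N2`, `N1_N3`, `N2_N3`; `NA` where
#'   the omnibus test was not significant). The adjusted threshold and test
#'   count are attached as attributes `alpha_adjusted` and `n_tests`.
#' @export
stage_statistics <- function(fc, metrics = names(fc$features), alpha = 0.05) {
  pairs <- c("W_N1", "W_N2", "W_N3", "N1_N2", "N1_N3", "N2_N3")
  m <- length(metrics) * length(fc$band_names)
  alpha_adj <- bonferroni_threshold(alpha, m)
  rows <- list()
  for (met in metrics) {
    tabs <- subject_stage_tables(fc, met)
    for (b in fc$band_names) {
      fr <- friedman_rank_test(tabs[[b]])
      sig <- fr$p < alpha_adj
      pv <- rep(NA_real_, length(pairs))
      names(pv) <- pairs
      if (sig) {
        P <- nemenyi_test(tabs[[b]])
        for (pp in pairs) {
          ab <- strsplit(pp, "_", fixed = TRUE)[[1]]
          pv[pp] <- P[ab[1], ab[2]]
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        metric = met, band = b, friedman_chi2 = fr$statistic, p = fr$p,
        significant = sig, t(pv), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "alpha_adjusted") <- alpha_adj
  attr(out, "n_tests") <- m
  out
}
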