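#' Per-gene pooled-variance t statistics between two species
#'
#' For each shared ortholog, computes the pooled variance
#' \deqn{s_p^2 = \frac{SD_1^2 (n_1 - 1) + SD_2^2 (n_2 - 1)}{n_1 + n_2 - 2}}
#' and the equal-variance two-sample t statistic
#' \eqn{t = (\bar x_1 - \bar x_2) / \sqrt{s_p^2 (1/n_1 + 1/n_2)}} with
#' \eqn{n_1 + n_2 - 2} degrees of freedom, two-sided by default.
#'
#' Genes with zero pooled variance get `p = 1` when the means are equal and
#' `p = 0` (with a warning) when they differ.
#'
#' @param a,b Harmonized [expression_dataset()]s (identical gene sets, at
#'   least 2 samples each).
#' @param two_sided Two-sided p-values (default `TRUE`).
#' @return Data frame, one row per ortholog: `ortholog_id`, `mean_a`,
#'   `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`, `pooled_variance`, `t_stat`,
#'   `p_value`.
#' @export
deg_statistics <- function(a, b, two_sided = TRUE) {
  stopifnot(is_expression_dataset(a), is_expression_dataset(b))
  if (!identical(rownames(a$values), rownames(b$values)))
    stop("datasets must share an identical gene set (harmonize first)")
  n1 <- ncol(a$values); n2 <- ncol(b$values)
  if (n1 < 2 || n2 < 2) stop("at least 2 samples per species are required")
  m1 <- rowMeans(a$values); m2 <- rowMeans(b$values)
  s1 <- row_sds(a$values); s2 <- row_sds(b$values)
  df <- n1 + n2 - 2
  pooled <- (s1^2 * (n1 - 1) + s2^2 * (n2 - 1)) / df
  se <- sqrt(pooled * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, (m1 - m2) / se, 0)
  p <- if (two_sided) 2 * stats::pt(-abs(t_stat), df)
       else stats::pt(t_stat, df, lower.tail = FALSE)
  zero_var <- pooled == 0
  if (any(zero_var)) {
    unequal <- zero_var & (m1 != m2)
    p[zero_var & !unequal] <- 1
    if (any(unequal)) {
      warning(sum(unequal),
              " gene(s) with zero pooled variance but unequal means; p set to 0")
      p[unequal] <- 0
      t_stat[unequal] <- sign(m1[unequal] - m2[unequal]) * Inf
    }
  }
  data.frame(ortholog_id = rownames(a$values),
             mean_a = m1, mean_b = m2, sd_a = s1, sd_b = s2,
             n_a = n1, n_b = n2, pooled_variance = pooled,
             t_stat = t_stat, p_value = pmin(1, p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up BH adjustment with monotonicity enforcement; the output
#' preserves the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop("p-values must be numeric in [0, 1] without missing values")
  stats::p.adjust(p_values, method = "BH")
}

#' Identify differentially expressed orthologs between species
#'
#' Removes the genes in the bottom `variance_percentile` percent of the
#' pooled-variance distribution, tests the remainder with the pooled
#' two-sample t-test of [deg_statistics()], applies BH correction over the
#' filtered gene count, and flags genes with `q <= alpha` as significant.
#'
#' @inheritParams deg_statistics
#' @param variance_percentile Percent of lowest-pooled-variance genes
#'   excluded before testing (default 30; 0 disables the filter).
#' @param alpha Significance threshold on the q-value (default 0.05).
#' @return Data frame as [deg_statistics()] restricted to tested genes, plus
#'   `q_value` and `significant`; the removed gene ids are attached as
#'   attribute `"filtered_out"`.
#' @export
identify_degs <- function(a, b, variance_percentile = 30, alpha = 0.05,
                          two_sided = TRUE) {
  if (variance_percentile < 0 || variance_percentile >= 100)
    stop("variance_percentile must lie in [0, 100)")
  tab <- deg_statistics(a, b, two_sided = two_sided)
  m <- nrow(tab)
  n_drop <- floor(m * variance_percentile / 100)
  drop_idx <- if (n_drop > 0) order(tab$pooled_variance)[seq_len(n_drop)]
              else integer(0)
  kept <- if (length(drop_idx)) tab[-drop_idx, , drop = FALSE] else tab
  if (nrow(kept) < 2) stop("fewer than 2 genes survive the variance filter")
  kept$q_value <- bh_adjust(kept$p_value)
  kept$significant <- kept$q_value <= alpha
  rownames(kept) <- NULL
  attr(kept, "filtered_out") <- tab$ortholog_id[drop_idx]
  kept
}
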