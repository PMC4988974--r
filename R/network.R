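#' Signed weighted adjacency from a correlation matrix
#'
#' Applies the standard signed soft-threshold transform
#' \eqn{a_{ij} = ((1 + cor_{ij})/2)^\beta}, which maps correlation -1 to 0
#' and +1 to 1, preserving the sign of co-expression. The diagonal is set to
#' 0 so connectivity sums exclude self-edges.
#'
#' @param corr Symmetric Pearson correlation matrix (e.g.
#'   `cor(t(expr$values))`).
#' @param beta Soft-threshold power, an integer >= 1.
#' @return Adjacency matrix in \[0, 1\] with zero diagonal and attribute
#'   `"beta"`.
#' @export
signed_adjacency <- function(corr, beta) {
  if (length(beta) != 1 || beta < 1 || beta != round(beta))
    stop("beta must be a single integer >= 1")
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr)) stop("correlation matrix must be square")
  a <- ((1 + corr) / 2)^beta
  diag(a) <- 0
  attr(a, "beta") <- as.integer(beta)
  a
}

#' Scale-free fit of the connectivity distribution for one adjacency
#'
#' Bins node connectivities into `n_bins` equal-width bins and regresses
#' log10 frequency on log10 mean bin connectivity; returns the R-squared.
#' Degenerate (all-equal) connectivities give R-squared 0.
#' @noRd
scale_free_r2 <- function(k, n_bins = 10) {
  if (length(unique(k)) < 2) return(0)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(ok) < 3) return(0)
  fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  summary(fit)$r.squared
}

#' Choose a soft-threshold power by approximate scale-free fit
#'
#' For each candidate power, builds the signed adjacency, computes node
#' connectivities, and measures how well the connectivity distribution
#' follows a power law (R-squared of the log-log frequency regression over
#' 10 bins). The smallest candidate reaching `r2_target` is chosen; if none
#' does, the candidate with the best fit is chosen with a warning.
#'
#' @param corr Correlation matrix.
#' @param candidates Integer powers to scan (default `1:20`).
#' @param r2_target Required scale-free fit (default 0.8).
#' @return A `SoftThresholdReport` list: `table` (data frame of `beta`,
#'   `r_squared`, `mean_connectivity`) and `beta` (the chosen power).
#' @export
pick_soft_threshold <- function(corr, candidates = 1:20, r2_target = 0.8) {
  if (length(candidates) < 1) stop("at least one candidate power is required")
  candidates <- sort(unique(as.integer(candidates)))
  res <- lapply(candidates, function(b) {
    a <- signed_adjacency(corr, b)
    k <- rowSums(a)
    data.frame(beta = b, r_squared = scale_free_r2(k),
               mean_connectivity = mean(k))
  })
  tab <- do.call(rbind, res)
  hit <- which(tab$r_squared >= r2_target)
  if (length(hit)) {
    beta <- tab$beta[hit[1]]
  } else {
    beta <- tab$beta[which.max(tab$r_squared)]
    warning(sprintf(
      "no candidate reaches scale-free fit R^2 >= %.2f; using beta = %d (best R^2 = %.3f)",
      r2_target, beta, max(tab$r_squared)))
  }
  structure(list(table = tab, beta = beta), class = "SoftThresholdReport")
}

#' Topological overlap matrix and its dissimilarity
#'
#' Computes the topological overlap
#' \deqn{TOM_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' with shared-neighbor term \eqn{l_{ij} = \sum_u a_{iu} a_{uj}} (the sum
#' excludes \eqn{u \in \{i, j\}}, automatic with a zero diagonal) and node
#' connectivity \eqn{k_i = \sum_u a_{iu}}, plus the dissimilarity
#' `DisTOM = 1 - TOM`. Diagonal TOM is 1 by convention. Isolated node pairs
#' (zero connectivity, zero adjacency) have TOM 0.
#'
#' @param adj Adjacency matrix from [signed_adjacency()] (symmetric,
#'   entries in \[0, 1\], zero diagonal).
#' @return A `TOMMatrix` list: `tom`, `dist` (= 1 - tom), and `k` (node
#'   connectivities).
#' @export
tom_similarity <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency must be square")
  if (any(adj < 0 | adj > 1)) stop("adjacency entries must lie in [0, 1]")
  diag(adj) <- 0
  k <- rowSums(adj)
  l <- adj %*% adj            # zero diagonal makes u = i, j terms vanish
  min_k <- outer(k, k, pmin)
  tom <- (l + adj) / (min_k + 1 - adj)
  diag(tom) <- 1
  d <- 1 - tom
  structure(list(tom = tom, dist = d, k = k), class = "TOMMatrix")
}
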