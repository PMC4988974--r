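#' Harmonize two species datasets onto shared ortholog identifiers
#'
#' Maps each species' transcripts to ortholog ids via its best-hit map
#' (retaining only hits with e-value <= `evalue_cutoff`), collapses multiple
#' transcripts of the same ortholog to the one with maximal sample standard
#' deviation (ties broken by lexicographically smallest transcript id), and
#' restricts both datasets to the orthologs present in both, in sorted order.
#'
#' @param a,b [expression_dataset()]s indexed by transcript id.
#' @param map_a,map_b Data frames with columns `transcript_id`,
#'   `ortholog_id`, `evalue`.
#' @param evalue_cutoff Maximum e-value for a hit to be used (default 1e-5).
#' @return A list with `a` and `b`: harmonized datasets indexed by ortholog
#'   id with identical, sorted gene sets. Element `transcript_of` records the
#'   transcript chosen per ortholog in each species (`transcript_of$a`,
#'   `transcript_of$b`, named by ortholog id).
#' @export
harmonize_orthologs <- function(a, b, map_a, map_b, evalue_cutoff = 1e-5) {
  stopifnot(is_expression_dataset(a), is_expression_dataset(b))
  pick <- function(x, map) {
    map <- map[map$evalue <= evalue_cutoff, , drop = FALSE]
    map <- map[map$transcript_id %in% rownames(x$values), , drop = FALSE]
    if (!nrow(map)) stop("ortholog map covers no transcripts in the dataset")
    # one best hit per transcript (smallest e-value, then lexicographic)
    map <- map[order(map$transcript_id, map$evalue), , drop = FALSE]
    map <- map[!duplicated(map$transcript_id), , drop = FALSE]
    sds <- row_sds(x$values)[map$transcript_id]
    # keep the max-SD transcript per ortholog; ties -> smallest transcript id
    ord <- order(map$ortholog_id, -sds, map$transcript_id)
    map <- map[ord, , drop = FALSE]
    map <- map[!duplicated(map$ortholog_id), , drop = FALSE]
    stats::setNames(map$transcript_id, map$ortholog_id)
  }
  ta <- pick(a, map_a)
  tb <- pick(b, map_b)
  shared <- sort(intersect(names(ta), names(tb)))
  if (!length(shared)) stop("empty intersection of ortholog sets")
  ta <- ta[shared]
  tb <- tb[shared]
  ha <- expression_dataset(a$values[ta, , drop = FALSE], gene_ids = shared,
                           species = a$species)
  hb <- expression_dataset(b$values[tb, , drop = FALSE], gene_ids = shared,
                           species = b$species)
  list(a = ha, b = hb, transcript_of = list(a = ta, b = tb))
}

#' Quality-control filter for an expression dataset
#'
#' Removes genes with an excessive fraction of missing values or a
#' near-constant profile, and flags (and drops) outlying samples whose
#' standardized mean inter-sample correlation falls below `-outlier_z`.
#'
#' @param x An [expression_dataset()].
#' @param max_missing_frac Genes with a larger missing fraction are removed
#'   (default 0.5).
#' @param min_sd Genes with sample SD below this are removed (default 1e-8,
#'   i.e. constant genes).
#' @param outlier_z Threshold on the standardized mean inter-sample
#'   correlation (default 2.5); samples below `-outlier_z` are flagged.
#' @return A list: `x` (filtered dataset) and `report`, itself a list with
#'   `genes_removed` (data frame of gene and reason), `samples_flagged`,
#'   `n_genes_before/after`, `n_samples_before/after`.
#' @export
qc_filter <- function(x, max_missing_frac = 0.5, min_sd = 1e-8,
                      outlier_z = 2.5) {
  stopifnot(is_expression_dataset(x))
  v <- x$values
  miss <- rowMeans(is.na(v))
  sds <- row_sds(v)
  reason <- character(0); gene <- character(0)
  bad_miss <- miss > max_missing_frac
  bad_sd <- !bad_miss & (is.na(sds) | sds < min_sd)
  gene <- c(rownames(v)[bad_miss], rownames(v)[bad_sd])
  reason <- c(rep("missing_values", sum(bad_miss)),
              rep("low_sd", sum(bad_sd)))
  keep <- !(bad_miss | bad_sd)
  if (!any(keep)) stop("qc_filter removed all genes")
  v <- v[keep, , drop = FALSE]

  flagged <- character(0)
  if (ncol(v) >= 3) {
    cc <- stats::cor(v, use = "pairwise.complete.obs")
    diag(cc) <- NA
    mean_cor <- rowMeans(cc, na.rm = TRUE)
    z <- (mean_cor - mean(mean_cor)) / stats::sd(mean_cor)
    if (!any(is.na(z))) {
      flagged <- colnames(v)[z < -outlier_z]
      if (length(flagged)) v <- v[, !(colnames(v) %in% flagged), drop = FALSE]
    }
  }
  report <- list(
    genes_removed = data.frame(gene = gene, reason = reason,
                               stringsAsFactors = FALSE),
    samples_flagged = flagged,
    n_genes_before = nrow(x$values), n_genes_after = nrow(v),
    n_samples_before = ncol(x$values), n_samples_after = ncol(v))
  list(x = expression_dataset(v, species = x$species), report = report)
}

#' Rank-based comparability check between two harmonized datasets
#'
#' Computes each gene's mean expression in each dataset, converts the means
#' to ranks (average rank for ties), and reports the Pearson correlation of
#' the ranks with its p-value -- i.e. a Spearman correlation of per-gene
#' average expression, the standard cross-platform comparability measure.
#'
#' @param a,b Harmonized [expression_dataset()]s with identical gene sets.
#' @return A list `r`, `p`, `n_shared` (class `ComparabilityResult`).
#' @export
comparability_check <- function(a, b) {
  stopifnot(is_expression_dataset(a), is_expression_dataset(b))
  if (!identical(rownames(a$values), rownames(b$values)))
    stop("datasets must share an identical gene set (harmonize first)")
  if (nrow(a$values) < 3) stop("fewer than 3 shared genes")
  ma <- rowMeans(a$values, na.rm = TRUE)
  mb <- rowMeans(b$values, na.rm = TRUE)
  ct <- stats::cor.test(rank(ma), rank(mb), method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 n_shared = length(ma)), class = "ComparabilityResult")
}

#' Joint PCA overview of samples from both species
#'
#' Projects all samples of both datasets into one shared two-dimensional
#' principal-component space (genes as variables, gene-wise centered),
#' to visualize overall between-species expression separation.
#'
#' @param a,b Harmonized [expression_dataset()]s with identical gene sets.
#' @return Data frame with `sample`, `species`, `pc1`, `pc2` and the
#'   variance explained as attribute `"var_explained"`.
#' @export
pca_overview <- function(a, b) {
  stopifnot(is_expression_dataset(a), is_expression_dataset(b))
  if (!identical(rownames(a$values), rownames(b$values)))
    stop("datasets must share an identical gene set (harmonize first)")
  m <- t(cbind(a$values, b$values))  # samples x genes
  species <- c(rep(a$species, ncol(a$values)), rep(b$species, ncol(b$values)))
  if (nrow(m) < 3) {
    warning("fewer than 3 samples: PCA is degenerate, second component set to 0")
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  scores <- pc$x
  pc1 <- scores[, 1]
  pc2 <- if (ncol(scores) >= 2) scores[, 2] else rep(0, nrow(m))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  out <- data.frame(sample = rownames(m), species = species,
                    pc1 = pc1, pc2 = pc2, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "var_explained") <- ve[seq_len(min(2, length(ve)))]
  out
}
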