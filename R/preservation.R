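#' Preservation category from a Z-summary score
#'
#' Standard thresholds: below 2 no evidence of preservation, 2 to 10
#' moderate, above 10 strong.
#'
#' @param z Numeric Z-summary score(s).
#' @return Character vector: `"not_preserved"`, `"moderate"` or `"strong"`.
#' @export
preservation_category <- function(z) {
  ifelse(z < 2, "not_preserved", ifelse(z <= 10, "moderate", "strong"))
}

# Eigengene and kME for an imposed gene set on a dataset: first PC of the
# standardized member expression, oriented towards the mean profile.
imposed_kme <- function(x, genes) {
  v <- x$values[genes, , drop = FALSE]
  z <- t(scale(t(v)))
  z[is.na(z)] <- 0
  e <- if (nrow(z) == 1) as.numeric(z) else {
    sv <- svd(z, nu = 0, nv = 1)
    ev <- sv$v[, 1]
    if (stats::sd(colMeans(z)) > 0 && stats::cor(ev, colMeans(z)) < 0)
      ev <- -ev
    ev
  }
  kme <- suppressWarnings(as.numeric(stats::cor(t(x$values), e)))
  names(kme) <- rownames(x$values)
  kme
}

# The four preservation statistics for a gene set, given precomputed
# correlation/adjacency matrices of reference and test datasets.
preservation_stats <- function(genes, cor_test, adj_ref, adj_test,
                               ref_x, test_x) {
  ct <- cor_test[genes, genes]
  at <- adj_test[genes, genes]
  off <- row(ct) != col(ct)
  k_ref <- rowSums(adj_ref[genes, genes])
  k_test <- rowSums(at)
  safe_cor <- function(a, b) {
    r <- suppressWarnings(stats::cor(a, b))
    if (is.na(r)) 0 else r
  }
  kme_ref <- imposed_kme(ref_x, genes)[genes]
  kme_test <- imposed_kme(test_x, genes)[genes]
  c(mean_cor = mean(ct[off]),
    mean_adj = mean(at[off]),
    cor_k = safe_cor(k_ref, k_test),
    cor_kme = safe_cor(kme_ref, kme_test))
}

#' Permutation Z-summary module preservation between two datasets
#'
#' Module definitions from the reference partition are imposed on the test
#' dataset and scored with two density statistics (mean intramodule
#' correlation and adjacency in the test network) and two connectivity
#' statistics (correlation of intramodular connectivities and of kME values
#' between reference and test). Each statistic is standardized against a
#' permutation null of same-size random gene sets drawn from the shared
#' universe; `z_density` and `z_connectivity` are the medians of their
#' statistic groups and `z_summary` their mean. A `"gold"` row -- one random
#' gene sample of `gold_size`, evaluated identically -- is included as a
#' negative control. Modules smaller than 3 genes are skipped with a
#' warning; a zero permutation SD yields Z = 0 with a warning.
#'
#' @param ref_x,test_x Harmonized [expression_dataset()]s over a shared
#'   gene universe.
#' @param ref_part `ModulePartition` of the reference dataset.
#' @param n_perm Number of permutations (>= 50; default 100).
#' @param gold_size Size of the random control module (default 50, capped
#'   at the universe size).
#' @param beta Soft-threshold power for the signed adjacencies (default 14).
#' @param seed Optional integer seed for the permutation draws.
#' @return A `PreservationReport` data frame: `module`, `size`, `z_density`,
#'   `z_connectivity`, `z_summary`, `category`, `kme_cor_all`, `kme_p_all`,
#'   `kme_cor_in`, `kme_p_in`.
#' @export
z_summary <- function(ref_x, test_x, ref_part, n_perm = 100, gold_size = 50,
                      beta = 14, seed = NULL) {
  stopifnot(is_expression_dataset(ref_x), is_expression_dataset(test_x))
  if (n_perm < 50) stop("n_perm must be at least 50")
  universe <- intersect(rownames(ref_x$values), rownames(test_x$values))
  if (length(universe) < 4) stop("shared gene universe is too small")
  labels <- ref_part$label_of[names(ref_part$label_of) %in% universe]
  mods <- setdiff(names(sort(table(labels[labels != "grey"]),
                             decreasing = TRUE)), character(0))
  gold_size <- min(gold_size, length(universe))

  cor_test <- suppressWarnings(stats::cor(t(test_x$values[universe, ])))
  cor_ref <- suppressWarnings(stats::cor(t(ref_x$values[universe, ])))
  cor_test[is.na(cor_test)] <- 0
  cor_ref[is.na(cor_ref)] <- 0
  adj_test <- signed_adjacency(cor_test, beta)
  adj_ref <- signed_adjacency(cor_ref, beta)

  stat <- function(genes)
    preservation_stats(genes, cor_test, adj_ref, adj_test, ref_x, test_x)

  with_seed(seed, {
    gold_genes <- sample(universe, gold_size)
    sizes <- c(vapply(mods, function(m) sum(labels == m), integer(1)),
               gold = gold_size)
    names(sizes) <- c(mods, "gold")
    # permutation nulls, one set of draws per distinct module size
    null_for_size <- list()
    for (s in unique(sizes)) {
      draws <- replicate(n_perm, stat(sample(universe, s)))
      null_for_size[[as.character(s)]] <-
        list(mean = rowMeans(draws), sd = apply(draws, 1L, stats::sd))
    }
    rows <- lapply(names(sizes), function(m) {
      s <- sizes[[m]]
      if (m != "gold" && s < 3) {
        warning("module ", m, " has fewer than 3 genes; skipped")
        return(NULL)
      }
      genes <- if (m == "gold") gold_genes else names(labels)[labels == m]
      obs <- stat(genes)
      null <- null_for_size[[as.character(s)]]
      zero_sd <- null$sd == 0
      if (any(zero_sd))
        warning("zero permutation SD for module ", m,
                "; affected Z set to 0")
      z <- ifelse(zero_sd, 0, (obs - null$mean) / null$sd)
      z_density <- stats::median(z[c("mean_cor", "mean_adj")])
      z_connectivity <- stats::median(z[c("cor_k", "cor_kme")])
      data.frame(module = m, size = s, z_density = z_density,
                 z_connectivity = z_connectivity,
                 z_summary = mean(c(z_density, z_connectivity)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$category <- preservation_category(out$z_summary)

    # kME correlations per reference module (test eigengenes imposed)
    all_assigned <- names(labels)[labels != "grey"]
    kme_cols <- lapply(out$module, function(m) {
      if (m == "gold")
        return(data.frame(kme_cor_all = NA_real_, kme_p_all = NA_real_,
                          kme_cor_in = NA_real_, kme_p_in = NA_real_))
      genes <- names(labels)[labels == m]
      kr <- imposed_kme(ref_x, genes)[universe]
      kt <- imposed_kme(test_x, genes)[universe]
      cor_pair <- function(scope) {
        if (length(scope) < 3 || stats::sd(kr[scope]) == 0 ||
            stats::sd(kt[scope]) == 0)
          return(c(NA_real_, NA_real_))
        ct <- stats::cor.test(kr[scope], kt[scope])
        c(unname(ct$estimate), ct$p.value)
      }
      a <- cor_pair(all_assigned); i <- cor_pair(genes)
      data.frame(kme_cor_all = a[1], kme_p_all = a[2],
                 kme_cor_in = i[1], kme_p_in = i[2])
    })
    out <- cbind(out, do.call(rbind, kme_cols))
    rownames(out) <- NULL
    class(out) <- c("PreservationReport", "data.frame")
    out
  })
}

#' Cross-tabulation of two module partitions with Fisher exact tests
#'
#' Counts shared genes between every module of partition A and every module
#' of partition B over their shared gene universe, and computes a two-sided
#' Fisher exact p-value per cell from the 2x2 membership table.
#'
#' @param part_a,part_b `ModulePartition`s over the shared gene universe.
#' @return An `OverlapTable` list: `counts` and `p` matrices (rows = modules
#'   of A, columns = modules of B), and `n_universe`.
#' @export
overlap_table <- function(part_a, part_b) {
  universe <- intersect(names(part_a$label_of), names(part_b$label_of))
  if (!length(universe)) stop("partitions share no genes")
  la <- part_a$label_of[universe]
  lb <- part_b$label_of[universe]
  counts <- as.matrix(table(la, lb))
  n <- length(universe)
  p <- counts
  for (i in rownames(counts)) for (j in colnames(counts)) {
    in_a <- sum(la == i); in_b <- sum(lb == j); both <- counts[i, j]
    tab <- matrix(c(both, in_a - both, in_b - both,
                    n - in_a - in_b + both), 2, 2)
    p[i, j] <- stats::fisher.test(tab)$p.value
  }
  structure(list(counts = counts, p = p, n_universe = n),
            class = "OverlapTable")
}

#' Correlation of kME values between reference and test networks
#'
#' For one reference module, correlates the reference kME column with the
#' matched test kME column over (i) all module-assigned (non-grey) genes and
#' (ii) in-module genes only.
#'
#' @param ref_kme,test_kme `ModuleEigengenes` objects (the test one computed
#'   with the reference module definitions imposed), or kME matrices with
#'   matching column names.
#' @param module Module label present in both kME tables.
#' @param ref_part Reference `ModulePartition`.
#' @return List with `all = c(r, p)` and `in_module = c(r, p)`; entries are
#'   `NA` when fewer than 3 genes are in scope.
#' @export
kme_correlations <- function(ref_kme, test_kme, module, ref_part) {
  km_r <- if (inherits(ref_kme, "ModuleEigengenes")) ref_kme$kme else ref_kme
  km_t <- if (inherits(test_kme, "ModuleEigengenes")) test_kme$kme
          else test_kme
  if (!module %in% colnames(km_r) || !module %in% colnames(km_t))
    stop("module ", module, " absent from a kME table")
  shared <- intersect(rownames(km_r), rownames(km_t))
  labels <- ref_part$label_of[names(ref_part$label_of) %in% shared]
  scopes <- list(all = names(labels)[labels != "grey"],
                 in_module = names(labels)[labels == module])
  lapply(scopes, function(scope) {
    scope <- scope[!is.na(km_r[scope, module]) & !is.na(km_t[scope, module])]
    if (length(scope) < 3) return(c(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(km_r[scope, module], km_t[scope, module])
    c(r = unname(ct$estimate), p = ct$p.value)
  })
}
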