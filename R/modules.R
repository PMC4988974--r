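#' Module color labels in the conventional size-ordered palette
#'
#' Returns the first `n` module colors in the conventional co-expression
#' ordering (turquoise, blue, brown, ...), falling back to `moduleN` beyond
#' the named palette. `"grey"` is reserved for unassigned genes.
#'
#' @param n Number of labels.
#' @return Character vector of length `n`.
#' @export
module_colors <- function(n) {
  pal <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
           "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
           "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
           "lightyellow", "royalblue", "darkred", "darkgreen",
           "darkturquoise", "darkgrey", "orange", "darkorange", "white",
           "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
           "darkolivegreen", "darkmagenta")
  if (n <= length(pal)) pal[seq_len(n)]
  else c(pal, paste0("module", seq.int(length(pal) + 1L, n)))
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Builds an average-linkage dendrogram on the TOM dissimilarity and cuts it
#' with a hybrid rule controlled by a `deepsplit` sensitivity level:
#' a static cut at the `0.99 - 0.02 * deepsplit` quantile of merge heights,
#' followed by a recursive split of any branch whose internal height gap --
#' the branch's merge height minus the smaller merge height of its non-leaf
#' children -- exceeds `0.25 - 0.05 * deepsplit`. Branches smaller than
#' `min_module_size` become unassigned (`"grey"`). Genes are sorted before
#' clustering so the partition does not depend on input order, and module
#' labels are colors assigned by decreasing size (ties broken by the
#' smallest member gene id).
#'
#' When the expression dataset is supplied, the tree-cut branches are
#' treated as module cores and refined by module membership (kME): for a few
#' iterations, module eigengenes are computed from the current members and
#' every gene is reassigned to the module whose eigengene it correlates with
#' most, provided that correlation reaches `kme_cut`; other genes go to
#' grey, and modules falling below `min_module_size` dissolve. This is the
#' standard two-stage practice for short sample panels, where
#' average-linkage trees chain through background genes that correlate with
#' a module by chance.
#'
#' Degenerate input with all pairwise dissimilarities equal yields either a
#' single module (distances within the gap tolerance) or all-grey genes.
#'
#' @param dist A `TOMMatrix` from [tom_similarity()], or a symmetric
#'   dissimilarity matrix.
#' @param deepsplit Split sensitivity, 0 (coarse) to 4 (fine); default 2.
#' @param min_module_size Minimum genes per module (>= 3); default 20.
#' @param expr Optional [expression_dataset()] over the same genes; enables
#'   the kME refinement stage.
#' @param kme_cut Minimum absolute eigengene correlation for a gene to stay
#'   in a module during refinement (default 0.8, calibrated for small
#'   sample panels where null correlations are wide).
#' @param refine_iter Refinement iterations (default 3).
#' @return A `ModulePartition`: list with `label_of` (named character vector
#'   gene -> color), `sizes` (named, decreasing, grey last), and `params`.
#' @export
detect_modules <- function(dist, deepsplit = 2, min_module_size = 20,
                           expr = NULL, kme_cut = 0.8, refine_iter = 3) {
  if (inherits(dist, "TOMMatrix")) dist <- dist$dist
  dist <- as.matrix(dist)
  if (min_module_size < 3) stop("min_module_size must be at least 3")
  if (!(deepsplit %in% 0:4)) stop("deepsplit must be an integer in 0..4")
  genes <- sort(rownames(dist))
  if (is.null(genes)) stop("dissimilarity matrix must have gene row names")
  dist <- dist[genes, genes]
  n <- length(genes)
  if (n < 2) {
    part <- stats::setNames(rep("grey", n), genes)
    return(new_partition(part, deepsplit, min_module_size, NA_real_))
  }
  hc <- stats::hclust(stats::as.dist(dist), method = "average")
  h_cut <- unname(stats::quantile(hc$height, 0.99 - 0.02 * deepsplit))
  gap_cut <- 0.25 - 0.05 * deepsplit

  heights <- hc$height
  merge <- hc$merge
  # leaves of every internal node
  leaves_of <- vector("list", nrow(merge))
  node_leaves <- function(id) {
    if (id < 0) -id else leaves_of[[id]]
  }
  for (i in seq_len(nrow(merge)))
    leaves_of[[i]] <- c(node_leaves(merge[i, 1]), node_leaves(merge[i, 2]))

  child_height <- function(id) if (id < 0) NA_real_ else heights[id]
  branches <- list()
  descend <- function(id) {
    if (id < 0) {
      branches[[length(branches) + 1L]] <<- -id
      return(invisible())
    }
    ch <- c(child_height(merge[id, 1]), child_height(merge[id, 2]))
    internal <- ch[!is.na(ch)]
    gap <- if (length(internal)) heights[id] - min(internal) else 0
    if (heights[id] > h_cut || gap > gap_cut) {
      descend(merge[id, 1])
      descend(merge[id, 2])
    } else {
      branches[[length(branches) + 1L]] <<- leaves_of[[id]]
    }
  }
  descend(nrow(merge))

  label_of <- stats::setNames(rep("grey", n), genes)
  keep <- branches[vapply(branches, length, integer(1)) >= min_module_size]
  for (i in seq_along(keep))
    label_of[keep[[i]]] <- paste0("core", i)
  if (!is.null(expr))
    label_of <- refine_membership(label_of, expr, kme_cut, min_module_size,
                                  refine_iter)
  label_of <- assign_colors(label_of)
  new_partition(label_of, deepsplit, min_module_size, h_cut)
}

# kME refinement: iteratively recompute eigengenes from current members and
# reassign every gene to its best-correlated module (or grey).
refine_membership <- function(label_of, expr, kme_cut, min_module_size,
                              refine_iter) {
  stopifnot(is_expression_dataset(expr))
  if (!all(names(label_of) %in% rownames(expr$values)))
    stop("expression dataset does not cover the clustered genes")
  v <- expr$values[names(label_of), , drop = FALSE]
  for (it in seq_len(refine_iter)) {
    mods <- setdiff(unique(label_of), "grey")
    if (!length(mods)) break
    eig <- sapply(mods, function(m) {
      z <- t(scale(t(v[names(label_of)[label_of == m], , drop = FALSE])))
      z[is.na(z)] <- 0
      if (nrow(z) == 1) return(as.numeric(z))
      e <- svd(z, nu = 0, nv = 1)$v[, 1]
      if (stats::sd(colMeans(z)) > 0 && stats::cor(e, colMeans(z)) < 0)
        e <- -e
      e
    })
    km <- suppressWarnings(stats::cor(t(v), eig))
    km[is.na(km)] <- 0
    best <- max.col(km, ties.method = "first")
    mx <- km[cbind(seq_len(nrow(km)), best)]
    new_labels <- ifelse(mx >= kme_cut, mods[best], "grey")
    names(new_labels) <- rownames(v)
    sz <- table(new_labels[new_labels != "grey"])
    small <- names(sz)[sz < min_module_size]
    new_labels[new_labels %in% small] <- "grey"
    if (identical(new_labels, label_of)) break
    label_of <- new_labels
  }
  label_of
}

# Replace provisional branch labels by palette colors in decreasing size
# order; ties broken by the smallest member gene id.
assign_colors <- function(label_of) {
  mods <- setdiff(unique(label_of), "grey")
  if (!length(mods)) return(label_of)
  sizes <- vapply(mods, function(m) sum(label_of == m), integer(1))
  firsts <- vapply(mods, function(m) min(names(label_of)[label_of == m]),
                   character(1))
  ord <- order(-sizes, firsts)
  cols <- module_colors(length(mods))
  out <- label_of
  for (i in seq_along(ord))
    out[label_of == mods[ord[i]]] <- cols[i]
  out
}

new_partition <- function(label_of, deepsplit, min_module_size, h_cut) {
  non_grey <- label_of[label_of != "grey"]
  sizes <- sort(table(non_grey), decreasing = TRUE)
  sizes <- c(sizes, grey = sum(label_of == "grey"))
  structure(list(label_of = label_of,
                 sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 params = list(deepsplit = deepsplit,
                               min_module_size = min_module_size,
                               cut_height = h_cut)),
            class = "ModulePartition")
}

#' @export
print.ModulePartition <- function(x, ...) {
  cat("ModulePartition:", length(x$label_of), "genes,",
      sum(names(x$sizes) != "grey"), "modules\n")
  print(x$sizes)
  invisible(x)
}

#' Member genes of a module
#' @param part A `ModulePartition`.
#' @param label Module color label.
#' @return Character vector of gene ids.
#' @export
module_genes <- function(part, label) {
  names(part$label_of)[part$label_of == label]
}

#' Module eigengenes and module membership (kME)
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardized expression (sample scores), oriented so that its
#' correlation with the module's mean expression profile is non-negative.
#' kME is the Pearson correlation of every gene's profile (member or not)
#' with each eigengene. Grey genes are excluded from eigengene computation
#' but do receive kME values.
#'
#' @param x [expression_dataset()] covering the partition's genes.
#' @param part A `ModulePartition`, or a named character vector gene->label.
#' @return A `ModuleEigengenes` list: `eigengenes` (samples x modules),
#'   `kme` (genes x modules), `modules` (labels).
#' @export
module_eigengenes <- function(x, part) {
  stopifnot(is_expression_dataset(x))
  labels <- if (inherits(part, "ModulePartition")) part$label_of else part
  labels <- labels[names(labels) %in% rownames(x$values)]
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(match(mods, module_colors(length(mods) + 10L)))]
  if (!length(mods)) stop("no non-grey modules in the partition")
  eig <- sapply(mods, function(m) {
    members <- names(labels)[labels == m]
    v <- x$values[members, , drop = FALSE]
    z <- t(scale(t(v)))
    z[is.na(z)] <- 0
    if (nrow(z) == 1) return(as.numeric(z))
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (stats::sd(colMeans(z)) > 0 &&
        stats::cor(e, colMeans(z)) < 0) e <- -e
    e
  })
  rownames(eig) <- colnames(x$values)
  kme <- suppressWarnings(stats::cor(t(x$values), eig))
  rownames(kme) <- rownames(x$values)
  structure(list(eigengenes = eig, kme = kme, modules = mods),
            class = "ModuleEigengenes")
}

#' Module-by-tissue mean expression and tissue assignment
#'
#' Standardizes each gene across samples, averages member genes per module
#' and tissue, and assigns each module the tissue where its mean
#' standardized expression is maximal. Exact ties are reported and warned
#' about.
#'
#' @param x [expression_dataset()] whose sample labels are tissues.
#' @param part A `ModulePartition`.
#' @return List: `means` (module x tissue matrix), `top_tissue` (named
#'   character vector), `ties` (list of tied tissues per module, when any).
#' @export
tissue_specificity <- function(x, part) {
  stopifnot(is_expression_dataset(x))
  labels <- part$label_of[names(part$label_of) %in% rownames(x$values)]
  mods <- setdiff(unique(labels), "grey")
  z <- t(scale(t(x$values)))
  z[is.na(z)] <- 0
  means <- t(sapply(mods, function(m) {
    colMeans(z[names(labels)[labels == m], , drop = FALSE])
  }))
  colnames(means) <- colnames(x$values)
  ties <- list()
  top <- apply(means, 1L, function(row) {
    mx <- max(row)
    hit <- colnames(means)[abs(row - mx) < 1e-10]
    hit[1]
  })
  for (m in rownames(means)) {
    row <- means[m, ]
    hit <- colnames(means)[abs(row - max(row)) < 1e-10]
    if (length(hit) > 1) ties[[m]] <- hit
  }
  if (length(ties))
    warning("tissue assignment ties in module(s): ",
            paste(names(ties), collapse = ", "))
  list(means = means, top_tissue = top, ties = ties)
}

#' Hypergeometric gene-set enrichment with Bonferroni correction
#'
#' One-sided (upper tail) hypergeometric test of the overlap between a
#' module and each supplied gene set, against a background universe; p-values
#' are Bonferroni-adjusted over the number of tested sets.
#'
#' @param module_genes Character vector of module gene ids (must be a subset
#'   of `background`).
#' @param gene_sets Named list of character vectors; each set is intersected
#'   with the background before testing.
#' @param background Character vector, the gene universe.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return `EnrichmentResult` data frame: `set`, `set_size`, `overlap`,
#'   `expected`, `p_value`, `p_adjusted`, `significant`.
#' @export
enrich_hypergeometric <- function(module_genes, gene_sets, background,
                                  alpha = 0.05) {
  background <- unique(background)
  if (!length(background)) stop("background gene universe is empty")
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% background))
    stop("module genes must be contained in the background")
  n_sets <- length(gene_sets)
  if (!n_sets) stop("no gene sets supplied")
  if (is.null(names(gene_sets)))
    names(gene_sets) <- paste0("set", seq_len(n_sets))
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), background)
    q <- length(intersect(module_genes, s))
    p <- stats::phyper(q - 1, length(s), length(background) - length(s),
                       length(module_genes), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = q,
               expected = length(module_genes) * length(s) /
                 length(background),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_value * n_sets)
  out$significant <- out$p_adjusted <= alpha
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}
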