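#' Build a bipartite gene-metabolite network around a module
#'
#' Seed edges are the correlation-table rows whose gene belongs to the
#' module and whose absolute Pearson correlation reaches `pcc_cut`. The
#' network is then expanded by one hop: every gene connected (at
#' `|pcc| >= pcc_cut` in `full_table`) to any seed metabolite -- a first
#' neighbor -- is added with its qualifying edges to those metabolites.
#'
#' @param module_genes Character vector of module gene ids.
#' @param table `MetaboliteCorrelationTable` (columns `gene_id`,
#'   `metabolite_id`, `pcc`) used for the seed edges.
#' @param pcc_cut Absolute-correlation threshold in (0, 1] (default 0.80).
#' @param full_table Correlation table used for the first-neighbor
#'   expansion; defaults to `table`.
#' @return A `GeneMetaboliteNetwork` list: `edges` (data frame `gene_id`,
#'   `metabolite_id`, `pcc`, `seed` flag), `genes`, `metabolites`, and
#'   `summary` (node/edge counts, density, number of module genes with at
#'   least one metabolite partner).
#' @export
build_metabolite_network <- function(module_genes, table, pcc_cut = 0.80,
                                     full_table = table) {
  if (!(pcc_cut > 0 && pcc_cut <= 1)) stop("pcc_cut must lie in (0, 1]")
  if (!nrow(table)) warning("empty gene-metabolite correlation table")
  seed <- table[table$gene_id %in% module_genes &
                  abs(table$pcc) >= pcc_cut, , drop = FALSE]
  seed_mets <- unique(seed$metabolite_id)
  expand <- full_table[full_table$metabolite_id %in% seed_mets &
                         abs(full_table$pcc) >= pcc_cut, , drop = FALSE]
  edges <- rbind(seed, expand)
  edges <- edges[!duplicated(edges[c("gene_id", "metabolite_id")]), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  edges$seed <- edges$gene_id %in% module_genes
  genes <- sort(unique(edges$gene_id))
  mets <- sort(unique(edges$metabolite_id))
  density <- if (length(genes) && length(mets))
    nrow(edges) / (length(genes) * length(mets)) else 0
  structure(list(
    edges = edges, genes = genes, metabolites = mets,
    summary = list(n_genes = length(genes), n_metabolites = length(mets),
                   n_nodes = length(genes) + length(mets),
                   n_edges = nrow(edges), density = density,
                   n_module_genes_linked =
                     length(intersect(genes, module_genes)),
                   pcc_cut = pcc_cut)),
    class = "GeneMetaboliteNetwork")
}

#' Compare the complexity of two gene-metabolite networks
#'
#' Reports node counts, edge counts and densities side by side and which
#' network is larger on each metric; no single complexity scalar is
#' constructed -- the per-metric comparison is the deliverable.
#'
#' @param net_a,net_b `GeneMetaboliteNetwork`s built at the same `pcc_cut`.
#' @return Data frame: `metric`, `a`, `b`, `larger` (`"a"`, `"b"` or
#'   `"tie"`).
#' @export
compare_complexity <- function(net_a, net_b) {
  if (!isTRUE(all.equal(net_a$summary$pcc_cut, net_b$summary$pcc_cut)))
    warning("networks were built at different pcc cut-offs")
  metrics <- c("n_genes", "n_metabolites", "n_nodes", "n_edges", "density")
  rows <- lapply(metrics, function(m) {
    a <- net_a$summary[[m]]; b <- net_b$summary[[m]]
    data.frame(metric = m, a = a, b = b,
               larger = if (a > b) "a" else if (b > a) "b" else "tie",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
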