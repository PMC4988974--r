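#' Intramodular connectivity of a module's genes
#'
#' Within one module, `k_i` is the sum of gene `i`'s adjacency weights to
#' the other member genes, and the normalized connectivity is
#' \eqn{K_i = k_i / k_{max}} where `k_max` is the module maximum -- so the
#' most connected gene has `K_i = 1` (ties give multiple 1s). A singleton
#' module gets `K_i = 1` by convention, with a warning.
#'
#' @param adj Adjacency matrix from [signed_adjacency()] covering the
#'   module's genes.
#' @param part A `ModulePartition`, or a named character vector
#'   gene -> label.
#' @param module Module label.
#' @return Data frame: `gene`, `k_i`, `K_i`, sorted by `K_i` decreasing.
#' @export
intramodular_connectivity <- function(adj, part, module) {
  labels <- if (inherits(part, "ModulePartition")) part$label_of else part
  members <- names(labels)[labels == module]
  members <- intersect(members, rownames(adj))
  if (!length(members)) stop("module ", module, " is empty")
  if (length(members) == 1) {
    warning("singleton module ", module, "; K_i = 1 by convention")
    out <- data.frame(gene = members, k_i = 0, K_i = 1,
                      stringsAsFactors = FALSE)
    return(out)
  }
  sub <- adj[members, members]
  diag(sub) <- 0
  k <- rowSums(sub)
  kmax <- max(k)
  K <- if (kmax > 0) k / kmax else rep(1, length(k))
  out <- data.frame(gene = members, k_i = unname(k), K_i = unname(K),
                    stringsAsFactors = FALSE)
  out[order(-out$K_i, out$gene), , drop = FALSE]
}

#' Paired hub table for a matched module pair across species
#'
#' Restricts to orthologs present in `module_a` of species A and `module_b`
#' of species B, computes each gene's normalized intramodular connectivity
#' `K_i` in both species, and keeps genes whose `K_i` exceeds `k_cut` in at
#' least one species. Rows are sorted by `K_i` in species A, decreasing.
#'
#' @param module_a,module_b Matched module labels (e.g. the most significant
#'   partner pair from [overlap_table()]).
#' @param parts List with `a` and `b`: the two `ModulePartition`s.
#' @param adjs List with `a` and `b`: the two adjacency matrices.
#' @param k_cut Hub threshold on `K_i` (strict `>`; default 0.6).
#' @param transcripts Optional list with `a` and `b`: named vectors
#'   ortholog -> transcript id (as returned by [harmonize_orthologs()]),
#'   echoed into the table.
#' @return A `HubTable` data frame: `ortholog_id`, `transcript_a`, `K_i_a`,
#'   `transcript_b`, `K_i_b`, `delta` (= `K_i_a - K_i_b`), `divergent`
#'   (all `FALSE` until [flag_divergent()] is applied).
#' @export
shared_hub_table <- function(module_a, module_b, parts, adjs, k_cut = 0.6,
                             transcripts = NULL) {
  ka <- intramodular_connectivity(adjs$a, parts$a, module_a)
  kb <- intramodular_connectivity(adjs$b, parts$b, module_b)
  shared <- intersect(ka$gene, kb$gene)
  if (!length(shared)) {
    warning("module pair shares no genes")
    return(empty_hub_table())
  }
  Ka <- ka$K_i[match(shared, ka$gene)]
  Kb <- kb$K_i[match(shared, kb$gene)]
  keep <- (Ka > k_cut) | (Kb > k_cut)
  shared <- shared[keep]; Ka <- Ka[keep]; Kb <- Kb[keep]
  if (!length(shared)) {
    warning("no shared gene exceeds the hub threshold")
    return(empty_hub_table())
  }
  tr_a <- if (!is.null(transcripts)) unname(transcripts$a[shared])
          else NA_character_
  tr_b <- if (!is.null(transcripts)) unname(transcripts$b[shared])
          else NA_character_
  out <- data.frame(ortholog_id = shared, transcript_a = tr_a, K_i_a = Ka,
                    transcript_b = tr_b, K_i_b = Kb, delta = Ka - Kb,
                    divergent = FALSE, stringsAsFactors = FALSE)
  out <- out[order(-out$K_i_a, out$ortholog_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("HubTable", "data.frame")
  out
}

empty_hub_table <- function() {
  out <- data.frame(ortholog_id = character(0),
                    transcript_a = character(0), K_i_a = numeric(0),
                    transcript_b = character(0), K_i_b = numeric(0),
                    delta = numeric(0), divergent = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("HubTable", "data.frame")
  out
}

#' Flag divergent hub genes by connectivity difference
#'
#' Marks genes whose absolute normalized-connectivity difference between
#' species reaches `delta_cut` as divergent, and returns the table sorted by
#' `|delta|` decreasing. Raising `delta_cut` never adds flagged genes.
#'
#' @param table A `HubTable` from [shared_hub_table()] (or any data frame
#'   with a `delta` column).
#' @param delta_cut Threshold on `|delta|` (default 0.2).
#' @return The table sorted by `|delta|` decreasing with the `divergent`
#'   flag set; the flagged subset is attached as attribute `"flagged"`.
#' @export
flag_divergent <- function(table, delta_cut = 0.2) {
  if (!nrow(table)) {
    attr(table, "flagged") <- table
    return(table)
  }
  table$divergent <- abs(table$delta) >= delta_cut
  out <- table[order(-abs(table$delta), table$ortholog_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flagged") <- out[out$divergent, , drop = FALSE]
  out
}
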