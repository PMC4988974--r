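#' Read an expression TSV into an ExpressionDataset
#'
#' Expects a header row of sample names and gene ids in the first column;
#' missing values are the token `NA`. Duplicate gene ids and non-numeric
#' cells are rejected with the offending id or line number.
#'
#' @param path File path.
#' @param species Species tag attached to the dataset.
#' @return An [expression_dataset()].
#' @export
load_expression <- function(path, species = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("expected a gene id column plus sample columns")
  ids <- tab[[1]]
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop(sprintf("duplicate gene id '%s' (line %d)", dup,
                 which(ids == dup)[2] + 1L))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- matrix(suppressWarnings(as.numeric(vals)), nrow(vals), ncol(vals))
  is_na_token <- matrix(is.na(vals) | vals %in% c("NA", ""),
                        nrow(vals), ncol(vals))
  bad <- which(is.na(num) & !is_na_token, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric value '%s' at line %d, column '%s'",
                 vals[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L,
                 colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(ids, colnames(vals))
  expression_dataset(num, species = species)
}

#' Write an ExpressionDataset as TSV
#'
#' Inverse of [load_expression()]; numeric formatting is fixed (15
#' significant digits) so rewrites are byte-stable.
#'
#' @param x An [expression_dataset()].
#' @param path Output file path.
#' @export
write_expression <- function(x, path) {
  stopifnot(is_expression_dataset(x))
  tab <- data.frame(gene_id = rownames(x$values),
                    signif(x$values, 15), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a transcript-to-ortholog map TSV
#'
#' Columns: `transcript_id`, `ortholog_id`, `evalue`.
#'
#' @param path File path.
#' @return Data frame with those three columns.
#' @export
load_ortholog_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("transcript_id", "ortholog_id", "evalue")
  if (!all(need %in% colnames(tab)))
    stop("ortholog map needs columns: ", paste(need, collapse = ", "))
  tab[need]
}

#' Read a gene-metabolite correlation table TSV
#'
#' Columns: `gene_id`, `metabolite_id`, `pcc`. Duplicate (gene, metabolite)
#' pairs and correlations outside \[-1, 1\] are rejected.
#'
#' @param path File path.
#' @return A `MetaboliteCorrelationTable` data frame.
#' @export
load_metabolite_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "metabolite_id", "pcc")
  if (!all(need %in% colnames(tab)))
    stop("metabolite table needs columns: ", paste(need, collapse = ", "))
  tab <- tab[need]
  if (any(abs(tab$pcc) > 1)) stop("pcc values must lie in [-1, 1]")
  if (anyDuplicated(tab[c("gene_id", "metabolite_id")]))
    stop("duplicate (gene, metabolite) pairs in table")
  class(tab) <- c("MetaboliteCorrelationTable", "data.frame")
  tab
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Default pipeline configuration
#'
#' Collects every stage parameter of the comparative pipeline with its
#' default: DEG screening (`variance_percentile` 30, `alpha` 0.05), signed
#' network construction (`beta` 14, or `pick_beta` over `beta_candidates`),
#' module detection (`deepsplit` per species, `min_module_size` 20),
#' preservation (`n_perm` 100, `gold_size` 50), robustness
#' (`tau_percentile` 0.95, `random_reps` 25), hub comparison (`k_cut` 0.6,
#' `delta_cut` 0.2) and metabolite integration (`pcc_cut` 0.80).
#'
#' @param ... Overrides for any default, by name; unknown names are
#'   rejected.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    evalue_cutoff = 1e-5,
    max_missing_frac = 0.5, min_sd = 1e-8, outlier_z = 2.5,
    variance_percentile = 30, alpha = 0.05,
    beta = 14, pick_beta = FALSE, beta_candidates = 1:20, r2_target = 0.8,
    deepsplit_a = 2, deepsplit_b = 2, min_module_size = 20, kme_cut = 0.8,
    n_perm = 100, gold_size = 50,
    tau = NULL, tau_percentile = 0.95, random_reps = 25,
    k_cut = 0.6, delta_cut = 0.2, pcc_cut = 0.80,
    seed = 1)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the comparative co-expression pipeline end to end
#'
#' Executes preprocess (ortholog harmonization, QC, comparability, PCA),
#' DEG screening, per-species signed network and TOM construction, module
#' detection, preservation (Z-summary, overlap table), robustness
#' evaluation, hub divergence for the best-matched module pair, and --
#' when a metabolite table is supplied -- gene-metabolite network
#' comparison. All randomized stages draw from `config$seed`, so a rerun
#' with the same inputs and config reproduces every number. When `out_dir`
#' is given, the main artifacts are written as TSV/JSON together with a
#' manifest echoing every parameter.
#'
#' @param expr_a,expr_b [expression_dataset()]s indexed by transcript id.
#' @param map_a,map_b Ortholog maps (see [load_ortholog_map()]).
#' @param config A [pipeline_config()].
#' @param metabolite_table Optional `MetaboliteCorrelationTable`; when
#'   `NULL` the metabolite stage is skipped with a notice.
#' @param out_dir Optional output directory for artifacts.
#' @return A list with the results of every stage: `harmonized`, `qc`,
#'   `comparability`, `pca`, `degs`, `networks`, `partitions`,
#'   `preservation`, `overlap`, `robustness`, `hub_pair`, `hubs`,
#'   `metabolites` (or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(expr_a, expr_b, map_a, map_b,
                         config = pipeline_config(),
                         metabolite_table = NULL, out_dir = NULL) {
  stages <- character(0)
  note <- function(s) {
    stages <<- c(stages, s)
    message("[conetdiff] stage: ", s)
  }

  note("preprocess")
  qa <- qc_filter(expr_a, config$max_missing_frac, config$min_sd,
                  config$outlier_z)
  qb <- qc_filter(expr_b, config$max_missing_frac, config$min_sd,
                  config$outlier_z)
  harm <- harmonize_orthologs(qa$x, qb$x, map_a, map_b,
                              evalue_cutoff = config$evalue_cutoff)
  comp <- comparability_check(harm$a, harm$b)
  pca <- pca_overview(harm$a, harm$b)

  note("deg")
  degs <- identify_degs(harm$a, harm$b,
                        variance_percentile = config$variance_percentile,
                        alpha = config$alpha)
  sig <- degs$ortholog_id[degs$significant]
  if (length(sig) < config$min_module_size)
    stop("stage deg: fewer significant genes (", length(sig),
         ") than min_module_size")
  xa <- expression_dataset(harm$a$values[sig, , drop = FALSE],
                           species = harm$a$species)
  xb <- expression_dataset(harm$b$values[sig, , drop = FALSE],
                           species = harm$b$species)

  note("network")
  build_net <- function(x) {
    cc <- suppressWarnings(stats::cor(t(x$values)))
    cc[is.na(cc)] <- 0
    beta <- if (isTRUE(config$pick_beta))
      pick_soft_threshold(cc, config$beta_candidates, config$r2_target)$beta
    else config$beta
    adj <- signed_adjacency(cc, beta)
    list(cor = cc, adj = adj, tom = tom_similarity(adj), beta = beta)
  }
  net_a <- build_net(xa)
  net_b <- build_net(xb)

  note("modules")
  part_a <- detect_modules(net_a$tom, config$deepsplit_a,
                           config$min_module_size, expr = xa,
                           kme_cut = config$kme_cut)
  part_b <- detect_modules(net_b$tom, config$deepsplit_b,
                           config$min_module_size, expr = xb,
                           kme_cut = config$kme_cut)

  note("preserve")
  pres <- z_summary(xa, xb, part_a, n_perm = config$n_perm,
                    gold_size = config$gold_size,
                    beta = net_b$beta, seed = config$seed)
  ovl <- overlap_table(part_a, part_b)

  note("robustness")
  rob_a <- evaluate_robustness(net_a$adj, tau = config$tau,
                               tau_percentile = config$tau_percentile,
                               reps = config$random_reps, seed = config$seed)
  rob_b <- evaluate_robustness(net_b$adj, tau = config$tau,
                               tau_percentile = config$tau_percentile,
                               reps = config$random_reps, seed = config$seed)

  note("hubs")
  hub_pair <- best_module_pair(ovl)
  hubs <- NULL
  if (!is.null(hub_pair)) {
    hubs <- shared_hub_table(hub_pair[1], hub_pair[2],
                             parts = list(a = part_a, b = part_b),
                             adjs = list(a = net_a$adj, b = net_b$adj),
                             k_cut = config$k_cut,
                             transcripts = harm$transcript_of)
    hubs <- flag_divergent(hubs, config$delta_cut)
  }

  mets <- NULL
  if (!is.null(metabolite_table) && !is.null(hub_pair)) {
    note("metabolites")
    na <- build_metabolite_network(module_genes(part_a, hub_pair[1]),
                                   metabolite_table, config$pcc_cut)
    nb <- build_metabolite_network(module_genes(part_b, hub_pair[2]),
                                   metabolite_table, config$pcc_cut)
    mets <- list(net_a = na, net_b = nb,
                 comparison = compare_complexity(na, nb))
  } else {
    message("[conetdiff] metabolite stage skipped (no table supplied)")
  }

  manifest <- list(parameters = unclass(config), stages = stages,
                   n_input_genes = c(a = nrow(expr_a$values),
                                     b = nrow(expr_b$values)),
                   n_shared_orthologs = nrow(harm$a$values),
                   n_tested = nrow(degs), n_significant = length(sig))
  res <- list(harmonized = harm, qc = list(a = qa$report, b = qb$report),
              comparability = comp, pca = pca, degs = degs,
              networks = list(a = net_a, b = net_b),
              partitions = list(a = part_a, b = part_b),
              preservation = pres, overlap = ovl,
              robustness = list(a = rob_a, b = rob_b),
              hub_pair = hub_pair, hubs = hubs, metabolites = mets,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

# Most significant (module_a, module_b) pair among non-grey cells of an
# overlap table; p ties broken by the larger shared-gene count, then by
# label. NULL when no cell is informative.
best_module_pair <- function(ovl) {
  p <- ovl$p
  keep_r <- setdiff(rownames(p), "grey")
  keep_c <- setdiff(colnames(p), "grey")
  if (!length(keep_r) || !length(keep_c)) return(NULL)
  p <- p[keep_r, keep_c, drop = FALSE]
  counts <- ovl$counts[keep_r, keep_c, drop = FALSE]
  # only enriched cells qualify: a two-sided Fisher p can also be small for
  # strong depletion, which is not a module match
  expected <- outer(rowSums(ovl$counts)[keep_r],
                    colSums(ovl$counts)[keep_c]) / ovl$n_universe
  p[counts <= expected] <- 1
  if (all(p >= 1)) return(NULL)
  idx <- which(p == min(p), arr.ind = TRUE)
  idx <- idx[order(-counts[idx], rownames(p)[idx[, 1]],
                   colnames(p)[idx[, 2]]), , drop = FALSE]
  c(rownames(p)[idx[1, 1]], colnames(p)[idx[1, 2]])
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(res$degs, "deg_table.tsv")
  w(data.frame(gene = names(res$partitions$a$label_of),
               module_a = res$partitions$a$label_of,
               module_b = res$partitions$b$label_of[
                 names(res$partitions$a$label_of)]),
    "module_assignments.tsv")
  w(res$preservation, "preservation_report.tsv")
  if (!is.null(res$hubs)) w(res$hubs, "hub_table.tsv")
  rob <- rbind(cbind(network = "a", res$robustness$a$report$table),
               cbind(network = "b", res$robustness$b$report$table))
  w(rob, "robustness_indices.tsv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
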