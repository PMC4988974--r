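#' Specify a planted co-expression module for the synthetic generator
#'
#' A planted module is generated from a latent eigengene: per species, a
#' per-sample tissue mean-shift pattern plus a standard-normal latent factor.
#' Member genes load on that factor with gene-specific loadings, so the
#' module is recoverable both by clustering and by kME statistics.
#'
#' @param size Number of member orthologs.
#' @param tissue_pattern_a,tissue_pattern_b Per-sample mean shifts (length
#'   equal to the species' sample count, or a single number recycled).
#'   Defaults to no shift.
#' @param preserved If `TRUE` the module exists in both species (same genes,
#'   same loadings up to planted hub differences). If `FALSE` the member
#'   genes are coherent in species A only and independent noise in species B.
#' @param loading Either `NULL` (loadings drawn uniformly from \[0.5, 1\]),
#'   a single value used for every gene, or a length-2 range to draw from.
#'
#' @return A list describing the module, for `module_specs` in
#'   [synthetic_config()].
#' @export
synthetic_module <- function(size, tissue_pattern_a = 0, tissue_pattern_b = 0,
                             preserved = TRUE, loading = NULL) {
  stopifnot(size >= 1)
  list(size = as.integer(size), tissue_pattern_a = tissue_pattern_a,
       tissue_pattern_b = tissue_pattern_b, preserved = isTRUE(preserved),
       loading = loading)
}

#' Configuration for the paired-species synthetic data generator
#'
#' Defines the study conditions emulated by [generate_paired_datasets()]:
#' two log-expression matrices over a shared ortholog space (8 and 6 tissue
#' samples by default, as in multi-tissue medicinal-plant RNA-seq panels),
#' block-correlated planted modules, optional divergent hub genes with a
#' target normalized-connectivity gap, background noise genes, duplicated
#' transcripts per ortholog, and gene-metabolite correlation links.
#'
#' @param module_specs List of module descriptions from [synthetic_module()].
#' @param n_background Number of background (independent-noise) orthologs.
#' @param n_samples_a,n_samples_b Sample counts for species A and B.
#' @param n_divergent_hubs Number of genes in the first preserved module
#'   given a planted connectivity difference between species.
#' @param hub_delta Target normalized intramodular connectivity gap, in
#'   (0, 1]. Planted hubs load maximally in species B and attenuated by
#'   `hub_delta` in species A.
#' @param noise_sd Gaussian expression noise SD on the log scale.
#' @param duplicate_rate Fraction of orthologs represented by two transcripts
#'   (the second with inflated noise, so duplicate collapse by maximal
#'   sample SD is exercised).
#' @param metabolite_links List of `list(gene =, metabolite =, r =)` links;
#'   `gene` is an ortholog id (see [generate_paired_datasets()] for the id
#'   scheme), `r` the target Pearson correlation.
#' @param seed Integer seed; the generator is deterministic given the config.
#'
#' @return A `SyntheticConfig` list, validated.
#' @export
synthetic_config <- function(module_specs = list(), n_background = 0,
                             n_samples_a = 8, n_samples_b = 6,
                             n_divergent_hubs = 0, hub_delta = 0.3,
                             noise_sd = 0.25, duplicate_rate = 0,
                             metabolite_links = list(), seed = 1) {
  cfg <- list(module_specs = module_specs,
              n_background = as.integer(n_background),
              n_samples_a = as.integer(n_samples_a),
              n_samples_b = as.integer(n_samples_b),
              n_divergent_hubs = as.integer(n_divergent_hubs),
              hub_delta = hub_delta, noise_sd = noise_sd,
              duplicate_rate = duplicate_rate,
              metabolite_links = metabolite_links, seed = as.integer(seed))
  sizes <- vapply(module_specs, function(m) m$size, integer(1))
  cfg$n_orthologs <- as.integer(sum(sizes) + cfg$n_background)
  if (cfg$n_samples_a < 2 || cfg$n_samples_b < 2)
    stop("each species needs at least 2 samples")
  if (cfg$n_background < 0) stop("n_background must be non-negative")
  if (cfg$n_orthologs < 1) stop("config generates no genes")
  if (!(cfg$hub_delta > 0 && cfg$hub_delta <= 1))
    stop("hub_delta must lie in (0, 1]")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$duplicate_rate < 0 || cfg$duplicate_rate > 1)
    stop("duplicate_rate must lie in [0, 1]")
  if (cfg$n_divergent_hubs > 0) {
    preserved <- which(vapply(module_specs, function(m) m$preserved,
                              logical(1)))
    if (!length(preserved))
      stop("divergent hubs require at least one preserved module")
    if (cfg$n_divergent_hubs > module_specs[[preserved[1]]]$size)
      stop("more divergent hubs than genes in the first preserved module")
  }
  for (ml in metabolite_links) {
    if (!all(c("gene", "metabolite", "r") %in% names(ml)))
      stop("each metabolite link needs gene, metabolite and r")
    if (abs(ml$r) > 1) stop("metabolite link correlation must be in [-1, 1]")
  }
  class(cfg) <- "SyntheticConfig"
  cfg
}

expand_pattern <- function(p, n) {
  if (length(p) == 1L) rep(p, n)
  else if (length(p) == n) p
  else stop("tissue pattern length must be 1 or the species sample count")
}

draw_loadings <- function(spec, n) {
  l <- spec$loading
  if (is.null(l)) stats::runif(n, 0.5, 1)
  else if (length(l) == 1L) rep(l, n)
  else if (length(l) == 2L) stats::runif(n, l[1], l[2])
  else stop("loading must be NULL, a scalar or a range")
}

#' Generate a paired two-species synthetic expression study
#'
#' Simulates log-scale expression for two related species over a shared
#' ortholog space, with planted module structure. Each module gene is
#' `baseline + loading * eigengene + noise`, where the eigengene is the
#' species' tissue mean-shift pattern plus a standard-normal latent factor.
#' Background genes are independent noise around a shared baseline. Planted
#' divergent hubs (in the first preserved module) load at 1 in species B and
#' at `1 - hub_delta` in species A, producing an expected normalized
#' intramodular connectivity gap of at least `hub_delta / 2`. A fraction of
#' orthologs gets a second transcript with doubled noise SD, exercising the
#' duplicate-collapse rule.
#'
#' Ortholog ids follow `og00001, ...`; transcript ids are
#' `<species>_<ortholog>_t1` (and `_t2` for duplicates).
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `expr_a`, `expr_b`
#'   ([expression_dataset()]s indexed by transcript id), `map_a`, `map_b`
#'   (ortholog-map data frames: `transcript_id`, `ortholog_id`, `evalue`),
#'   and `truth` (a `GroundTruth` list: `true_module_of` per species with 0
#'   meaning background, `planted_hubs`, `preserved_modules`,
#'   `metabolite_links`, plus the ortholog-level profiles used to derive
#'   metabolite data).
#' @export
#' @examples
#' cfg <- synthetic_config(list(synthetic_module(30)), n_background = 50,
#'                         seed = 42)
#' sim <- generate_paired_datasets(cfg)
#' dim(sim$expr_a)
generate_paired_datasets <- function(config) {
  if (!inherits(config, "SyntheticConfig"))
    config <- do.call(synthetic_config, config)
  with_seed(config$seed, {
    sizes <- vapply(config$module_specs, function(m) m$size, integer(1))
    n_mod_genes <- sum(sizes)
    n_total <- config$n_orthologs
    orth <- sprintf("og%05d", seq_len(n_total))
    module_of <- rep(0L, n_total)
    if (length(sizes))
      module_of[seq_len(n_mod_genes)] <-
        rep(seq_along(sizes), times = sizes)
    names(module_of) <- orth

    baseline <- stats::rnorm(n_total, mean = 5, sd = 1.5)
    loadings <- stats::runif(n_total, 0.5, 1)  # overwritten per module below
    for (m in seq_along(sizes)) {
      idx <- which(module_of == m)
      loadings[idx] <- draw_loadings(config$module_specs[[m]], length(idx))
    }
    loadings_a <- loadings
    loadings_b <- loadings

    # Planted divergent hubs: first genes of the first preserved module.
    # In species B the hub is a pure high-loading module gene; in species A
    # its profile mixes the module factor with a gene-specific orthogonal
    # direction (mixing weight 1 - hub_delta on the factor), a
    # correlation-scale decoupling that survives the soft-threshold power
    # and yields a stable normalized-connectivity gap -- a pure loading
    # change would not, since correlations are scale-invariant.
    planted_hubs <- data.frame(ortholog = character(0),
                               module = integer(0),
                               delta_sign = numeric(0),
                               magnitude = numeric(0))
    hub_idx <- integer(0)
    if (config$n_divergent_hubs > 0) {
      pres <- which(vapply(config$module_specs, function(m) m$preserved,
                           logical(1)))[1]
      hub_idx <- which(module_of == pres)[seq_len(config$n_divergent_hubs)]
      loadings_b[hub_idx] <- 1
      loadings_a[hub_idx] <- 1
      planted_hubs <- data.frame(ortholog = orth[hub_idx],
                                 module = pres,
                                 delta_sign = -1,  # K_i higher in species B
                                 magnitude = config$hub_delta)
    }

    gen_species <- function(n_samples, which_species) {
      x <- baseline +
        matrix(stats::rnorm(n_total * n_samples, sd = config$noise_sd),
               n_total, n_samples)
      # Latent factors, one per module, orthogonalized across modules (and
      # against the intercept) so planted modules are identifiable
      # expression programs rather than chance-correlated draws -- with few
      # samples, raw independent draws can be strongly sample-correlated,
      # leaving the ground-truth partition ill-defined.
      n_mods <- length(sizes)
      factors <- NULL
      if (n_mods > 0) {
        raw <- matrix(stats::rnorm(n_samples * n_mods), n_samples, n_mods)
        if (n_mods + 1 <= n_samples) {
          q <- qr.Q(qr(cbind(1, raw)))[, -1, drop = FALSE]
          # re-sign towards the raw draw, rescale to unit sample SD
          factors <- sapply(seq_len(n_mods), function(m) {
            f <- q[, m]
            if (sum(f * raw[, m]) < 0) f <- -f
            f / stats::sd(f)
          })
        } else {
          factors <- scale(raw)  # more modules than samples: centered only
        }
      }
      for (m in seq_along(sizes)) {
        spec <- config$module_specs[[m]]
        if (which_species == "b" && !spec$preserved) next
        pat <- expand_pattern(
          if (which_species == "a") spec$tissue_pattern_a
          else spec$tissue_pattern_b, n_samples)
        idx <- which(module_of == m)
        l <- if (which_species == "a") loadings_a[idx] else loadings_b[idx]
        # tissue pattern enters as an unscaled per-sample mean shift; only
        # the latent factor is modulated by the gene loading
        x[idx, ] <- x[idx, ] + rep(1, length(idx)) %o% pat +
          l %o% factors[, m]
        if (which_species == "a") {
          hubs_here <- intersect(idx, hub_idx)
          for (g in hubs_here) {
            # replace the factor contribution by the attenuated mixture
            d <- stats::rnorm(n_samples)
            d <- stats::lm.fit(cbind(1, factors), d)$residuals
            d <- d / stats::sd(d)
            alpha <- 1 - config$hub_delta
            x[g, ] <- x[g, ] - loadings_a[g] * factors[, m] +
              loadings_a[g] * (alpha * factors[, m] +
                                 sqrt(1 - alpha^2) * d)
          }
        }
      }
      rownames(x) <- orth
      x
    }
    xa <- gen_species(config$n_samples_a, "a")
    xb <- gen_species(config$n_samples_b, "b")
    colnames(xa) <- paste0("tissueA", seq_len(config$n_samples_a))
    colnames(xb) <- paste0("tissueB", seq_len(config$n_samples_b))

    make_transcripts <- function(x, prefix, dup) {
      ids <- paste0(prefix, "_", rownames(x), "_t1")
      vals <- x
      if (length(dup)) {
        extra <- x[dup, , drop = FALSE] +
          matrix(stats::rnorm(length(dup) * ncol(x),
                              sd = 2 * config$noise_sd),
                 length(dup), ncol(x))
        vals <- rbind(vals, extra)
        ids <- c(ids, paste0(prefix, "_", rownames(x)[dup], "_t2"))
      }
      rownames(vals) <- ids
      map <- data.frame(
        transcript_id = ids,
        ortholog_id = c(rownames(x), rownames(x)[dup]),
        evalue = 10^-stats::runif(length(ids), 6, 30),
        stringsAsFactors = FALSE)
      list(values = vals, map = map)
    }
    n_dup <- as.integer(floor(config$duplicate_rate * n_total))
    dup_idx <- if (n_dup > 0) sort(sample.int(n_total, n_dup)) else integer(0)
    ta <- make_transcripts(xa, "spA", dup_idx)
    tb <- make_transcripts(xb, "spB", dup_idx)

    true_module_b <- module_of
    for (m in seq_along(sizes))
      if (!config$module_specs[[m]]$preserved)
        true_module_b[module_of == m] <- 0L

    for (ml in config$metabolite_links)
      if (!ml$gene %in% orth)
        stop("metabolite link refers to unknown gene: ", ml$gene)

    truth <- structure(list(
      true_module_of = list(a = module_of, b = true_module_b),
      planted_hubs = planted_hubs,
      preserved_modules = which(vapply(config$module_specs,
                                       function(m) m$preserved, logical(1))),
      metabolite_links = config$metabolite_links,
      profiles_a = xa, profiles_b = xb), class = "GroundTruth")

    list(expr_a = expression_dataset(ta$values, species = "speciesA"),
         expr_b = expression_dataset(tb$values, species = "speciesB"),
         map_a = ta$map, map_b = tb$map, truth = truth)
  })
}

#' Generate a gene-metabolite correlation table from planted links
#'
#' For every configured link, a metabolite profile is built over species A's
#' samples as `r * z(gene) + sqrt(1 - r^2) * noise` where `z(gene)` is the
#' standardized ortholog-level expression profile, so the population Pearson
#' correlation equals the target `r` (exactly 1 when `r = 1`). The realized
#' sample correlation is recomputed from the generated profile and reported.
#'
#' @param truth `GroundTruth` from [generate_paired_datasets()].
#' @param config The same [synthetic_config()].
#' @return A `MetaboliteCorrelationTable` data frame with columns `gene_id`,
#'   `metabolite_id`, `pcc` (realized correlation); metabolite profiles are
#'   attached as attribute `"profiles"`.
#' @export
generate_metabolome <- function(truth, config) {
  if (!inherits(truth, "GroundTruth"))
    stop("truth must come from generate_paired_datasets()")
  links <- config$metabolite_links
  empty <- data.frame(gene_id = character(0), metabolite_id = character(0),
                      pcc = numeric(0))
  if (!length(links)) {
    class(empty) <- c("MetaboliteCorrelationTable", "data.frame")
    return(empty)
  }
  with_seed(config$seed + 1L, {
    n <- ncol(truth$profiles_a)
    rows <- lapply(links, function(ml) {
      if (!ml$gene %in% rownames(truth$profiles_a))
        stop("metabolite link refers to unknown gene: ", ml$gene)
      z <- as.numeric(scale(truth$profiles_a[ml$gene, ]))
      prof <- ml$r * z + sqrt(max(0, 1 - ml$r^2)) * stats::rnorm(n)
      list(row = data.frame(gene_id = ml$gene,
                            metabolite_id = ml$metabolite,
                            pcc = stats::cor(truth$profiles_a[ml$gene, ],
                                             prof)),
           prof = prof)
    })
    tab <- do.call(rbind, lapply(rows, `[[`, "row"))
    profs <- do.call(rbind, lapply(rows, `[[`, "prof"))
    rownames(profs) <- tab$metabolite_id
    colnames(profs) <- colnames(truth$profiles_a)
    attr(tab, "profiles") <- profs
    class(tab) <- c("MetaboliteCorrelationTable", "data.frame")
    tab
  })
}
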