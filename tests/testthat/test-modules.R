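test_that("three perfect blocks are cut into exactly three modules", {
  n <- 9
  d <- matrix(1, n, n)
  for (b in 0:2) d[b * 3 + 1:3, b * 3 + 1:3] <- 0
  dimnames(d) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
  part <- detect_modules(d, deepsplit = 0, min_module_size = 3)
  expect_equal(sum(part$label_of == "grey"), 0)
  expect_equal(sort(unname(part$sizes[names(part$sizes) != "grey"])),
               c(3, 3, 3))
  expect_setequal(unique(part$label_of), c("turquoise", "blue", "brown"))
  # block co-membership must match the planted blocks
  blocks <- rep(1:3, each = 3)
  expect_equal(length(unique(tapply(part$label_of, blocks, function(l)
    length(unique(l))))), 1)
})

test_that("degenerate all-equal dissimilarity does not crash", {
  d <- matrix(0.5, 6, 6); diag(d) <- 0
  dimnames(d) <- list(letters[1:6], letters[1:6])
  part <- detect_modules(d, deepsplit = 0, min_module_size = 3)
  labs <- unique(part$label_of)
  expect_true(identical(labs, "grey") || identical(labs, "turquoise"))
  expect_error(detect_modules(d, min_module_size = 2), "at least 3")
})

test_that("partition is invariant to gene input order", {
  cfg <- synthetic_config(list(synthetic_module(25), synthetic_module(20)),
                          n_background = 40, seed = 17)
  sim <- generate_paired_datasets(cfg)
  v <- sim$truth$profiles_a
  cc <- stats::cor(t(v))
  tom <- tom_similarity(signed_adjacency(cc, 6))
  p1 <- detect_modules(tom, 2, 10)
  set.seed(99)
  perm <- sample(nrow(v))
  cc2 <- cc[perm, perm]
  tom2 <- tom_similarity(signed_adjacency(cc2, 6))
  p2 <- detect_modules(tom2, 2, 10)
  expect_identical(p1$label_of, p2$label_of[names(p1$label_of)])
})

test_that("planted modules are recovered from generated data", {
  skip_if_not_installed("mclust")
  cfg <- synthetic_config(list(synthetic_module(60), synthetic_module(50),
                               synthetic_module(40), synthetic_module(30)),
                          n_background = 300, seed = 1)
  sim <- generate_paired_datasets(cfg)
  h <- harmonize_orthologs(sim$expr_a, sim$expr_b, sim$map_a, sim$map_b)
  cc <- stats::cor(t(h$a$values))
  tom <- tom_similarity(signed_adjacency(cc, 14))
  part <- detect_modules(tom, deepsplit = 2, min_module_size = 20,
                         expr = h$a)
  truth <- sim$truth$true_module_of$a[names(part$label_of)]
  ari <- mclust::adjustedRandIndex(part$label_of, truth)
  expect_gte(ari, 0.8)
  # color labels follow decreasing module size, largest = turquoise
  sz <- part$sizes[names(part$sizes) != "grey"]
  expect_equal(names(sz)[1], "turquoise")
  expect_true(all(diff(unname(sz)) <= 0))
})

test_that("eigengenes and kME behave as correlations with the module factor", {
  # identical genes: eigengene is the shared standardized profile, kME = 1
  prof <- c(1, 3, 2, 5, 4, 6)
  v <- rbind(g1 = prof, g2 = prof, g3 = prof)
  colnames(v) <- paste0("s", 1:6)
  x <- expression_dataset(v, species = "t")
  part <- stats::setNames(rep("turquoise", 3), rownames(v))
  me <- module_eigengenes(x, part)
  expect_equal(abs(stats::cor(me$eigengenes[, "turquoise"], prof)), 1)
  expect_equal(unname(me$kme[, "turquoise"]), rep(1, 3))

  # orientation convention: flipping all genes flips the eigengene back
  me2 <- module_eigengenes(expression_dataset(-v, species = "t"), part)
  z_flipped <- t(scale(t(-v)))
  expect_gte(stats::cor(me2$eigengenes[, "turquoise"], colMeans(z_flipped)),
             0)

  # a noise gene has low kME against a strong module
  cfg <- synthetic_config(list(synthetic_module(40, loading = 1)),
                          n_background = 60, noise_sd = 0.1,
                          n_samples_a = 30, seed = 23)
  sim <- generate_paired_datasets(cfg)
  truth <- sim$truth$true_module_of$a
  xa <- expression_dataset(sim$truth$profiles_a, species = "A")
  labs <- stats::setNames(ifelse(truth == 1, "turquoise", "grey"),
                          names(truth))
  mea <- module_eigengenes(xa, labs)
  bg_kme <- abs(mea$kme[names(truth)[truth == 0], "turquoise"])
  expect_lt(stats::median(bg_kme), 0.5)
  in_kme <- mea$kme[names(truth)[truth == 1], "turquoise"]
  expect_gt(min(in_kme), 0.8)
})

test_that("tissue specificity recovers planted per-tissue shifts", {
  pat_a1 <- c(0, 0, 0, 2, 0, 0, 0, 0)   # module 1 up in tissue 4
  pat_a2 <- c(0, 0, 0, -2, 0, 0, 0, 2)  # module 2 up in tissue 8
  cfg <- synthetic_config(list(
    synthetic_module(20, tissue_pattern_a = pat_a1),
    synthetic_module(20, tissue_pattern_a = pat_a2)),
    n_background = 20, noise_sd = 0.1, seed = 19)
  sim <- generate_paired_datasets(cfg)
  truth <- sim$truth$true_module_of$a
  labs <- stats::setNames(
    c("turquoise", "blue", "grey")[ifelse(truth == 0, 3, truth)],
    names(truth))
  x <- expression_dataset(sim$truth$profiles_a, species = "A")
  ts <- tissue_specificity(x, structure(list(label_of = labs),
                                        class = "ModulePartition"))
  expect_equal(unname(ts$top_tissue["turquoise"]), "tissueA4")
  expect_equal(unname(ts$top_tissue["blue"]), "tissueA8")
  # an exactly flat module triggers the tie warning
  vflat <- matrix(5, 4, 4,
                  dimnames = list(paste0("f", 1:4), paste0("s", 1:4)))
  flat_labs <- stats::setNames(rep("turquoise", 4), rownames(vflat))
  expect_warning(
    tissue_specificity(expression_dataset(vflat, species = "f"),
                       structure(list(label_of = flat_labs),
                                 class = "ModulePartition")),
    "tie")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # module identical to a set of size k in a background of 2k:
  # p = 1 / choose(2k, k)
  for (k in 2:5) {
    bg <- paste0("g", 1:(2 * k))
    mod <- bg[1:k]
    res <- enrich_hypergeometric(mod, list(hit = mod), bg)
    expect_equal(res$p_value, 1 / choose(2 * k, k), tolerance = 1e-12)
  }
  # against the summed-pmf oracle on a random scenario
  set.seed(40)
  bg <- paste0("g", 1:30)
  sets <- list(s1 = sample(bg, 12), s2 = sample(bg, 7), s3 = sample(bg, 20))
  mod <- sample(bg, 10)
  res <- enrich_hypergeometric(mod, sets, bg)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p_value[i],
                 naive_hyper_upper(res$overlap[i], res$set_size[i], 30, 10),
                 tolerance = 1e-12)
  }
  expect_equal(res$p_adjusted, pmin(1, res$p_value * 3))
  # zero overlap with an everything-set still yields p = 1
  res0 <- enrich_hypergeometric(character(0), list(all = bg), bg)
  expect_equal(res0$p_value, 1)
  expect_error(enrich_hypergeometric(mod, sets, character(0)), "empty")
})

test_that("null-overlap enrichment p-values are uniform-ish", {
  set.seed(55)
  bg <- paste0("g", 1:200)
  s <- bg[1:40]
  ps <- replicate(400, {
    mod <- sample(bg, 30)
    enrich_hypergeometric(mod, list(s = s), bg)$p_value
  })
  expect_gt(stats::median(ps), 0.3)
  expect_lt(stats::median(ps), 0.8)
})
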