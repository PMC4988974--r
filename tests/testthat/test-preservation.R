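truth_partition <- function(truth, labels = c("turquoise", "blue")) {
  labs <- ifelse(truth == 0, "grey", labels[truth])
  names(labs) <- names(truth)
  structure(list(label_of = labs), class = "ModulePartition")
}

test_that("a module preserved against itself scores strongly", {
  cfg <- synthetic_config(list(synthetic_module(40)), n_background = 100,
                          seed = 61)
  sim <- generate_paired_datasets(cfg)
  xa <- expression_dataset(sim$truth$profiles_a, species = "A")
  part <- truth_partition(sim$truth$true_module_of$a)
  rep <- z_summary(xa, xa, part, n_perm = 100, gold_size = 30, seed = 1)
  z <- rep$z_summary[rep$module == "turquoise"]
  expect_gt(z, 10)
  expect_equal(rep$category[rep$module == "turquoise"], "strong")
  # self-preservation beats the size-matched gold control
  expect_gt(z, rep$z_summary[rep$module == "gold"])
  # identical data: kME columns match perfectly
  expect_equal(rep$kme_cor_all[rep$module == "turquoise"], 1,
               tolerance = 1e-8)
})

test_that("an independent-noise module is not preserved", {
  cfg <- synthetic_config(list(synthetic_module(40, preserved = FALSE)),
                          n_background = 100, seed = 62)
  sim <- generate_paired_datasets(cfg)
  h <- harmonize_orthologs(sim$expr_a, sim$expr_b, sim$map_a, sim$map_b)
  part <- truth_partition(sim$truth$true_module_of$a[rownames(h$a$values)])
  rep <- z_summary(h$a, h$b, part, n_perm = 100, gold_size = 30, seed = 2)
  expect_lt(abs(rep$z_summary[rep$module == "turquoise"]), 2)
  expect_equal(rep$category[rep$module == "turquoise"], "not_preserved")
})

test_that("preservation categories follow the fixed thresholds", {
  expect_equal(preservation_category(c(6.69, 1.80, 12, -0.95, 2, 10)),
               c("moderate", "not_preserved", "strong", "not_preserved",
                 "moderate", "moderate"))
})

test_that("permutation draws are reproducible under a fixed seed", {
  cfg <- synthetic_config(list(synthetic_module(30)), n_background = 60,
                          seed = 63)
  sim <- generate_paired_datasets(cfg)
  h <- harmonize_orthologs(sim$expr_a, sim$expr_b, sim$map_a, sim$map_b)
  part <- truth_partition(sim$truth$true_module_of$a[rownames(h$a$values)])
  r1 <- z_summary(h$a, h$b, part, n_perm = 60, gold_size = 20, seed = 9)
  r2 <- z_summary(h$a, h$b, part, n_perm = 60, gold_size = 20, seed = 9)
  expect_identical(r1, r2)
})

test_that("overlap table counts and Fisher p match enumeration", {
  genes <- paste0("g", 1:100)
  la <- stats::setNames(rep(c("turquoise", "blue", "grey"),
                            times = c(20, 20, 60)), genes)
  lb <- la
  pa <- structure(list(label_of = la), class = "ModulePartition")
  pb <- structure(list(label_of = lb), class = "ModulePartition")
  ovl <- overlap_table(pa, pb)
  expect_equal(ovl$counts["turquoise", "turquoise"], 20)
  expect_equal(ovl$counts["turquoise", "blue"], 0)
  # row sums equal module sizes restricted to the shared universe
  expect_equal(unname(rowSums(ovl$counts)[c("turquoise", "blue", "grey")]),
               c(20, 20, 60))
  # diagonal p is the row minimum for identical partitions
  expect_equal(unname(which.min(ovl$p["turquoise", ])),
               which(colnames(ovl$p) == "turquoise"))

  # a 2x2 cell against the hypergeometric enumeration oracle:
  # 10 shared, sizes 20 and 20, universe 100
  lb2 <- stats::setNames(rep("grey", 100), genes)
  lb2[c(paste0("g", 1:10), paste0("g", 51:60))] <- "turquoise"
  pb2 <- structure(list(label_of = lb2), class = "ModulePartition")
  ovl2 <- overlap_table(pa, pb2)
  expect_equal(ovl2$counts["turquoise", "turquoise"], 10)
  expect_equal(ovl2$p["turquoise", "turquoise"],
               naive_fisher2x2(10, 10, 10, 70), tolerance = 1e-9)
})

test_that("independent random partitions rarely overlap significantly", {
  set.seed(70)
  genes <- paste0("g", 1:300)
  frac_sig <- replicate(10, {
    la <- stats::setNames(sample(rep(c("turquoise", "blue", "brown"),
                                     each = 100)), genes)
    lb <- stats::setNames(sample(rep(c("turquoise", "blue", "brown"),
                                     each = 100)), genes)
    pa <- structure(list(label_of = la), class = "ModulePartition")
    pb <- structure(list(label_of = lb), class = "ModulePartition")
    mean(overlap_table(pa, pb)$p < 0.05)
  })
  expect_lte(mean(frac_sig), 0.05 + 0.03)
})

test_that("kME correlations report identity and noise correctly", {
  set.seed(71)
  genes <- paste0("g", 1:60)
  km <- matrix(stats::runif(60, -1, 1), 60, 1,
               dimnames = list(genes, "turquoise"))
  labs <- stats::setNames(rep(c("turquoise", "blue"), each = 30), genes)
  part <- structure(list(label_of = labs), class = "ModulePartition")
  res <- kme_correlations(km, km, "turquoise", part)
  expect_equal(unname(res$all["r"]), 1)
  expect_equal(unname(res$in_module["r"]), 1)
  # independent noise: mostly insignificant over seeded repeats
  sig <- replicate(20, {
    k2 <- matrix(stats::runif(60, -1, 1), 60, 1,
                 dimnames = list(genes, "turquoise"))
    kme_correlations(km, k2, "turquoise", part)$in_module["p"] < 0.05
  })
  expect_gte(mean(!sig), 0.8)
  # direct oracle on a mixed vector
  k3 <- km
  k3[1:10, 1] <- -k3[1:10, 1]
  res3 <- kme_correlations(km, k3, "turquoise", part)
  scope <- genes[labs == "turquoise"]
  expect_equal(unname(res3$in_module["r"]),
               stats::cor(km[scope, 1], k3[scope, 1]), tolerance = 1e-12)
})
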