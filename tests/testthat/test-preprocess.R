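make_ds <- function(m, species = "x") expression_dataset(m, species = species)

test_that("harmonization keeps max-SD transcripts and the sorted intersection", {
  # one ortholog with two transcripts of different spread
  v <- rbind(t1 = c(1, 1.5, 1, 1.2), t2 = c(0, 4, -2, 3),
             t3 = c(5, 5, 5.5, 5.1))
  colnames(v) <- paste0("s", 1:4)
  a <- make_ds(v, "A")
  vb <- rbind(u1 = c(2, 1, 0, 2), u2 = c(1, 1, 2, 1))
  colnames(vb) <- paste0("t", 1:4)
  b <- make_ds(vb, "B")
  map_a <- data.frame(transcript_id = c("t1", "t2", "t3"),
                      ortholog_id = c("OG1", "OG1", "OG2"),
                      evalue = c(1e-10, 1e-12, 1e-9))
  map_b <- data.frame(transcript_id = c("u1", "u2"),
                      ortholog_id = c("OG1", "OG3"),
                      evalue = c(1e-8, 1e-8))
  h <- harmonize_orthologs(a, b, map_a, map_b)
  expect_equal(rownames(h$a$values), "OG1")
  expect_equal(unname(h$transcript_of$a["OG1"]), "t2")  # SD 2.6 > 0.24
  expect_equal(h$a$values["OG1", ], v["t2", ])

  # disjoint ortholog sets fail loudly
  map_b2 <- data.frame(transcript_id = c("u1", "u2"),
                       ortholog_id = c("OG7", "OG8"),
                       evalue = c(1e-8, 1e-8))
  expect_error(harmonize_orthologs(a, b, map_a, map_b2),
               "empty intersection")
})

test_that("harmonization matches a set-intersection oracle and is idempotent", {
  cfg <- synthetic_config(list(synthetic_module(30)), n_background = 70,
                          duplicate_rate = 0.1, seed = 13)
  sim <- generate_paired_datasets(cfg)
  # add private transcripts on each side
  extra_a <- expression_dataset(
    rbind(sim$expr_a$values,
          matrix(stats::rnorm(10 * 8), 10, 8,
                 dimnames = list(paste0("spA_priv", 1:10),
                                 colnames(sim$expr_a$values)))),
    species = "A")
  map_a <- rbind(sim$map_a,
                 data.frame(transcript_id = paste0("spA_priv", 1:10),
                            ortholog_id = paste0("ogP", 1:10),
                            evalue = 1e-10))
  h <- harmonize_orthologs(extra_a, sim$expr_b, map_a, sim$map_b)
  shared <- sort(intersect(unique(sim$map_a$ortholog_id),
                           unique(sim$map_b$ortholog_id)))
  expect_identical(rownames(h$a$values), shared)
  expect_identical(rownames(h$a$values), rownames(h$b$values))
  # idempotence: re-harmonizing the harmonized outputs changes nothing
  id_map <- function(x) data.frame(transcript_id = rownames(x$values),
                                   ortholog_id = rownames(x$values),
                                   evalue = 1e-10)
  h2 <- harmonize_orthologs(h$a, h$b, id_map(h$a), id_map(h$b))
  expect_identical(h2$a$values, h$a$values)
  expect_identical(h2$b$values, h$b$values)
})

test_that("qc_filter removes constant/missing genes and its report reconciles", {
  v <- matrix(stats::rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  x <- make_ds(v)
  clean <- qc_filter(x)
  expect_equal(nrow(clean$x$values), 10)
  expect_equal(nrow(clean$report$genes_removed), 0)

  v2 <- v
  v2["g3", ] <- 7                      # constant
  v2["g5", c(1, 2, 3)] <- NA           # 75% missing
  f <- qc_filter(make_ds(v2))
  expect_setequal(f$report$genes_removed$gene, c("g3", "g5"))
  expect_equal(f$report$n_genes_before - f$report$n_genes_after,
               nrow(f$report$genes_removed))
  expect_error(qc_filter(make_ds(matrix(1, 2, 3,
    dimnames = list(c("a", "b"), c("s1", "s2", "s3"))))), "all genes")
})

test_that("an independent-noise sample is flagged as an outlier", {
  set.seed(42)
  n <- 500
  base <- stats::rnorm(n, sd = 2)
  v <- sapply(1:6, function(i) base + stats::rnorm(n, sd = 0.3))
  v <- cbind(v, stats::rnorm(n, sd = 2))   # sample 7: unrelated noise
  dimnames(v) <- list(paste0("g", 1:n), paste0("s", 1:7))
  f <- qc_filter(make_ds(v), outlier_z = 2.0)
  expect_equal(f$report$samples_flagged, "s7")
  # oracle: recompute standardized mean inter-sample correlations by hand
  cc <- stats::cor(v); diag(cc) <- NA
  mc <- rowMeans(cc, na.rm = TRUE)
  z <- (mc - mean(mc)) / stats::sd(mc)
  expect_true(z["s7"] < -2)
  expect_equal(ncol(f$x$values), 6)
})

test_that("comparability check equals a rank-correlation oracle", {
  set.seed(11)
  n <- 1000
  ma <- stats::rnorm(n, 5, 2)
  mb <- 0.6 * ma + stats::rnorm(n)
  va <- matrix(rep(ma, 3), n, 3, dimnames = list(paste0("g", 1:n), NULL))
  vb <- matrix(rep(mb, 4), n, 4, dimnames = list(paste0("g", 1:n), NULL))
  colnames(va) <- paste0("a", 1:3); colnames(vb) <- paste0("b", 1:4)
  res <- comparability_check(make_ds(va), make_ds(vb))
  # Spearman-by-definition oracle on the mean vectors
  oracle <- stats::cor(rank(ma), rank(mb))
  expect_equal(res$r, oracle, tolerance = 1e-12)
  expect_equal(res$n_shared, n)
  # identity and antisymmetry
  expect_equal(comparability_check(make_ds(va), make_ds(va))$r, 1)
  vrev <- matrix(rep(-ma, 4), n, 4,
                 dimnames = list(paste0("g", 1:n), paste0("r", 1:4)))
  expect_equal(comparability_check(make_ds(va), make_ds(vrev))$r, -1)
})

test_that("PCA overview separates species with a planted mean shift", {
  set.seed(5)
  n <- 200
  va <- matrix(stats::rnorm(n * 4), n, 4,
               dimnames = list(paste0("g", 1:n), paste0("a", 1:4)))
  vb <- matrix(stats::rnorm(n * 3) + 4, n, 3,
               dimnames = list(paste0("g", 1:n), paste0("b", 1:3)))
  sc <- pca_overview(make_ds(va, "A"), make_ds(vb, "B"))
  signs <- sign(sc$pc1)
  expect_true(length(unique(signs[sc$species == "A"])) == 1)
  expect_true(length(unique(signs[sc$species == "B"])) == 1)
  expect_false(signs[sc$species == "A"][1] == signs[sc$species == "B"][1])
  # oracle: first eigenvector of the sample covariance gives the same axis
  m <- t(cbind(va, vb)); m <- scale(m, scale = FALSE)
  ev <- eigen(stats::cov(m))$vectors[, 1]
  oracle_scores <- as.numeric(m %*% ev)
  expect_equal(abs(stats::cor(oracle_scores, sc$pc1)), 1, tolerance = 1e-8)
  # degenerate single-sample-per-species case
  expect_warning(
    pca_overview(make_ds(va[, 1, drop = FALSE], "A"),
                 make_ds(vb[, 1, drop = FALSE], "B")),
    "degenerate")
})
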