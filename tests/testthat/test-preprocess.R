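test_that("log-normalization follows the CP10K formula and conserves totals", {
  m <- matrix(c(1, 1, 2), nrow = 3, dimnames = list(paste0("g", 1:3), "c1"))
  ln <- lognormalize(m)
  expect_equal(unname(ln[, 1]),
               c(log(1 + 2500), log(1 + 2500), log(1 + 5000)))
  set.seed(1)
  r <- matrix(rpois(50 * 20, 3), 50, 20,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:20)))
  lr <- lognormalize(r)
  expect_true(all(abs(colSums(expm1(lr)) - 10000) < 1e-6))
  expect_error(lognormalize(-r), "non-negative")
})

test_that("all-zero cells are flagged and left at zero", {
  m <- matrix(c(1, 2, 0, 0), 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_warning(ln <- lognormalize(m), "all-zero")
  expect_equal(unname(ln[, "c2"]), c(0, 0))
})

test_that("variable gene selection ranks dominant dispersion first", {
  set.seed(2)
  m <- matrix(rnorm(100 * 50, mean = 5, sd = 1), 100, 50)
  m[7, ] <- rnorm(50, mean = 5, sd = sqrt(10))
  rownames(m) <- sprintf("g%03d", 1:100)
  expect_equal(select_variable_genes(m, 1), "g007")
  expect_setequal(select_variable_genes(m, 100), rownames(m))
  expect_error(select_variable_genes(m, 101), "exceeds")
})

test_that("planted program genes dominate the variable gene ranking", {
  sim <- generate_immune_counts(small_config(seed = 9))
  ln <- lognormalize(sim$counts)
  prog <- unique(unlist(sim$truth$program_gene_members))
  top <- select_variable_genes(ln, length(prog))
  expect_gte(mean(prog %in% top), 0.8)
})

test_that("regression and scaling remove covariates and standardize genes", {
  set.seed(3)
  n <- 80
  batch <- factor(rep(1:2, each = n / 2))
  m <- matrix(rnorm(40 * n), 40, n,
              dimnames = list(paste0("g", 1:40), paste0("c", 1:n)))
  m[5, ] <- as.numeric(batch)                      # perfect confound
  cov <- data.frame(batch = batch, pct_mito = runif(n), pct_ribo = runif(n))
  sc <- regress_and_scale(m, cov)
  expect_true(all(abs(rowMeans(sc)) < 1e-8))
  nonconst <- apply(sc, 1, sd) > 0
  expect_true(all(abs(apply(sc[nonconst, ], 1, sd) - 1) < 1e-6))
  expect_true(all(abs(sc[5, ]) < 1e-8))
  # residuals orthogonal to the covariate design
  X <- model.matrix(~., cov)
  resid_dot <- abs(crossprod(t(sc), scale(X[, -1])))
  expect_lt(max(resid_dot) / n, 1e-6)
  # constant covariates reduce to a plain per-gene z-score
  sc0 <- regress_and_scale(m, data.frame(batch = rep(1, n)))
  expect_equal(sc0, t(scale(t(m))), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("regressing the batch covariate shrinks between-batch gaps", {
  sim <- generate_immune_counts(small_config(seed = 10, batch_effect_sd = 1))
  ln <- lognormalize(sim$counts)
  batch <- factor(sim$truth$batch)
  z <- t(scale(t(ln)))
  z[is.na(z)] <- 0
  gap <- function(m) mean(abs(rowMeans(m[, batch == 1]) -
                              rowMeans(m[, batch == 2])))
  sc <- regress_and_scale(ln, data.frame(batch = batch))
  expect_gt(gap(z) / gap(sc), 5)
})

test_that("parallel analysis counts planted components and ignores noise", {
  ks <- vapply(1:10, function(s) {
    set.seed(s)
    noise <- matrix(rnorm(60 * 80), 60, 80)
    nontrivial_components(t(scale(t(noise))), n_max = 20, n_perm = 20, seed = s)
  }, numeric(1))
  expect_true(all(ks <= 2))
  set.seed(11)
  u <- matrix(rnorm(60 * 3), 60, 3)
  v <- matrix(rnorm(80 * 3), 80, 3)
  signal <- u %*% (diag(c(9, 7, 5)) %*% t(v)) + matrix(rnorm(60 * 80, sd = 0.1), 60, 80)
  expect_equal(nontrivial_components(signal, n_max = 20, n_perm = 10, seed = 1), 3)
  expect_equal(nontrivial_components(signal, n_max = 1, n_perm = 5, seed = 1), 1)
  expect_error(nontrivial_components(matrix(1, 5, 5)), "rank")
})

test_that("SNN clustering separates blobs and is permutation-equivariant", {
  set.seed(4)
  emb <- rbind(matrix(rnorm(100, 0, 0.2), 50, 2),
               matrix(rnorm(100, 5, 0.2), 50, 2))
  rownames(emb) <- sprintf("c%03d", 1:100)
  truth <- rep(1:2, each = 50)
  cl <- snn_cluster(emb, k_neighbors = 10, resolution = 0.3, seed = 1)
  expect_equal(adjusted_rand_index(cl, truth), 1)
  # single blob at low resolution
  one <- matrix(rnorm(160, 0, 0.2), 80, 2)
  rownames(one) <- sprintf("c%03d", 1:80)
  expect_equal(length(unique(snn_cluster(one, k_neighbors = 10,
                                         resolution = 0.1, seed = 1))), 1)
  # permuting cells permutes labels identically up to renaming
  perm <- sample(nrow(emb))
  clp <- snn_cluster(emb[perm, ], k_neighbors = 10, resolution = 0.3, seed = 1)
  expect_equal(adjusted_rand_index(clp, cl[perm]), 1)
  expect_identical(clp[rownames(emb)], cl)
  expect_error(snn_cluster(emb[1:5, ], k_neighbors = 10), "fewer cells")
})

test_that("SNN clustering recovers planted cell types on synthetic data", {
  sim <- generate_immune_counts(synth_config(n_cells = 1500, n_genes = 800,
                                             program_sizes = c(
                                               ligand = 10, induction = 25,
                                               receptor = 10, activation = 25,
                                               signature = 25),
                                             seed = 12))
  ln <- lognormalize(sim$counts)
  hvg <- select_variable_genes(ln, 300)
  sc <- regress_and_scale(ln[hvg, ], data.frame(batch = factor(sim$truth$batch)))
  sv <- svd(sc, nu = 0, nv = 15)
  emb <- sv$v %*% diag(svd(sc, nu = 0, nv = 0)$d[1:15])
  rownames(emb) <- colnames(sc)
  cl <- snn_cluster(emb, k_neighbors = 20, resolution = 0.8, seed = 1)
  expect_gte(adjusted_rand_index(cl, sim$truth$cell_labels[names(cl)]), 0.8)
})

test_that("SVD enrichment matches exact low-rank and brute-force oracles", {
  # rank-1: scores proportional to the known right factor
  u <- c(1, 2, 3)
  v <- c(0.5, 1, 0.2, 2)
  m <- u %o% v
  dimnames(m) <- list(paste0("g", 1:3), paste0("c", 1:4))
  s <- svd_enrichment(m, paste0("g", 1:3), rescale = FALSE)
  expect_equal(abs(cor(s, v)), 1, tolerance = 1e-12)
  expect_gt(sum(s * colMeans(m)), 0)
  # brute force: eigenvector of the 4x4 Gram matrix
  set.seed(5)
  m2 <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  s2 <- svd_enrichment(m2, paste0("g", 1:3), rescale = FALSE)
  ev <- eigen(t(m2) %*% m2)$vectors[, 1]
  if (sum(ev * colMeans(m2)) < 0) ev <- -ev
  expect_lt(max(abs(abs(s2) - abs(ev))), 1e-10)
  # the SVD's internal sign ambiguity never leaks: repeated runs agree, and
  # negating the matrix flips the oriented raw score exactly
  expect_identical(svd_enrichment(m2, paste0("g", 1:3)),
                   svd_enrichment(m2, paste0("g", 1:3)))
  expect_equal(svd_enrichment(-m2, paste0("g", 1:3), rescale = FALSE),
               -svd_enrichment(m2, paste0("g", 1:3), rescale = FALSE),
               tolerance = 1e-10)
  # gene order invariance
  expect_equal(svd_enrichment(m2[c(3, 1, 2), ], paste0("g", 1:3)),
               svd_enrichment(m2, paste0("g", 1:3)), tolerance = 1e-10)
  expect_error(svd_enrichment(m2, c("g1", "gX", "gY")), "gX")
})

test_that("quantile filter retains the central mass", {
  set.seed(6)
  x <- rnorm(1000)
  mask <- quantile_filter(x, 0.95)
  # binomial 99% band around 950 of 1000
  expect_gte(sum(mask), qbinom(0.005, 1000, 0.95))
  expect_lte(sum(mask), qbinom(0.995, 1000, 0.95) + 2)
  expect_true(all(quantile_filter(rep(1, 100))))
  expect_warning(m <- quantile_filter(rnorm(5)), "fewer than 10")
  expect_true(all(m))
})
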