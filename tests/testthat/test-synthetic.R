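test_that("count generation is deterministic under a fixed seed and diverges otherwise", {
  a <- generate_immune_counts(small_config(seed = 1))
  b <- generate_immune_counts(small_config(seed = 1))
  c <- generate_immune_counts(small_config(seed = 2))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$cell_labels, b$truth$cell_labels)
  expect_false(identical(a$counts, c$counts))
})

test_that("zero program effect leaves program genes at background level", {
  cfg <- synth_config(n_cells = 500, n_genes = 400,
                      program_sizes = c(ligand = 10, induction = 20,
                                        receptor = 10, activation = 20,
                                        signature = 15),
                      program_effect = 0, seed = 3)
  sim <- generate_immune_counts(cfg)
  ln <- lognormalize(sim$counts)
  prog <- unlist(sim$truth$program_gene_members[c("ligand", "induction")])
  lab <- sim$truth$cell_labels
  mA <- colMeans(ln[prog, names(lab)[lab == "myeloidA"]])
  mB <- colMeans(ln[prog, names(lab)[lab == "myeloidB"]])
  expect_gt(t.test(mA, mB)$p.value, 0.01)
})

test_that("mean per-cell total matches the configured library size", {
  # analytic oracle: dropout-adjusted means are renormalized per cell, so
  # E[total UMI per cell] = library_size_mean exactly
  cfg <- synth_config(n_cells = 2000, n_genes = 400,
                      program_sizes = c(ligand = 10, induction = 20,
                                        receptor = 10, activation = 20,
                                        signature = 15),
                      library_size_mean = 5000, seed = 5)
  sim <- generate_immune_counts(cfg)
  expect_lt(abs(mean(Matrix::colSums(sim$counts)) / 5000 - 1), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_cells = 0), "n_cells")
  expect_error(synth_config(cell_type_proportions = numeric(0)), "empty")
  expect_error(synth_config(cell_type_proportions = c(myeloidA = 0.5, Texh = 0.4)),
               "sum to 1")
  expect_error(synth_config(n_genes = 100), "exceed")
})

test_that("planted program separation grows monotonically with effect size", {
  gap <- vapply(c(0.5, 1, 2), function(eff) {
    sim <- generate_immune_counts(small_config(seed = 7, program_effect = eff))
    ln <- lognormalize(sim$counts)
    z <- t(scale(t(ln)))
    prog <- sim$truth$program_gene_members$ligand
    lab <- sim$truth$cell_labels
    mean(z[prog, lab == "myeloidA"]) - mean(z[prog, lab != "myeloidA"])
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
})

test_that("spot aggregation conserves member-cell counts exactly", {
  cfg <- small_config(seed = 2)
  sim <- generate_immune_counts(cfg)
  grid <- generate_spatial_spots(cfg, sim$counts, sim$truth)
  members <- attr(grid, "members")
  dense <- as.matrix(sim$counts)
  for (s in c(1, 17, 40)) {
    expect_identical(unname(grid$counts[s, ]),
                     unname(rowSums(dense[, members[[s]], drop = FALSE])))
  }
})

test_that("median cells per spot equals the configured midpoint", {
  # enough spots that the sample median of the uniform 4..12 draw settles
  cfg <- small_config(seed = 4, grid_shape = c(18, 18))
  sim <- generate_immune_counts(cfg)
  grid <- generate_spatial_spots(cfg, sim$counts, sim$truth)
  n_per_spot <- lengths(attr(grid, "members"))
  expect_equal(median(n_per_spot), mean(cfg$cells_per_spot_range))
  expect_true(all(n_per_spot >= cfg$cells_per_spot_range[1]))
  expect_true(all(n_per_spot <= cfg$cells_per_spot_range[2]))
})

test_that("grid geometry respects the configured pitch", {
  cfg <- small_config(seed = 4, spot_pitch_um = 200)
  sim <- generate_immune_counts(cfg)
  grid <- generate_spatial_spots(cfg, sim$counts, sim$truth)
  xy <- cbind(grid$spots$x_um, grid$spots$y_um)
  nnd <- vapply(seq_len(nrow(xy)), function(i) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    min(d[-i])
  }, numeric(1))
  expect_true(all(nnd == 200))
})

test_that("without a region, composition is homogeneous across the grid", {
  cfg <- small_config(seed = 6, region_fraction = 0)
  sim <- generate_immune_counts(cfg)
  grid <- generate_spatial_spots(cfg, sim$counts, sim$truth)
  members <- attr(grid, "members")
  lab <- sim$truth$cell_labels
  half <- grid$spots$col < median(grid$spots$col)
  types_half <- table(lab[unlist(members[half])])
  types_rest <- table(lab[unlist(members[!half])])
  tab <- rbind(as.numeric(types_half), as.numeric(types_rest))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
  expect_true(all(grid$spots$region == "other"))
})

test_that("planted copy-number shifts scale tumor chromosomes and nothing else", {
  cfg <- small_config(seed = 8, cnv_shift = 1)
  sim <- generate_immune_counts(cfg)
  pos <- make_gene_positions(rownames(sim$counts))
  out <- plant_cnv(sim$counts, sim$truth, pos, cfg)
  lab <- sim$truth$cell_labels
  tumor <- names(lab)[lab == "tumor"]
  nont <- names(lab)[lab != "tumor"]
  chr7 <- intersect(pos$gene[pos$chrom == "chr7"], rownames(sim$counts))
  ratio <- sum(out$counts[chr7, tumor]) / sum(sim$counts[chr7, tumor])
  expect_lt(abs(ratio - 2), 0.2)
  # non-tumor columns bitwise unchanged
  expect_identical(as.matrix(out$counts[, nont]), as.matrix(sim$counts[, nont]))
  # zero shift is the identity
  cfg0 <- small_config(seed = 8, cnv_shift = 0)
  out0 <- plant_cnv(sim$counts, sim$truth, pos, cfg0)
  expect_identical(as.matrix(out0$counts), as.matrix(sim$counts))
  # unknown chromosome label
  cfgbad <- small_config(seed = 8, cnv_gain_chrom = "chr99")
  expect_error(plant_cnv(sim$counts, sim$truth, pos, cfgbad), "chr99")
})
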