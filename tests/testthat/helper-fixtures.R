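# shared fixtures and small utilities for the test suite

# small, fast generator configuration for unit tests
small_config <- function(seed = 1L, ...) {
  defaults <- list(n_cells = 600, n_genes = 400,
                   program_sizes = c(ligand = 10, induction = 20,
                                     receptor = 10, activation = 20,
                                     signature = 15),
                   grid_shape = c(8, 8), seed = seed)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (max_index - expected)
}

# scaled expression + planted-program spec for a simulated dataset
prepare_pipeline <- function(sim) {
  ln <- lognormalize(sim$counts)
  sc <- regress_and_scale(ln, data.frame(batch = factor(sim$truth$batch)))
  pg <- sim$truth$program_gene_members
  spec <- ligand_receptor_spec(pg$ligand, pg$induction, pg$receptor,
                               pg$activation,
                               target_cell_labels = c("Teff", "Texh"))
  list(scaled = sc, spec = spec, programs = pg)
}

# toy spot grid whose expression is hand-set per spot (genes x spots matrix)
toy_grid <- function(expr_by_spot, n_rows, n_cols, pitch = 200) {
  n_spots <- n_rows * n_cols
  stopifnot(ncol(expr_by_spot) == n_spots)
  rc <- expand.grid(row = seq_len(n_rows) - 1L, col = seq_len(n_cols) - 1L)
  spots <- data.frame(
    spot = sprintf("s%02d", seq_len(n_spots)),
    row = rc$row, col = rc$col,
    x_um = rc$col * pitch, y_um = rc$row * pitch,
    stringsAsFactors = FALSE
  )
  spatial_grid(spots, t(expr_by_spot), pitch_um = pitch,
               n_rows = n_rows, n_cols = n_cols)
}

# brute-force Moran's I with row-standardized weights (independent oracle)
moran_brute <- function(values, grid, scheme = "queen") {
  n <- length(values)
  r <- grid$spots$row
  c <- grid$spots$col
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dr <- abs(r[i] - r[j]); dc <- abs(c[i] - c[j])
    adj <- if (scheme == "rook") (dr + dc) == 1 else max(dr, dc) == 1
    if (adj) w[i, j] <- 1
  }
  for (i in seq_len(n)) if (sum(w[i, ]) > 0) w[i, ] <- w[i, ] / sum(w[i, ])
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}
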