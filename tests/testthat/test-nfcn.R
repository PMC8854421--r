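test_that("stratified downsampling is proportional and deterministic", {
  cells <- sprintf("c%04d", 1:2000)
  strata <- rep(c("a", "b"), c(1600, 400))
  expect_identical(downsample_representative(cells, 3000, strata), cells)
  big <- sprintf("c%04d", 1:5000)
  sb <- rep(c("a", "b"), c(4000, 1000))
  out <- downsample_representative(big, 1000, sb, seed = 1)
  expect_equal(length(out), 1000)
  tab <- table(sb[match(out, big)])
  expect_lte(abs(tab[["a"]] - 800), 1)
  expect_lte(abs(tab[["b"]] - 200), 1)
  expect_identical(out, downsample_representative(big, 1000, sb, seed = 1))
  expect_error(downsample_representative(character(0), 10, character(0)), "empty")
})

test_that("min-max normalization matches the literal formula", {
  expect_equal(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(-3, -1)), c(0, 1))
  set.seed(7)
  x <- rnorm(200)
  expect_lt(max(abs(minmax_normalize(x) -
                      (x - min(x)) / (max(x) - min(x)))), 1e-12)
  expect_error(minmax_normalize(rep(2, 5)), "constant")
})

test_that("kernel density estimator matches closed forms and direct summation", {
  # single atom, gaussian: f(0.5) = K(0)/h = 1/(h*sqrt(2*pi))
  expect_equal(kde_density(0.5, "gaussian", h = 0.5, eval_points = 0.5),
               1 / (0.5 * sqrt(2 * pi)), tolerance = 1e-12)
  # two points at 0 and 1, evaluated midway: symmetric sum
  f <- kde_density(c(0, 1), "gaussian", h = 0.4, eval_points = 0.5)
  oracle <- mean(dnorm((0.5 - c(0, 1)) / 0.4)) / 0.4
  expect_lt(abs(f - oracle), 1e-10)
  # cauchy kernel against direct summation
  set.seed(8)
  x <- runif(50)
  ev <- runif(10)
  fc <- kde_density(x, "cauchy", h = 0.45, eval_points = ev)
  oc <- vapply(ev, function(e)
    mean(1 / (pi * (1 + ((e - x) / 0.45)^2))) / 0.45, numeric(1))
  expect_lt(max(abs(fc - oc)), 1e-12)
  # bandwidth bounds are enforced
  expect_error(kde_density(x, "gaussian", h = 0.8), "0.3, 0.7")
  expect_error(kde_density(x, "gaussian", h = 0.3), "0.3, 0.7")
})

test_that("planted ligand cells occupy the extreme of the ligand side", {
  hits <- vapply(1:3, function(s) {
    sim <- generate_immune_counts(small_config(seed = s))
    pp <- prepare_pipeline(sim)
    ts <- build_interaction_trajectory(pp$scaled, pp$spec, sim$truth$cell_labels)
    lig <- ts[ts$side == "ligand" & ts$retained, ]
    topdec <- lig$cell[abs(lig$position) >=
                         quantile(abs(lig$position), 0.9, names = FALSE)]
    mean(topdec %in% sim$truth$ligand_cells)
  }, numeric(1))
  expect_true(all(hits >= 0.9))
})

test_that("removing the induction program worsens planted ligand ranks", {
  median_rank <- function(eff_ind) {
    sim <- generate_immune_counts(small_config(
      seed = 21,
      program_effect = c(ligand = 1.25, induction = eff_ind,
                         receptor = 1.25, activation = 1.25, signature = 1.25)))
    pp <- prepare_pipeline(sim)
    ts <- build_interaction_trajectory(pp$scaled, pp$spec, sim$truth$cell_labels)
    lig <- ts[ts$side == "ligand" & ts$retained, ]
    median(lig$rank[lig$cell %in% sim$truth$ligand_cells])
  }
  expect_gt(median_rank(0), median_rank(1.25))
})

test_that("degenerate trajectories propagate the constant-input error", {
  m <- matrix(1, 20, 40,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:40)))
  spec <- ligand_receptor_spec("g1", c("g2", "g3"), "g4", c("g5", "g6"), "T")
  clusters <- setNames(rep(c("M", "T"), each = 20), colnames(m))
  expect_error(
    suppressWarnings(build_interaction_trajectory(m, spec, clusters)),
    "constant")
})

test_that("pair selection counts and empty cases behave as specified", {
  # hand-built trajectory with aligned axes: eligible counts are exact
  mk_side <- function(side, n) {
    v <- seq(0, 1, length.out = n)
    data.frame(cell = sprintf("%s%03d", side, seq_len(n)), side = side,
               cluster = side, A_exp = v, A_eff = v, retained = TRUE,
               n_exp = v, n_eff = v, position = 0, f_hat = 0,
               rank = seq_len(n), stringsAsFactors = FALSE)
  }
  ts <- rbind(mk_side("ligand", 334), mk_side("receiver", 334))
  class(ts) <- c("trajectory_scores", "data.frame")
  pairs <- select_connected(ts, ci = 0.70, top_fraction = 0.01)
  v <- seq(0, 1, length.out = 334)
  n_el <- sum(v > quantile(v, 0.7))            # strictly above, per axis
  expect_equal(nrow(pairs), n_el^2)
  expect_equal(sum(pairs$connected), ceiling(0.01 * n_el^2))
  # exactly 100 x 100 eligible at 1% gives exactly 100 flagged pairs
  ts2 <- rbind(mk_side("ligand", 1000), mk_side("receiver", 1000))
  class(ts2) <- c("trajectory_scores", "data.frame")
  v2 <- seq(0, 1, length.out = 1000)
  ci100 <- mean(v2 <= sort(v2, decreasing = TRUE)[101])  # 100 strictly above
  pairs2 <- select_connected(ts2, ci = ci100, top_fraction = 0.01)
  expect_equal(nrow(pairs2), 100 * 100)
  expect_equal(sum(pairs2$connected), 100)
  # no receiver passes the retention filter: empty result, not an error
  ts3 <- ts
  ts3$retained[ts3$side == "receiver"] <- FALSE
  pairs3 <- select_connected(ts3)
  expect_equal(nrow(pairs3), 0)
  expect_s3_class(pairs3, "connected_pairs")
})

test_that("threshold coherence: stricter settings select nested subsets", {
  sim <- generate_immune_counts(small_config(seed = 13))
  pp <- prepare_pipeline(sim)
  ts <- build_interaction_trajectory(pp$scaled, pp$spec, sim$truth$cell_labels)
  key <- function(p) paste(p$ligand_cell, p$receiver_cell)
  prev <- NULL
  for (ci in c(0.5, 0.6, 0.7, 0.8, 0.9)) {
    cur <- key(select_connected(ts, ci = ci))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  pairs <- select_connected(ts, top_fraction = 0.05)
  prev <- NULL
  for (f in c(0.05, 0.02, 0.01, 0.005)) {
    p <- select_connected(ts, top_fraction = f)
    cur <- key(p[p$connected, ])
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("spatial proximity filter reproduces hand-computed toy distances", {
  # 3x3 grid, two cluster signatures expressed at single spots
  genes <- c("gA1", "gA2", "gB1", "gB2", paste0("bg", 1:6))
  base <- matrix(5, length(genes), 9, dimnames = list(genes, NULL))
  peak_a <- 1          # spot (row 0, col 0)
  peak_b <- 9          # spot (row 2, col 2)
  base[c("gA1", "gA2"), peak_a] <- 80
  base[c("gB1", "gB2"), peak_b] <- 80
  grid <- toy_grid(base, 3, 3, pitch = 200)
  pairs <- data.frame(
    ligand_cell = "l1", receiver_cell = "r1",
    ligand_cluster = "A", receiver_cluster = "B",
    pair_score = 1, connected = TRUE,
    distance_um = NA_real_, spatial_status = "unassessed",
    stringsAsFactors = FALSE
  )
  class(pairs) <- c("connected_pairs", "data.frame")
  sigs <- list(A = c("gA1", "gA2"), B = c("gB1", "gB2"))
  out <- spatial_proximity_filter(pairs, grid, sigs, top_spots = 1,
                                  smooth_theta = NULL)
  # peaks at opposite corners: hand-computed distance sqrt(400^2+400^2)
  expect_equal(out$distance_um, sqrt(2) * 400, tolerance = 1e-9)
  expect_equal(out$spatial_status, "excluded")
  # same peak spot: distance zero, retained
  base2 <- base
  base2[c("gB1", "gB2"), ] <- 5
  base2[c("gB1", "gB2"), peak_a] <- 80
  out2 <- spatial_proximity_filter(pairs, toy_grid(base2, 3, 3, pitch = 200),
                                   sigs, top_spots = 1, smooth_theta = NULL)
  expect_equal(out2$distance_um, 0)
  expect_equal(out2$spatial_status, "retained")
  # peaks two pitches apart on one axis are excluded at 150 um
  base3 <- base
  base3[c("gB1", "gB2"), ] <- 5
  base3[c("gB1", "gB2"), 7] <- 80   # row 0, col 2 -> 400 um from peak_a
  out3 <- spatial_proximity_filter(pairs, toy_grid(base3, 3, 3, pitch = 200),
                                   sigs, top_spots = 1, smooth_theta = NULL)
  expect_equal(out3$distance_um, 400, tolerance = 1e-9)
  expect_equal(out3$spatial_status, "excluded")
  # grid without micrometer coordinates errors
  g <- toy_grid(base, 3, 3)
  g$spots$x_um <- NULL
  expect_error(spatial_proximity_filter(pairs, g, sigs), "micrometer")
})

test_that("NFCN score matrix normalizes and handles the empty case", {
  pairs <- data.frame(
    ligand_cell = "l1", receiver_cell = "r1",
    ligand_cluster = "A", receiver_cluster = "B",
    pair_score = 0.37, connected = TRUE,
    distance_um = NA_real_, spatial_status = "unassessed",
    stringsAsFactors = FALSE
  )
  class(pairs) <- c("connected_pairs", "data.frame")
  sm <- nfcn_score(pairs)
  expect_equal(unname(sm["A", "B"]), 1)
  empty <- pairs[0, ]
  class(empty) <- c("connected_pairs", "data.frame")
  sm0 <- nfcn_score(empty, ligand_clusters = c("A", "C"),
                    receiver_clusters = "B")
  expect_true(all(sm0 == 0))
  expect_equal(dim(sm0), c(2, 1))
})
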