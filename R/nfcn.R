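#' Ligand-receptor interaction specification
#'
#' Names the four gene programs the connection model requires: the ligand
#' itself, the upstream program inducing its expression (evidence the ligand
#' is functionally produced), the receptor, and the downstream program
#' activated by receptor engagement (evidence the signal is received), plus
#' the cluster labels of the receiver population.
#'
#' @param ligand_genes,induction_genes,receptor_genes,activation_genes
#'   Character vectors of gene ids; non-empty and pairwise disjoint.
#' @param target_cell_labels Cluster labels identifying receiver cells.
#' @return A list of class `ligand_receptor_spec`.
#' @export
ligand_receptor_spec <- function(ligand_genes, induction_genes,
                                 receptor_genes, activation_genes,
                                 target_cell_labels) {
  sets <- list(ligand = ligand_genes, induction = induction_genes,
               receptor = receptor_genes, activation = activation_genes)
  if (any(lengths(sets) == 0)) stop("all four gene sets must be non-empty")
  for (i in 1:3) for (j in (i + 1):4)
    if (length(intersect(sets[[i]], sets[[j]])))
      stop("gene sets must be pairwise disjoint: ", names(sets)[i],
           " overlaps ", names(sets)[j])
  if (!length(target_cell_labels)) stop("target_cell_labels is empty")
  structure(c(sets, list(target_cell_labels = target_cell_labels)),
            class = "ligand_receptor_spec")
}

#' Stratified representative downsampling
#'
#' Proportional stratified sampling without replacement: each stratum
#' contributes cells in proportion to its size (largest-remainder
#' rounding). All cells are returned when there are fewer than `n`.
#'
#' @param cells Character vector of cell ids.
#' @param n Target sample size (default 3000, the reference setting).
#' @param strata Stratum label per cell (e.g. cluster).
#' @param seed Seed for the within-stratum sampling.
#' @return Character vector of sampled cell ids.
#' @export
downsample_representative <- function(cells, n = 3000, strata, seed = 1L) {
  if (!length(cells)) stop("empty cell set")
  stopifnot(length(strata) == length(cells))
  if (length(cells) <= n) return(cells)
  groups <- split(cells, strata)
  if (n < length(groups))
    stop("n (", n, ") below the number of strata (", length(groups), ")")
  take <- .allocate(n, lengths(groups))
  set.seed(seed)
  out <- unlist(lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    g[sample.int(length(g), min(take[i], length(g)))]
  }), use.names = FALSE)
  out
}

#' Min-max normalization to the unit interval
#'
#' `(a - min(a)) / (max(a) - min(a))`, elementwise. Undefined (and an
#' error) for constant input.
#'
#' @param a Numeric vector with at least two distinct values.
#' @return Numeric vector in `[0, 1]`, names preserved.
#' @export
minmax_normalize <- function(a) {
  if (!length(a) || anyNA(a)) stop("input must be non-missing")
  rng <- range(a)
  if (rng[2] - rng[1] <= 0)
    stop("constant vector: min-max normalization is undefined")
  (a - rng[1]) / (rng[2] - rng[1])
}

#' Kernel density estimate on the unit interval
#'
#' The plain kernel estimator
#' `f(x) = (1/n) * sum_i K((x - x_i)/h) / h` with a Gaussian
#' (`dnorm`) or Cauchy (`1/(pi (1 + u^2))`) kernel. The bandwidth is
#' restricted to the open interval `(0.3, 0.7)`, the range the estimator is
#' specified for on min-max normalized scores.
#'
#' @param x Sample points, in `[0, 1]`.
#' @param kernel `"gaussian"` or `"cauchy"`.
#' @param h Bandwidth, strictly between 0.3 and 0.7.
#' @param eval_points Where to evaluate (defaults to `x`).
#' @return Numeric densities at `eval_points`.
#' @export
kde_density <- function(x, kernel = c("gaussian", "cauchy"), h = 0.5,
                        eval_points = x) {
  kernel <- match.arg(kernel)
  if (!(h > 0.3 && h < 0.7))
    stop("bandwidth h = ", h, " outside the permitted interval (0.3, 0.7)")
  if (any(x < -1e-9 | x > 1 + 1e-9))
    stop("sample points must lie in [0, 1]")
  K <- switch(kernel,
    gaussian = function(u) stats::dnorm(u),
    cauchy = function(u) 1 / (pi * (1 + u^2))
  )
  n <- length(x)
  vapply(eval_points, function(e) sum(K((e - x) / h)) / (n * h), numeric(1))
}

# one side (ligand candidates or receivers) of the interaction trajectory
.trajectory_side <- function(m, cells, exp_genes, eff_genes, side_sign,
                             side, clusters, kernel, h, q) {
  exp_present <- intersect(exp_genes, rownames(m))
  if (!length(exp_present))
    stop("no ", side, "-side expression genes present in the matrix")
  sub <- m[, cells, drop = FALSE]
  a_exp <- colMeans(sub[exp_present, , drop = FALSE])
  a_eff <- svd_enrichment(sub, eff_genes)
  retained <- quantile_filter(a_exp, q) & quantile_filter(a_eff, q)
  n_exp <- n_eff <- position <- f_hat <- rep(NA_real_, length(cells))
  rank_ <- rep(NA_integer_, length(cells))
  if (sum(retained) >= 2) {
    n_exp[retained] <- minmax_normalize(a_exp[retained])
    n_eff[retained] <- minmax_normalize(a_eff[retained])
    raw_pos <- side_sign * (n_exp[retained] + n_eff[retained]) / 2
    # kernel-weighted local averaging along the expression axis (the fitted
    # density model smooths each cell's position by its neighborhood)
    K <- switch(kernel,
      gaussian = function(u) stats::dnorm(u),
      cauchy = function(u) 1 / (pi * (1 + u^2))
    )
    W <- K(outer(n_exp[retained], n_exp[retained], `-`) / h)
    position[retained] <- as.vector(W %*% raw_pos) / rowSums(W)
    f_hat[retained] <- kde_density(n_exp[retained], kernel = kernel, h = h)
    ord <- order(-abs(position[retained]), cells[retained])
    rk <- integer(sum(retained))
    rk[ord] <- seq_len(sum(retained))
    rank_[retained] <- rk
  }
  data.frame(
    cell = cells, side = side,
    cluster = as.character(clusters[cells]),
    A_exp = unname(a_exp), A_eff = unname(a_eff),
    retained = unname(retained),
    n_exp = n_exp, n_eff = n_eff,
    position = position, f_hat = f_hat, rank = rank_,
    stringsAsFactors = FALSE
  )
}

#' Align cells along the ligand-receptor interaction trajectory
#'
#' For candidate ligand cells (all cells outside the target labels) the
#' expression score `A_exp` is the mean scaled expression of the ligand
#' genes and the effect score `A_eff` the SVD enrichment of the upstream
#' induction program; receivers (target labels) are scored on receptor
#' expression and downstream activation enrichment. Each side is outlier
#' filtered (central 95% on both scores), min-max normalized, and placed at
#' `position = -(n_exp + n_eff)/2` (ligand side) or `+(n_exp + n_eff)/2`
#' (receiver side); positions are then smoothed by kernel-weighted local
#' averaging along the expression axis, so the trajectory runs from strong
#' ligand producers at one pole to strongly activated receivers at the
#' other. Ranks (1 = most extreme) are assigned by `|position|` per side.
#'
#' @param m Gene x cell scaled expression matrix.
#' @param spec A [ligand_receptor_spec()].
#' @param clusters Per-cell cluster labels, named by cell id.
#' @param kernel Smoothing kernel, `"gaussian"` (default) or `"cauchy"`.
#' @param h Kernel bandwidth in `(0.3, 0.7)`; default 0.5.
#' @param q Central quantile retained by the outlier filter (default 0.95).
#' @return A data.frame of class `trajectory_scores` with one row per cell:
#'   `cell`, `side`, `cluster`, `A_exp`, `A_eff`, `retained`, `n_exp`,
#'   `n_eff`, `position`, `f_hat`, `rank`.
#' @export
build_interaction_trajectory <- function(m, spec, clusters,
                                         kernel = c("gaussian", "cauchy"),
                                         h = 0.5, q = 0.95) {
  stopifnot(inherits(spec, "ligand_receptor_spec"))
  kernel <- match.arg(kernel)
  if (!(h > 0.3 && h < 0.7))
    stop("bandwidth h = ", h, " outside the permitted interval (0.3, 0.7)")
  m <- as.matrix(m)
  cells <- colnames(m)
  if (is.null(names(clusters))) names(clusters) <- cells
  is_target <- clusters[cells] %in% spec$target_cell_labels
  lig_cells <- cells[!is_target]
  rec_cells <- cells[is_target]
  if (!length(lig_cells) || !length(rec_cells))
    stop("both trajectory sides must be non-empty")
  out <- rbind(
    .trajectory_side(m, lig_cells, spec$ligand, spec$induction, -1,
                     "ligand", clusters, kernel, h, q),
    .trajectory_side(m, rec_cells, spec$receptor, spec$activation, +1,
                     "receiver", clusters, kernel, h, q)
  )
  attr(out, "kernel") <- kernel
  attr(out, "h") <- h
  attr(out, "q") <- q
  class(out) <- c("trajectory_scores", "data.frame")
  out
}

#' Select connected cell pairs from a trajectory
#'
#' Connected cells are those in the upper confidence band on *both* score
#' axes of their side: above the `ci` empirical percentile in normalized
#' expression and in normalized effect enrichment. Every eligible ligand
#' cell is paired with every eligible receiver; the pair score is the
#' product of the four normalized scores (the conjunction of ligand,
#' induction, receptor and activation evidence), and the top `top_fraction`
#' of pairs by score are additionally flagged `connected` (the
#' highly-connected subset used for characterization).
#'
#' @param ts A [build_interaction_trajectory()] result.
#' @param ci Eligibility percentile per axis (default 0.70).
#' @param top_fraction Fraction of pairs flagged highly connected
#'   (default 0.01).
#' @return A data.frame of class `connected_pairs` with `ligand_cell`,
#'   `receiver_cell`, their clusters, `pair_score`, `connected` and
#'   `spatial_status` (initially `"unassessed"`); empty when no cell is
#'   eligible.
#' @export
select_connected <- function(ts, ci = 0.70, top_fraction = 0.01) {
  stopifnot(inherits(ts, "trajectory_scores"))
  if (ci <= 0 || ci >= 1) stop("ci must be in (0, 1)")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  eligible_side <- function(side) {
    d <- ts[ts$side == side & ts$retained, , drop = FALSE]
    if (!nrow(d)) return(d[0, ])
    thr_exp <- quantile(d$n_exp, ci, names = FALSE)
    thr_eff <- quantile(d$n_eff, ci, names = FALSE)
    d[d$n_exp > thr_exp & d$n_eff > thr_eff, , drop = FALSE]
  }
  L <- eligible_side("ligand")
  R <- eligible_side("receiver")
  empty <- data.frame(
    ligand_cell = character(0), receiver_cell = character(0),
    ligand_cluster = character(0), receiver_cluster = character(0),
    pair_score = numeric(0), connected = logical(0),
    distance_um = numeric(0), spatial_status = character(0),
    stringsAsFactors = FALSE
  )
  if (!nrow(L) || !nrow(R)) {
    out <- empty
  } else {
    il <- rep(seq_len(nrow(L)), times = nrow(R))
    ir <- rep(seq_len(nrow(R)), each = nrow(L))
    out <- data.frame(
      ligand_cell = L$cell[il], receiver_cell = R$cell[ir],
      ligand_cluster = L$cluster[il], receiver_cluster = R$cluster[ir],
      pair_score = (L$n_exp * L$n_eff)[il] * (R$n_exp * R$n_eff)[ir],
      stringsAsFactors = FALSE
    )
    k <- ceiling(top_fraction * nrow(out))
    ord <- order(-out$pair_score, out$ligand_cell, out$receiver_cell)
    out$connected <- FALSE
    out$connected[ord[seq_len(k)]] <- TRUE
    out$distance_um <- NA_real_
    out$spatial_status <- "unassessed"
  }
  attr(out, "thresholds") <- c(ci = ci, top_fraction = top_fraction)
  class(out) <- c("connected_pairs", "data.frame")
  out
}

#' Per-spot signature enrichment scores
#'
#' Log-normalizes the spot expression, z-scores genes across spots, and
#' computes SVD gene-set enrichment per spot for each signature.
#'
#' @param grid A [spatial_grid()].
#' @param signatures Named list of gene id vectors.
#' @return Spot x signature score matrix (NA column where a signature has
#'   fewer than two genes on the array).
#' @export
spot_signature_scores <- function(grid, signatures) {
  stopifnot(inherits(grid, "spatial_grid"))
  expr <- t(grid$counts)                     # gene x spot
  ln <- lognormalize(expr)
  sc <- regress_and_scale(ln, covariates = NULL)
  colnames(sc) <- grid$spots$spot
  out <- matrix(NA_real_, nrow(grid$spots), length(signatures),
                dimnames = list(grid$spots$spot, names(signatures)))
  for (nm in names(signatures)) {
    present <- intersect(signatures[[nm]], rownames(sc))
    if (length(present) >= 2)
      out[, nm] <- svd_enrichment(sc, present)
  }
  out
}

#' Spatial plausibility filter for connected pairs
#'
#' Places each cluster at the enrichment-weighted centroid of the five
#' spots scoring highest for its signature, assigns every cell its
#' cluster's putative position, and excludes pairs whose putative
#' ligand-receiver distance exceeds `max_dist_um`. Per-spot signature
#' scores are spatially regularized with the same squared-distance kernel
#' as [surface_matrix()] before peak-finding (`smooth_theta = NULL`
#' disables this), since single-spot scores at a handful of cells per spot
#' are too noisy for sub-pitch localization. Cells whose cluster signature
#' cannot be scored are marked `unmapped` and retained with a warning.
#'
#' @param pairs A [select_connected()] result.
#' @param grid A [spatial_grid()] with micrometer coordinates.
#' @param signatures Named list of cluster signature gene sets.
#' @param max_dist_um Distance cutoff in micrometers (default 150).
#' @param top_spots Spots averaged per cluster centroid (default 5).
#' @param smooth_theta Squared-distance threshold for the pre-smoothing
#'   (default `pitch^2`); `NULL` for raw per-spot scores.
#' @return `pairs` with `distance_um` and `spatial_status` filled in
#'   (`retained`, `excluded` or `unmapped`); cluster positions are attached
#'   as attribute `cluster_positions`.
#' @export
spatial_proximity_filter <- function(pairs, grid, signatures,
                                     max_dist_um = 150, top_spots = 5,
                                     smooth_theta = grid$pitch_um^2) {
  stopifnot(inherits(pairs, "connected_pairs"), inherits(grid, "spatial_grid"))
  if (!all(c("x_um", "y_um") %in% names(grid$spots)))
    stop("grid lacks micrometer coordinates")
  if (!nrow(pairs)) return(pairs)
  scores <- spot_signature_scores(grid, signatures)
  if (!is.null(smooth_theta) && smooth_theta > 0) {
    xy <- cbind(grid$spots$x_um, grid$spots$y_um)
    d2 <- outer(xy[, 1], xy[, 1], `-`)^2 + outer(xy[, 2], xy[, 2], `-`)^2
    w <- exp(-d2 / smooth_theta)
    w <- w / rowSums(w)
    ok <- !apply(scores, 2, anyNA)
    scores[, ok] <- w %*% scores[, ok, drop = FALSE]
  }
  pos <- t(vapply(colnames(scores), function(nm) {
    s <- scores[, nm]
    if (all(is.na(s))) return(c(NA_real_, NA_real_))
    top <- order(-s)[seq_len(min(top_spots, length(s)))]
    w <- pmax(s[top], 0)
    if (sum(w) == 0) w <- rep(1, length(top))
    c(sum(grid$spots$x_um[top] * w) / sum(w),
      sum(grid$spots$y_um[top] * w) / sum(w))
  }, numeric(2)))
  colnames(pos) <- c("x_um", "y_um")
  get_pos <- function(cl) {
    ix <- match(cl, rownames(pos))
    cbind(pos[ix, 1], pos[ix, 2])
  }
  pl <- get_pos(pairs$ligand_cluster)
  pr <- get_pos(pairs$receiver_cluster)
  d <- sqrt((pl[, 1] - pr[, 1])^2 + (pl[, 2] - pr[, 2])^2)
  pairs$distance_um <- d
  status <- ifelse(is.na(d), "unmapped",
                   ifelse(d > max_dist_um, "excluded", "retained"))
  if (any(status == "unmapped"))
    warning(sum(status == "unmapped"),
            " pair(s) involve clusters with no scoreable signature; ",
            "kept as unmapped")
  pairs$spatial_status <- status
  attr(pairs, "max_dist_um") <- max_dist_um
  attr(pairs, "cluster_positions") <- pos
  pairs
}

#' Cluster-level NFCN connectivity scores
#'
#' Summarizes retained pairs into a ligand-cluster x receiver-cluster
#' matrix: each entry is the mean pair score of its retained pairs,
#' normalized by the matrix maximum to `[0, 1]`; entries without pairs are
#' zero. Pair counts are attached as attribute `n_pairs`.
#'
#' @param pairs A [select_connected()] (optionally spatially filtered)
#'   result.
#' @param ligand_clusters,receiver_clusters Optional cluster label sets
#'   fixing the matrix dimensions.
#' @return Numeric matrix of NFCN scores.
#' @export
nfcn_score <- function(pairs, ligand_clusters = NULL,
                       receiver_clusters = NULL) {
  keep <- pairs$spatial_status != "excluded"
  d <- pairs[keep, , drop = FALSE]
  lc <- sort(unique(c(ligand_clusters, d$ligand_cluster)))
  rc <- sort(unique(c(receiver_clusters, d$receiver_cluster)))
  scores <- matrix(0, length(lc), length(rc), dimnames = list(lc, rc))
  n_pairs <- matrix(0L, length(lc), length(rc), dimnames = list(lc, rc))
  if (nrow(d)) {
    agg_m <- tapply(d$pair_score,
                    list(factor(d$ligand_cluster, lc),
                         factor(d$receiver_cluster, rc)), mean)
    agg_n <- table(factor(d$ligand_cluster, lc),
                   factor(d$receiver_cluster, rc))
    ix <- !is.na(agg_m)
    scores[ix] <- agg_m[ix]
    n_pairs[] <- as.integer(agg_n)
    mx <- max(scores)
    if (mx > 0) scores <- scores / mx
  }
  attr(scores, "n_pairs") <- n_pairs
  scores
}

#' Precision and recall of connected pairs against planted truth
#'
#' A predicted pair is correct when its ligand cell is a planted ligand
#' carrier and its receiver a planted receptor carrier. Recall is computed
#' against the planted cross restricted to the cells that entered the
#' pairing stage (those retained by the trajectory's outlier filter on
#' their respective side), the universe the method actually ranks.
#'
#' @param pairs A [select_connected()] result (spatially `excluded` pairs,
#'   if any, are ignored).
#' @param ts The [build_interaction_trajectory()] result the pairs came from.
#' @param truth Ground truth from [generate_immune_counts()].
#' @return A list with `precision`, `recall`, `n_predicted`, `n_truth`.
#' @export
pair_recovery <- function(pairs, ts, truth) {
  keep <- pairs$spatial_status != "excluded"
  d <- pairs[keep, , drop = FALSE]
  u_l <- ts$cell[ts$side == "ligand" & ts$retained]
  u_r <- ts$cell[ts$side == "receiver" & ts$retained]
  truth_l <- intersect(truth$ligand_cells, u_l)
  truth_r <- intersect(truth$receiver_cells, u_r)
  n_truth <- length(truth_l) * length(truth_r)
  correct <- d$ligand_cell %in% truth_l & d$receiver_cell %in% truth_r
  list(
    precision = if (nrow(d)) mean(correct) else NA_real_,
    recall = if (n_truth) sum(correct) / n_truth else NA_real_,
    n_predicted = nrow(d), n_truth = n_truth
  )
}
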