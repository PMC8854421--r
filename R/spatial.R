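#' Spatial spot grid container
#'
#' Light container for a rectangular spot array: a spot table with 0-based
#' array coordinates and micrometer positions, a spot x gene count matrix,
#' and the grid geometry.
#'
#' @param spots Data frame with at least `spot`, `row`, `col`, `x_um`,
#'   `y_um`; coordinates must be unique.
#' @param counts Spot x gene matrix, rows matching `spots$spot`.
#' @param pitch_um Center-to-center spot distance, > 0.
#' @param n_rows,n_cols Grid extent (defaults to the coordinate range).
#' @return A list of class `spatial_grid`.
#' @export
spatial_grid <- function(spots, counts, pitch_um,
                         n_rows = max(spots$row) + 1L,
                         n_cols = max(spots$col) + 1L) {
  need <- c("spot", "row", "col", "x_um", "y_um")
  if (!all(need %in% names(spots)))
    stop("spots must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(spots[, c("row", "col")]))
    stop("duplicate spot coordinates")
  if (pitch_um <= 0) stop("pitch must be positive")
  if (n_rows <= max(spots$row) || n_cols <= max(spots$col))
    stop("grid extent does not cover all spots")
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(spots))
    stop("counts rows must match spots")
  rownames(counts) <- spots$spot
  structure(list(spots = spots, counts = counts, pitch_um = pitch_um,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "spatial_grid")
}

#' Smoothed surface matrix over the grid extent
#'
#' Renders a per-spot value field as a dense `n_rows x n_cols` matrix.
#' Covered positions hold a distance-weighted average of all covered spots
#' with weights `exp(-d^2 / theta)` (squared micrometer distance divided by
#' the threshold `theta`), row-normalized so the result at each position is
#' a convex combination of the input; positions without a spot are zero.
#'
#' @param grid A [spatial_grid()].
#' @param values Per-spot numeric values (order of `grid$spots`).
#' @param theta Positive smoothing threshold; default `pitch_um^2`, so
#'   weights fall to `1/e` one pitch away.
#' @return Dense `n_rows x n_cols` matrix.
#' @export
surface_matrix <- function(grid, values, theta = grid$pitch_um^2) {
  stopifnot(inherits(grid, "spatial_grid"))
  if (theta <= 0) stop("theta must be positive")
  if (length(values) != nrow(grid$spots))
    stop("one value per spot required")
  if (any(!is.finite(values))) stop("values must be finite")
  xy <- cbind(grid$spots$x_um, grid$spots$y_um)
  d2 <- outer(xy[, 1], xy[, 1], `-`)^2 + outer(xy[, 2], xy[, 2], `-`)^2
  w <- exp(-d2 / theta)
  sm <- as.vector(w %*% values) / rowSums(w)
  out <- matrix(0, grid$n_rows, grid$n_cols)
  out[cbind(grid$spots$row + 1L, grid$spots$col + 1L)] <- sm
  out
}

#' Two-dimensional cellular state coordinates from four program scores
#'
#' Places each spot in a 2D state representation from four gene-set scores
#' (each min-max normalized to `[0, 1]`). The vertical axis contrasts the
#' two program pairs, `A1 = max(GS1, GS2) - max(GS3, GS4)`; the horizontal
#' axis separates within the winning pair with a signed compressed
#' difference, `A2 = sign(d) * log2(|d| + 1)` where `d = GS1 - GS2` for
#' `A1 > 0` and `d = GS3 - GS4` otherwise. A color value in `[0, 1]` is
#' derived from a location-scale (normal) fit to the winning score,
#' centered at its 0.5 quantile. Continuity across the `A1 = 0` branch
#' switch is not guaranteed.
#'
#' @param gs Spot x 4 matrix or data.frame of scores in `[0, 1]`
#'   (columns GS1..GS4).
#' @return Data frame with `A1`, `A2`, `color`.
#' @export
state_coordinates <- function(gs) {
  gs <- as.matrix(gs)
  if (ncol(gs) != 4) stop("exactly four gene-set scores required")
  if (anyNA(gs)) stop("missing score")
  if (any(gs < -1e-9 | gs > 1 + 1e-9))
    stop("scores must be min-max normalized to [0, 1]")
  a1 <- pmax(gs[, 1], gs[, 2]) - pmax(gs[, 3], gs[, 4])
  d <- ifelse(a1 > 0, gs[, 1] - gs[, 2], gs[, 3] - gs[, 4])
  a2 <- sign(d) * log2(abs(d) + 1)
  chosen <- ifelse(a1 > 0, pmax(gs[, 1], gs[, 2]), pmax(gs[, 3], gs[, 4]))
  s <- sd(chosen)
  color <- if (is.na(s) || s == 0) rep(0.5, length(chosen))
           else pnorm((chosen - median(chosen)) / s)
  data.frame(A1 = a1, A2 = a2, color = color)
}

# adjacency weight matrix for grid spots (rook or queen), row-standardized
.grid_weights <- function(grid, scheme) {
  r <- grid$spots$row
  c <- grid$spots$col
  dr <- abs(outer(r, r, `-`))
  dc <- abs(outer(c, c, `-`))
  w <- if (scheme == "rook") (dr + dc) == 1
       else (pmax(dr, dc) == 1)
  w <- w * 1
  diag(w) <- 0
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  w / rs
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' `I = (n / sum(W)) * (sum_ij w_ij z_i z_j) / (sum_i z_i^2)` on centered
#' values with row-standardized rook or queen adjacency over the spot
#' array, and a permutation p-value from randomly relabelling values over
#' spots.
#'
#' @param values Per-spot numeric values (non-constant, >= 5 spots).
#' @param grid A [spatial_grid()].
#' @param scheme Neighborhood scheme, `"queen"` (default) or `"rook"`.
#' @param n_perm Number of permutations (default 999).
#' @param alternative `"greater"`, `"less"` or `"two.sided"` (default).
#' @param seed Seed for the permutations.
#' @return A list with `I`, `p_value`, `n_perm`, `alternative`.
#' @export
morans_i <- function(values, grid, scheme = c("queen", "rook"),
                     n_perm = 999, alternative = c("two.sided", "greater", "less"),
                     seed = 1L) {
  scheme <- match.arg(scheme)
  alternative <- match.arg(alternative)
  stopifnot(inherits(grid, "spatial_grid"))
  n <- length(values)
  if (n != nrow(grid$spots)) stop("one value per spot required")
  if (n < 5) stop("need at least 5 spots")
  if (sd(values) == 0) stop("constant field: Moran's I is undefined")
  w <- .grid_weights(grid, scheme)
  stat <- function(v) {
    z <- v - mean(v)
    (n / sum(w)) * as.numeric(z %*% w %*% z) / sum(z^2)
  }
  i_obs <- stat(values)
  set.seed(seed)
  perm <- replicate(n_perm, stat(sample(values)))
  p <- switch(alternative,
    greater = (1 + sum(perm >= i_obs)) / (n_perm + 1),
    less = (1 + sum(perm <= i_obs)) / (n_perm + 1),
    two.sided = (1 + sum(abs(perm - mean(perm)) >= abs(i_obs - mean(perm)))) /
      (n_perm + 1)
  )
  list(I = i_obs, p_value = p, n_perm = n_perm, alternative = alternative)
}

#' Distance profile from a target signature to a reference niche
#'
#' Scores every spot for the target and reference signatures, converts the
#' target score to a rank-normalized probability in `[0, 1]`, defines the
#' reference niche as the top decile of reference enrichment, and reports
#' the mean micrometer distance to the nearest niche spot per target
#' probability bin. A decreasing curve means high-probability target spots
#' sit close to the reference niche.
#'
#' @param grid A [spatial_grid()].
#' @param target_signature,reference_signature Gene id vectors.
#' @param n_bins Number of equal-width probability bins (default 20).
#' @return Data frame with `bin`, `prob_mid`, `mean_dist_um`, `n_spots`
#'   (bins without spots are NA).
#' @export
distance_profile <- function(grid, target_signature, reference_signature,
                             n_bins = 20) {
  stopifnot(inherits(grid, "spatial_grid"))
  sc <- spot_signature_scores(grid, list(target = target_signature,
                                         reference = reference_signature))
  if (all(is.na(sc[, "reference"]))) stop("reference signature not scoreable")
  if (all(is.na(sc[, "target"]))) stop("target signature not scoreable")
  ref <- sc[, "reference"]
  top <- ref >= quantile(ref, 0.9, names = FALSE)
  if (!any(top)) stop("reference top decile is empty")
  xy <- cbind(grid$spots$x_um, grid$spots$y_um)
  ref_xy <- xy[top, , drop = FALSE]
  d <- apply(xy, 1, function(p)
    sqrt(min((p[1] - ref_xy[, 1])^2 + (p[2] - ref_xy[, 2])^2)))
  prob <- (rank(sc[, "target"], ties.method = "average") - 1) /
    (nrow(sc) - 1)
  bin <- pmin(floor(prob * n_bins) + 1L, n_bins)
  mean_dist <- tapply(d, factor(bin, levels = seq_len(n_bins)), mean)
  data.frame(
    bin = seq_len(n_bins),
    prob_mid = (seq_len(n_bins) - 0.5) / n_bins,
    mean_dist_um = as.numeric(mean_dist),
    n_spots = as.integer(table(factor(bin, levels = seq_len(n_bins))))
  )
}

#' Per-spot density of retained connected pairs
#'
#' Projects the connected pairs onto the array as a connectivity map: each
#' pair not excluded by the proximity filter contributes its pair score
#' times the product of its ligand-cluster and receiver-cluster signature
#' enrichments at every spot, so density accumulates where both partners
#' of a connection are co-enriched.
#'
#' @param pairs A [spatial_proximity_filter()] result.
#' @param grid The [spatial_grid()] used for the filtering.
#' @param signatures Named list of cluster signature gene sets (as passed
#'   to [spatial_proximity_filter()]).
#' @return Numeric per-spot connection density, named by spot id.
#' @export
pair_density <- function(pairs, grid, signatures) {
  stopifnot(inherits(grid, "spatial_grid"))
  d <- pairs[pairs$spatial_status != "excluded", , drop = FALSE]
  out <- setNames(numeric(nrow(grid$spots)), grid$spots$spot)
  if (!nrow(d)) return(out)
  scores <- spot_signature_scores(grid, signatures)
  agg <- stats::aggregate(pair_score ~ ligand_cluster + receiver_cluster,
                          data = d, FUN = sum)
  for (i in seq_len(nrow(agg))) {
    sl <- scores[, agg$ligand_cluster[i]]
    sr <- scores[, agg$receiver_cluster[i]]
    if (all(is.na(sl)) || all(is.na(sr))) next
    out <- out + agg$pair_score[i] * pmax(sl, 0) * pmax(sr, 0)
  }
  out
}
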