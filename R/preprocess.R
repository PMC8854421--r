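#' CP10K log-normalization
#'
#' Scales each cell to `scale` total counts and applies a natural-log
#' `log(1 + x)` transform, the standard counts-per-10k normalization. For
#' every non-empty cell the transform conserves
#' `sum(expm1(column)) == scale` exactly.
#'
#' @param counts Non-negative gene x cell raw counts (matrix or Matrix).
#' @param scale Per-cell scale factor (default 10,000).
#' @return A dense gene x cell matrix of log-normalized expression.
#'   All-zero cells are left at zero with a warning.
#' @export
lognormalize <- function(counts, scale = 10000) {
  m <- as.matrix(counts)
  if (any(m < 0)) stop("counts must be non-negative")
  totals <- colSums(m)
  empty <- totals == 0
  if (all(empty)) stop("no nonzero cells")
  if (any(empty))
    warning(sum(empty), " all-zero cell(s) left at zero")
  totals[empty] <- 1
  log1p(sweep(m, 2, scale / totals, `*`))
}

#' Select highly variable genes
#'
#' Ranks genes by a variance-stabilized dispersion statistic: per-gene
#' variance of log-normalized expression divided by a loess-fitted
#' mean-variance trend, so genes are compared against others of similar
#' abundance. Ties are broken by gene id for a fully deterministic ranking.
#'
#' @param m Gene x cell log-normalized matrix with gene rownames.
#' @param n Number of genes to return (default 2000).
#' @return Character vector of the top `n` gene ids, most variable first.
#' @export
select_variable_genes <- function(m, n = 2000) {
  m <- as.matrix(m)
  if (n > nrow(m)) stop("n (", n, ") exceeds number of genes (", nrow(m), ")")
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  score <- numeric(nrow(m))
  ok <- v > 0 & mu > 0
  if (sum(ok) >= 10) {
    fit <- loess(log10(v[ok]) ~ log10(mu[ok]), span = 0.5, degree = 2)
    expected <- 10^predict(fit)
    score[ok] <- v[ok] / pmax(expected, .Machine$double.eps)
  } else {
    score[ok] <- v[ok]
  }
  ord <- order(-score, rownames(m))
  rownames(m)[ord][seq_len(n)]
}

#' Regress out covariates and z-score genes
#'
#' Fits per-gene ordinary least squares against the supplied per-cell
#' covariates (e.g. batch, mitochondrial and ribosomal content), takes
#' residuals, and standardizes each gene to mean 0, sd 1. Residuals are
#' exactly orthogonal to the covariate design. Genes with zero residual
#' variance are set to 0 rather than NaN.
#'
#' @param m Gene x cell log-normalized matrix.
#' @param covariates Data frame with one row per cell (same order as the
#'   matrix columns); factors are expanded to indicators.
#' @return Gene x cell matrix of scaled residuals.
#' @export
regress_and_scale <- function(m, covariates) {
  m <- as.matrix(m)
  s_in <- sqrt(pmax(rowSums(sweep(m, 1, rowMeans(m))^2), 0) / (ncol(m) - 1))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != ncol(m))
      stop("covariates must have one row per cell")
    if (any(!complete.cases(covariates)))
      stop("covariates contain missing values")
    keep <- vapply(covariates, function(x)
      length(unique(x)) > 1, logical(1))
    if (any(keep)) {
      X <- model.matrix(~., data = covariates[, keep, drop = FALSE])
      qr_x <- qr(X)
      m <- t(qr.resid(qr_x, t(m)))
    } else {
      m <- sweep(m, 1, rowMeans(m))
    }
  } else {
    m <- sweep(m, 1, rowMeans(m))
  }
  s <- sqrt(rowSums(m^2) / (ncol(m) - 1))
  # genes fully explained by the covariates (or constant) carry only
  # numerical noise in their residuals: zero them instead of inflating
  explained <- s <= pmax(1e-8 * s_in, 1e-12)
  out <- m / ifelse(explained, Inf, s)
  out[explained, ] <- 0
  out - rowMeans(out)
}

#' Number of nontrivial principal components by parallel analysis
#'
#' Compares the leading eigenvalues of the expression covariance against the
#' 95th percentile of eigenvalues obtained after independently permuting each
#' gene across cells (Horn-style parallel analysis). The count of leading
#' observed eigenvalues exceeding their permutation threshold is the number
#' of components carrying structure beyond chance.
#'
#' @param m Gene x cell scaled matrix.
#' @param n_max Maximum number of components examined (default 100).
#' @param n_perm Number of per-gene permutations (default 20).
#' @param quantile_cut Percentile of the permuted eigenvalues (default 0.95).
#' @param seed Seed for the permutations.
#' @return Integer `k`, `1 <= k <= n_max`.
#' @export
nontrivial_components <- function(m, n_max = 100, n_perm = 20,
                                  quantile_cut = 0.95, seed = 1L) {
  m <- as.matrix(m)
  n_max <- min(n_max, min(dim(m)) - 1)
  if (n_max < 1) stop("matrix too small for component analysis")
  if (qr(m)$rank < 2) stop("degenerate matrix: rank < 2")
  eig <- function(x) {
    d <- svd(x, nu = 0, nv = 0)$d
    (d^2 / (ncol(x) - 1))[seq_len(n_max)]
  }
  obs <- eig(m)
  set.seed(seed)
  perm <- matrix(0, n_perm, n_max)
  for (p in seq_len(n_perm)) {
    mp <- m
    for (g in seq_len(nrow(m))) mp[g, ] <- mp[g, sample.int(ncol(m))]
    perm[p, ] <- eig(mp)
  }
  thresh <- apply(perm, 2, quantile, probs = quantile_cut)
  above <- obs > thresh
  k <- if (above[1]) {
    run <- which(!above)
    if (length(run)) run[1] - 1L else n_max
  } else 1L
  max(1L, min(k, n_max))
}

#' Shared-nearest-neighbor graph clustering
#'
#' Builds a k-nearest-neighbor graph on the embedding, reweights edges by
#' the Jaccard overlap of neighborhoods (shared nearest neighbors), prunes
#' weak overlaps, and partitions the graph by Louvain modularity
#' optimization at the given resolution. Deterministic given the seed.
#'
#' @param embedding Cell x dimension numeric matrix.
#' @param k_neighbors Neighborhood size (default 20).
#' @param resolution Modularity resolution (default 0.8).
#' @param prune Jaccard pruning threshold (default 1/15).
#' @param seed Seed for the community detection.
#' @return Integer cluster labels, named by the embedding rownames.
#' @export
snn_cluster <- function(embedding, k_neighbors = 20, resolution = 0.8,
                        prune = 1 / 15, seed = 1L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (ncol(embedding) < 1) stop("embedding needs >= 1 dimension")
  if (n <= k_neighbors) stop("fewer cells than k_neighbors")
  # canonicalize cell order so the result is equivariant under permutation
  input_names <- rownames(embedding)
  if (!is.null(input_names) && !anyDuplicated(input_names)) {
    ord <- order(input_names)
    embedding <- embedding[ord, , drop = FALSE]
  } else {
    ord <- seq_len(n)
  }
  d <- as.matrix(dist(embedding))
  nn <- matrix(0L, n, k_neighbors)
  for (i in seq_len(n)) {
    nbr <- order(d[i, ], decreasing = FALSE)
    nbr <- nbr[nbr != i]
    nn[i, ] <- nbr[seq_len(k_neighbors)]
  }
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k_neighbors),
    j = as.vector(t(nn)), x = 1, dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(A)           # counts of shared neighbors
  shared <- methods::as(shared, "TsparseMatrix")
  ii <- shared@i + 1L
  jj <- shared@j + 1L
  keep <- ii < jj
  ii <- ii[keep]; jj <- jj[keep]
  sh <- shared@x[keep]
  jac <- sh / (2 * k_neighbors - sh)
  ok <- jac >= prune
  if (!any(ok)) stop("SNN graph has no edges; increase k_neighbors")
  g <- igraph::graph_from_data_frame(
    data.frame(from = ii[ok], to = jj[ok], weight = jac[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- igraph::membership(comm)[as.character(seq_len(n))]
  out <- integer(n)
  out[ord] <- as.integer(labels)
  names(out)[ord] <- rownames(embedding)
  out
}

#' SVD gene-set enrichment score per cell
#'
#' Scores each cell's activity of a gene set as the coefficients of the
#' first right-singular vector of the member-gene submatrix, the dominant
#' shared expression pattern of the set across cells. The SVD's arbitrary
#' sign is pinned so the score correlates non-negatively with the mean
#' member expression (so negating the whole matrix flips the raw score
#' exactly), and the unit-norm vector is min-max rescaled to `[0, 1]`
#' (set `rescale = FALSE` for the raw oriented vector).
#'
#' @param m Gene x cell scaled expression matrix with gene rownames.
#' @param gene_set Character vector of member gene ids (>= 2 must be
#'   present in the matrix).
#' @param rescale Min-max rescale to `[0, 1]` (default TRUE).
#' @return Numeric per-cell scores, named by cell.
#' @export
svd_enrichment <- function(m, gene_set, rescale = TRUE) {
  m <- as.matrix(m)
  present <- intersect(gene_set, rownames(m))
  if (length(present) < 2) {
    missing <- setdiff(gene_set, rownames(m))
    stop("gene set has ", length(present), " member(s) in the matrix ",
         "(need >= 2); missing: ",
         paste(head(missing, 10), collapse = ", "))
  }
  sub <- m[present, , drop = FALSE]
  sv <- svd(sub, nu = 0, nv = 1)
  v <- sv$v[, 1]
  # pin the SVD's arbitrary sign: the score must rise with mean member
  # expression (consequently, negating the whole matrix flips the raw
  # score exactly — the orientation tracks the data, not the decomposition)
  if (sum(v * colMeans(sub)) < 0) v <- -v
  names(v) <- colnames(m)
  if (!rescale) return(v)
  rng <- range(v)
  if (rng[2] - rng[1] <= 0) return(setNames(rep(0, length(v)), colnames(m)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Central quantile retention filter
#'
#' Retains the cells whose scores fall inside the central `q` probability
#' mass of the empirical distribution, i.e. between the `(1-q)/2` and
#' `(1+q)/2` empirical quantiles (two-sided; both tails, including the top
#' tail, are rejected as outliers before any min-max normalization).
#'
#' @param scores Numeric per-cell scores.
#' @param q Central mass retained (default 0.95).
#' @return Logical retention mask, same length and names as `scores`.
#' @export
quantile_filter <- function(scores, q = 0.95) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (length(scores) < 10) {
    warning("fewer than 10 cells; no quantile filtering applied")
    return(setNames(rep(TRUE, length(scores)), names(scores)))
  }
  lo <- quantile(scores, (1 - q) / 2, names = FALSE)
  hi <- quantile(scores, (1 + q) / 2, names = FALSE)
  mask <- scores >= lo & scores <= hi
  names(mask) <- names(scores)
  mask
}
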