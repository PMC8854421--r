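#' Relative expression against a non-malignant reference, clipped
#'
#' Subtracts the per-gene mean over the reference cells from every cell's
#' log-normalized expression and clamps the result to `[-clip, clip]`, so
#' individual highly expressed genes cannot dominate the downstream moving
#' average.
#'
#' @param m Gene x cell log-normalized matrix.
#' @param reference_cells Cell ids of the non-malignant reference
#'   (>= 10 present in the matrix).
#' @param clip Symmetric clamp bound (default 2.6).
#' @return Gene x cell matrix of clipped relative expression.
#' @export
clip_relative_expression <- function(m, reference_cells, clip = 2.6) {
  m <- as.matrix(m)
  ref <- intersect(reference_cells, colnames(m))
  if (!length(ref)) stop("reference cells not found in the matrix")
  if (length(ref) < 10) stop("need at least 10 reference cells")
  rel <- m - rowMeans(m[, ref, drop = FALSE])
  pmin(pmax(rel, -clip), clip)
}

#' Moving-average copy-number estimate along the genome
#'
#' Sorts genes by genomic position, then smooths each cell's relative
#' expression with a centered sliding window of `window` genes that never
#' crosses a chromosome boundary (windows shrink at chromosome ends;
#' chromosomes with fewer genes than the window use all their genes), and
#' optionally re-centers each cell by its median smoothed value. Sustained
#' positive or negative stretches indicate chromosomal gains or losses.
#'
#' @param rel Gene x cell clipped relative expression from
#'   [clip_relative_expression()].
#' @param annotation Data frame with `gene`, `chrom`, `start` (0-based);
#'   genes absent from it are dropped.
#' @param window Window size in genes (default 100).
#' @param recenter Subtract the per-cell median after smoothing
#'   (default TRUE).
#' @param chrom_order Optional chromosome ordering; defaults to the order
#'   of first appearance in `annotation`.
#' @return A list of class `cnv_matrix` with `values` (gene-window x cell
#'   matrix, rows in genomic order), `windows` (`gene`, `chrom`, `start`)
#'   and `params`.
#' @export
moving_average_cnv <- function(rel, annotation, window = 100,
                               recenter = TRUE, chrom_order = NULL) {
  rel <- as.matrix(rel)
  ann <- annotation[annotation$gene %in% rownames(rel), , drop = FALSE]
  if (!nrow(ann)) stop("no annotated genes in the matrix")
  if (is.null(chrom_order)) chrom_order <- unique(annotation$chrom)
  ann$chrom <- factor(ann$chrom, levels = chrom_order)
  ord <- order(as.integer(ann$chrom), ann$start, ann$gene)
  ann <- ann[ord, , drop = FALSE]
  x <- rel[ann$gene, , drop = FALSE]

  half_lo <- floor(window / 2)
  half_hi <- window - half_lo - 1L
  out <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  for (ch in levels(droplevels(ann$chrom))) {
    ix <- which(ann$chrom == ch)
    n <- length(ix)
    cs <- apply(x[ix, , drop = FALSE], 2, cumsum)
    cs <- rbind(0, cs)
    lo <- pmax(seq_len(n) - half_lo, 1L)
    hi <- pmin(seq_len(n) + half_hi, n)
    out[ix, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
  }
  if (recenter) out <- sweep(out, 2, apply(out, 2, median))
  structure(list(
    values = out,
    windows = data.frame(gene = ann$gene, chrom = as.character(ann$chrom),
                         start = ann$start, stringsAsFactors = FALSE),
    params = list(window = window, recenter = recenter)
  ), class = "cnv_matrix")
}

#' Sample non-malignant reference cells
#'
#' Draws up to `n` cells from the marker-defined eligible population (e.g.
#' CD8+ T cells, unlikely to carry tumor copy-number changes); returns all
#' eligible cells with a warning when fewer than `n` pass, and errors when
#' the eligible population is below `n / 2`.
#'
#' @param cells Character vector of cell ids.
#' @param eligible Logical vector (parallel to `cells`) or character subset
#'   selecting the candidate reference cells.
#' @param n Reference size (default 400).
#' @param seed Seed for the sampling.
#' @return Character vector of reference cell ids.
#' @export
call_reference_cells <- function(cells, eligible, n = 400, seed = 1L) {
  pass <- if (is.logical(eligible)) {
    stopifnot(length(eligible) == length(cells))
    cells[eligible]
  } else intersect(cells, eligible)
  if (!length(pass)) stop("no cells pass the reference predicate")
  if (length(pass) < n / 2)
    stop("only ", length(pass), " cells pass the reference predicate ",
         "(need at least n/2 = ", n / 2, ")")
  if (length(pass) <= n) {
    if (length(pass) < n)
      warning("only ", length(pass), " eligible cells; returning all")
    return(pass)
  }
  set.seed(seed)
  sort(pass[sample.int(length(pass), n)])
}
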