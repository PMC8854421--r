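#' Read a gene-set collection in GMT format
#'
#' @param path Path to a tab-separated GMT file
#'   (`name <tab> description <tab> gene1 <tab> gene2 ...`).
#' @return Named list of gene id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' Write a gene-set collection in GMT format
#'
#' @param gene_sets Named list of gene id vectors.
#' @param path Output path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Write a synthetic dataset to standard on-disk formats
#'
#' Writes the count matrix as MatrixMarket triplets with gene and barcode
#' sidecars, a cell annotation table, the spot coordinate table, the
#' planted gene programs as GMT, the gene position table (BED-like) and a
#' JSON ground-truth sidecar.
#'
#' @param counts Gene x cell count matrix.
#' @param truth Ground truth from [generate_immune_counts()].
#' @param dir Output directory (created if missing).
#' @param grid Optional [spatial_grid()].
#' @param positions Optional gene position table.
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(counts, truth, dir, grid = NULL,
                                    positions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                    "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  ann <- data.frame(cell = names(truth$cell_labels),
                    cluster = unname(truth$cell_labels),
                    batch = unname(truth$batch[names(truth$cell_labels)]),
                    stringsAsFactors = FALSE)
  write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gmt(truth$program_gene_members, file.path(dir, "programs.gmt"))
  if (!is.null(grid)) {
    write.table(grid$spots, file.path(dir, "spots.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(grid$counts, file.path(dir, "spot_counts.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
  }
  if (!is.null(positions))
    write.table(positions[, c("chrom", "start", "end", "gene")],
                file.path(dir, "gene_positions.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  sidecar <- list(
    cell_labels = as.list(truth$cell_labels),
    ligand_cells = truth$ligand_cells,
    receiver_cells = truth$receiver_cells
  )
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a MatrixMarket count matrix with gene/barcode sidecars
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return A sparse gene x cell `dgCMatrix`.
#' @export
read_counts_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}
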