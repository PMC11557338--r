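# Expression-matrix quality control around the demultiplexing step: the
# standard detected-gene filters, cross-genotype doublet removal, and
# depth normalization with log1p. Matrices are genes x cells.

#' Filter cells and genes by detection thresholds
#'
#' Cells detecting fewer than `min_genes_per_cell` genes or more than
#' `max_genes_per_cell` genes are removed (boundaries kept: a cell with
#' exactly `min_genes_per_cell` or exactly `max_genes_per_cell` detected
#' genes survives); then genes detected in fewer than `min_cells_per_gene`
#' of the surviving cells are removed. "Detected" means nonzero count.
#' Cell filtering precedes gene filtering; surviving rows/columns keep
#' their order.
#'
#' @param matrix Non-negative genes x cells count matrix.
#' @param min_genes_per_cell,max_genes_per_cell Detected-gene bounds per
#'   cell (defaults 200 and 4000).
#' @param min_cells_per_gene Minimum cells a gene must be detected in
#'   (default 3).
#' @return A list: `matrix` (filtered), `report` (tibble `n_cells_removed`,
#'   `n_genes_removed`, `n_cells_kept`, `n_genes_kept`).
#' @export
filter_cells_genes <- function(matrix, min_genes_per_cell = 200L,
                               max_genes_per_cell = 4000L,
                               min_cells_per_gene = 3L) {
  if (min_genes_per_cell >= max_genes_per_cell) {
    abort("min_genes_per_cell must be below max_genes_per_cell")
  }
  if (any(matrix < 0)) abort("matrix must be non-negative")
  genes_per_cell <- Matrix::colSums(matrix > 0)
  keep_cells <- genes_per_cell >= min_genes_per_cell &
    genes_per_cell <= max_genes_per_cell
  m <- matrix[, keep_cells, drop = FALSE]
  cells_per_gene <- Matrix::rowSums(m > 0)
  keep_genes <- cells_per_gene >= min_cells_per_gene
  out <- m[keep_genes, , drop = FALSE]
  list(
    matrix = out,
    report = tibble(
      n_cells_removed = sum(!keep_cells),
      n_genes_removed = sum(!keep_genes),
      n_cells_kept = ncol(out),
      n_genes_kept = nrow(out)
    )
  )
}

#' Remove cross-genotype doublets from an expression matrix
#'
#' Drops every barcode whose demultiplexing status is `doublet`; singlets
#' and unassigned cells are retained, in their original order.
#'
#' @param matrix Genes x cells matrix with barcodes as colnames.
#' @param assignment Assignment tibble with `barcode` and `status` covering
#'   every column of `matrix`.
#' @return The filtered matrix.
#' @export
remove_cross_genotype_doublets <- function(matrix, assignment) {
  missing <- setdiff(colnames(matrix), assignment$barcode)
  if (length(missing)) {
    abort(sprintf("assignment missing %d barcode(s) present in the matrix", length(missing)))
  }
  status <- assignment$status[match(colnames(matrix), assignment$barcode)]
  matrix[, status != "doublet", drop = FALSE]
}

#' Depth-normalize and log-transform an expression matrix
#'
#' Scales each cell's counts to sum to `target_sum`, then applies
#' `log(x + 1)` elementwise. All-zero cells pass through unchanged.
#'
#' @param matrix Non-negative genes x cells matrix.
#' @param target_sum Per-cell total after scaling (default 10000).
#' @return The normalized matrix (dense or sparse, matching the input).
#' @export
normalize_log1p <- function(matrix, target_sum = 10000) {
  if (any(matrix < 0)) abort("matrix must be non-negative")
  totals <- Matrix::colSums(matrix)
  scale <- ifelse(totals > 0, target_sum / totals, 0)
  scaled <- matrix %*% Matrix::Diagonal(x = scale)
  colnames(scaled) <- colnames(matrix)
  out <- scaled
  out@x <- log1p(out@x)
  out
}
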