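#' Single-cell perturbation dataset container
#'
#' A light container pairing a sparse genes x cells UMI matrix, a sparse
#' guides x cells capture UMI matrix and a per-cell metadata tibble (columns
#' `barcode`, `condition`, `lane`, plus anything downstream steps add, e.g.
#' `guide` after assignment). Columns of both matrices are aligned to the
#' metadata rows by barcode.
#'
#' @param counts sparse (or dense) genes x cells UMI matrix with gene
#'   rownames and barcode colnames.
#' @param guides guides x cells capture UMI matrix, columns aligned with
#'   `counts`; may be `NULL` for expression-only data.
#' @param cells per-cell metadata tibble with a unique `barcode` column
#'   matching `colnames(counts)`.
#' @return a `cell_dataset` object.
#' @export
cell_dataset <- function(counts, guides = NULL, cells = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(colnames(counts))) abort("counts must have barcode colnames")
  if (is.null(cells)) {
    cells <- tibble(barcode = colnames(counts))
  }
  if (!"barcode" %in% names(cells)) abort("cells metadata needs a 'barcode' column")
  if (anyDuplicated(cells$barcode)) abort("cell barcodes must be unique")
  if (!identical(colnames(counts), cells$barcode)) {
    if (!setequal(colnames(counts), cells$barcode)) {
      abort("counts colnames and cells$barcode differ")
    }
    counts <- counts[, cells$barcode, drop = FALSE]
  }
  if (!is.null(guides)) {
    guides <- methods::as(methods::as(guides, "CsparseMatrix"), "dMatrix")
    if (is.null(colnames(guides))) colnames(guides) <- colnames(counts)
    if (!identical(colnames(guides), cells$barcode)) {
      if (!setequal(colnames(guides), cells$barcode)) {
        abort("guide matrix columns do not align with cell barcodes")
      }
      guides <- guides[, cells$barcode, drop = FALSE]
    }
  }
  if (any(counts@x < 0)) abort("UMI counts must be nonnegative")
  structure(
    list(counts = counts, guides = guides, cells = as_tibble(cells)),
    class = "cell_dataset"
  )
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf(
    "<cell_dataset> %d genes x %d cells%s\n",
    nrow(x$counts), ncol(x$counts),
    if (is.null(x$guides)) "" else sprintf(", %d guides captured", nrow(x$guides))
  ))
  invisible(x)
}

#' @export
dim.cell_dataset <- function(x) dim(x$counts)

# subset a cell_dataset to a barcode vector, preserving order
subset_cells <- function(ds, barcodes) {
  cell_dataset(
    counts = ds$counts[, barcodes, drop = FALSE],
    guides = if (is.null(ds$guides)) NULL else ds$guides[, barcodes, drop = FALSE],
    cells = ds$cells[match(barcodes, ds$cells$barcode), , drop = FALSE]
  )
}

# counts-per-scale normalisation of a sparse matrix (columns = cells)
normalize_cells <- function(m, scale = 1e4) {
  totals <- Matrix::colSums(m)
  totals[totals == 0] <- 1
  m %*% Matrix::Diagonal(x = scale / totals)
}
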