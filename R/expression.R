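#' Expression matrix container
#'
#' Bundles a raw count layer with an optional log-normalized layer. Both
#' layers are genes x cells matrices (dense or [Matrix::Matrix] sparse) with
#' unique gene symbols as rownames and unique cell ids as colnames.
#'
#' @param counts genes x cells matrix of non-negative integer counts with
#'   unique dimnames.
#' @param lognorm optional genes x cells matrix of log-normalized expression,
#'   same dimnames as `counts`.
#' @return An object of class `ptx_expr`: a list with elements `counts` and
#'   `lognorm` (possibly `NULL`).
#' @export
expression_matrix <- function(counts, lognorm = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in `counts`")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids in `counts`")
  if (min_value(counts) < 0) stop("`counts` must be non-negative")
  if (!is.null(lognorm) && !identical(dim(lognorm), dim(counts))) {
    stop("`lognorm` must have the same shape as `counts`")
  }
  structure(list(counts = counts, lognorm = lognorm), class = "ptx_expr")
}

min_value <- function(m) {
  if (inherits(m, "sparseMatrix")) min(0, min(m@x, Inf)) else min(m)
}

#' @export
print.ptx_expr <- function(x, ...) {
  cat(sprintf(
    "<ptx_expr> %d genes x %d cells (%s lognorm layer)\n",
    nrow(x$counts), ncol(x$counts),
    if (is.null(x$lognorm)) "no" else "with"
  ))
  invisible(x)
}

#' @export
dim.ptx_expr <- function(x) dim(x$counts)

gene_ids <- function(x) rownames(x$counts)
cell_ids <- function(x) colnames(x$counts)

#' Per-cell log-normalization of counts
#'
#' Scales each cell's counts to a common library size and applies `log1p`:
#' for a count `k` in a cell with total `T`, the normalized value is
#' `log1p(k * scale / T)`. Zeros stay exactly zero and the count layer is
#' left untouched.
#'
#' @param x a `ptx_expr` object (see [expression_matrix()]) or a bare
#'   genes x cells count matrix.
#' @param scale target library size; default `1e4` counts per cell.
#' @return The input as a `ptx_expr` with the `lognorm` layer filled in.
#' @export
log_normalize <- function(x, scale = 1e4) {
  if (!inherits(x, "ptx_expr")) x <- expression_matrix(x)
  totals <- Matrix::colSums(x$counts)
  if (any(totals <= 0)) {
    bad <- colnames(x$counts)[which(totals <= 0)]
    stop("all-zero cell(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (inherits(x$counts, "sparseMatrix")) {
    ln <- methods::as(x$counts, "CsparseMatrix")
    # scale column j by scale/totals[j]; @x is ordered by column
    ncol_rep <- diff(ln@p)
    ln@x <- log1p(ln@x * rep(scale / totals, ncol_rep))
  } else {
    ln <- log1p(sweep(x$counts, 2, scale / totals, `*`))
  }
  x$lognorm <- ln
  x
}

lognorm_layer <- function(x) {
  if (is.null(x$lognorm)) stop("no lognorm layer; call log_normalize() first")
  x$lognorm
}

#' Read a count matrix from disk
#'
#' Accepts either a CellRanger-style directory (`matrix.mtx`, `barcodes.tsv`,
#' `features.tsv`/`genes.tsv`) or a dense delimited table of cells x genes or
#' genes x cells (`orientation`).
#'
#' @param path directory with MTX triplet files, or a single TSV/CSV file.
#' @param orientation for dense tables: `"genes_x_cells"` (default) or
#'   `"cells_x_genes"`.
#' @return A `ptx_expr` object with the counts layer set.
#' @export
read_counts <- function(path, orientation = c("genes_x_cells", "cells_x_genes")) {
  orientation <- match.arg(orientation)
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    feat <- Filter(file.exists, file.path(path, c("features.tsv", "genes.tsv")))[1]
    bc <- file.path(path, "barcodes.tsv")
    if (!file.exists(mtx) || is.na(feat) || !file.exists(bc)) {
      stop("expected matrix.mtx + features.tsv/genes.tsv + barcodes.tsv in ", path)
    }
    m <- Matrix::readMM(mtx)
    features <- utils::read.table(feat, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)
    barcodes <- utils::read.table(bc, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    sym_col <- if (ncol(features) >= 2) 2L else 1L
    rownames(m) <- make.unique(features[[sym_col]])
    colnames(m) <- barcodes
    return(expression_matrix(m))
  }
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (orientation == "cells_x_genes") m <- t(m)
  expression_matrix(m)
}

#' Read a reference pseudotime table
#'
#' @param path TSV with columns `cell_id` and `pseudotime` (header required).
#' @return Named numeric vector of pseudotimes.
#' @export
read_pseudotime <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("cell_id", "pseudotime") %in% names(tab))) {
    stop("pseudotime table needs columns cell_id, pseudotime")
  }
  setNames(as.numeric(tab$pseudotime), tab$cell_id)
}

#' Read a gene list (one symbol per line)
#'
#' @param path plain-text file, one gene symbol per line.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}
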