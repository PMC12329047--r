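#' Reference lineage container
#'
#' Couples an expression matrix with a per-cell pseudotime over the
#' non-cycling cells of a non-branching lineage. Pseudotime is rescaled to
#' span exactly `[0,1]`; cycling cells carry no pseudotime and are excluded
#' from all downstream pseudotime computations.
#'
#' @param x a `ptx_expr` (log-normalized or not; [log_normalize()] is applied
#'   lazily where needed).
#' @param pseudotime named numeric vector, one entry per non-cycling cell id.
#' @param cycling optional logical vector named by cell id; defaults to
#'   "not in `pseudotime`".
#' @param boundaries a [stage_boundaries()] object.
#' @param rescale rescale pseudotime to span `[0,1]` (default `TRUE`).
#' @return A `ptx_reference` object.
#' @export
reference_lineage <- function(x, pseudotime, cycling = NULL,
                              boundaries = stage_boundaries(),
                              rescale = TRUE) {
  stopifnot(inherits(x, "ptx_expr"))
  cells <- cell_ids(x)
  if (is.null(names(pseudotime))) stop("`pseudotime` must be named by cell id")
  missing_cells <- setdiff(names(pseudotime), cells)
  if (length(missing_cells)) {
    stop("pseudotime cells absent from matrix: ",
         paste(utils::head(missing_cells, 5), collapse = ", "))
  }
  if (is.null(cycling)) {
    cycling <- setNames(!(cells %in% names(pseudotime)), cells)
  }
  pt <- as.numeric(pseudotime)
  if (length(unique(pt)) < 2) stop("need >= 2 distinct pseudotime values")
  if (rescale) pt <- (pt - min(pt)) / (max(pt) - min(pt))
  if (min(pt) < 0 || max(pt) > 1) stop("pseudotime must lie in [0,1]")
  structure(
    list(matrix = x, pseudotime = setNames(pt, names(pseudotime)),
         cycling = cycling, boundaries = boundaries),
    class = "ptx_reference"
  )
}

#' @export
print.ptx_reference <- function(x, ...) {
  cat(sprintf(
    "<ptx_reference> %d genes x %d cells; %d with pseudotime, %d cycling\n",
    nrow(x$matrix$counts), ncol(x$matrix$counts),
    length(x$pseudotime), sum(x$cycling)
  ))
  invisible(x)
}

noncycling_cells <- function(ref) names(ref$pseudotime)

ref_lognorm <- function(ref) {
  if (is.null(ref$matrix$lognorm)) ref$matrix <- log_normalize(ref$matrix)
  ref$matrix$lognorm
}

#' Bin a reference lineage along pseudotime
#'
#' Partitions `[0,1]` into `n_bins` equal-width bins, drops bins holding
#' fewer than `min_cells_per_bin` non-cycling cells, and stores the mean
#' log-normalized expression of the trajectory genes per retained bin. The
#' bin-mean profile is the coordinate system against which query cells are
#' correlated.
#'
#' @param ref a [reference_lineage()].
#' @param genes character vector of trajectory gene symbols, or a
#'   `ptx_geneset` tibble (column `gene`).
#' @param n_bins number of equal-width pseudotime bins (>= 5).
#' @param min_cells_per_bin bins with fewer cells are dropped.
#' @return A `ptx_binned` object: `bin_centers`, `bin_means` (genes x bins),
#'   `bin_counts`, `bin_edges`, `genes`, plus the per-cell `bin` assignment.
#' @export
bin_reference <- function(ref, genes, n_bins = 50, min_cells_per_bin = 10) {
  if (inherits(genes, "data.frame")) genes <- genes$gene
  if (n_bins < 5) stop("n_bins must be >= 5")
  ln <- ref_lognorm(ref)
  genes <- intersect(genes, rownames(ln))
  if (length(genes) == 0) stop("no trajectory genes found in reference")
  cells <- noncycling_cells(ref)
  pt <- ref$pseudotime
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(pt, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  keep <- which(counts >= min_cells_per_bin)
  dropped <- n_bins - length(keep)
  if (dropped > 0.2 * n_bins) {
    warning(sprintf("%d of %d pseudotime bins dropped (< %d cells)",
                    dropped, n_bins, min_cells_per_bin))
  }
  if (length(keep) < 5) stop("fewer than 5 surviving pseudotime bins")
  sub <- ln[genes, cells, drop = FALSE]
  means <- vapply(keep, function(b) {
    Matrix::rowMeans(sub[, bin == b, drop = FALSE])
  }, numeric(length(genes)))
  dimnames(means) <- list(genes, paste0("bin", keep))
  structure(
    list(
      n_bins = n_bins,
      bin_index = keep,
      bin_centers = (edges[keep] + edges[keep + 1]) / 2,
      bin_edges = edges,
      bin_means = means,
      bin_counts = counts[keep],
      genes = genes,
      cell_bin = setNames(bin, cells)
    ),
    class = "ptx_binned"
  )
}

#' @export
print.ptx_binned <- function(x, ...) {
  cat(sprintf("<ptx_binned> %d/%d bins retained, %d genes\n",
              length(x$bin_index), x$n_bins, length(x$genes)))
  invisible(x)
}
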