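#' Pseudotime similarity profiles of query cells
#'
#' Correlates each query cell's log-normalized trajectory-gene vector with
#' every reference pseudotime bin mean (Pearson, over the genes shared
#' between query and reference bins). The resulting per-cell profile over
#' bins is the coordinate from which pseudotime is predicted.
#'
#' @param query a `ptx_expr`; log-normalized on the fly when needed.
#' @param binned a [bin_reference()] result.
#' @param genes optional gene subset; defaults to the binned gene panel.
#' @return A `ptx_similarity` object: `raw` (cells x bins correlation
#'   matrix), `degenerate` (cells with zero variance over the panel, whose
#'   profiles are `NA`), and `normalized` (`NULL` until
#'   [normalize_profiles()]).
#' @export
similarity_profiles <- function(query, binned, genes = NULL) {
  if (is.null(query$lognorm)) query <- log_normalize(query)
  if (is.null(genes)) genes <- binned$genes
  if (inherits(genes, "data.frame")) genes <- genes$gene
  shared <- intersect(genes, intersect(rownames(query$lognorm),
                                       rownames(binned$bin_means)))
  if (length(shared) < 10) stop("fewer than 10 trajectory genes shared with query")
  # canonical gene and cell order makes results bit-identical under input
  # permutations (floating-point sums are order-sensitive)
  shared <- sort(shared)
  cells <- colnames(query$lognorm)
  canon <- sort(cells)
  q <- as.matrix(query$lognorm[shared, canon, drop = FALSE])
  b <- binned$bin_means[shared, , drop = FALSE]
  degenerate <- apply(q, 2, function(v) var(v) == 0)
  raw <- matrix(NA_real_, ncol(q), ncol(b),
                dimnames = list(canon, colnames(b)))
  if (any(!degenerate)) {
    raw[!degenerate, ] <- cor(q[, !degenerate, drop = FALSE], b)
  }
  structure(
    list(cell_ids = cells, raw = raw[cells, , drop = FALSE],
         normalized = NULL,
         degenerate = setNames(degenerate, canon)[cells],
         bin_centers = binned$bin_centers),
    class = "ptx_similarity"
  )
}

#' @export
print.ptx_similarity <- function(x, ...) {
  cat(sprintf("<ptx_similarity> %d cells x %d bins (%d degenerate, %s)\n",
              nrow(x$raw), ncol(x$raw), sum(x$degenerate),
              if (is.null(x$normalized)) "raw" else "normalized"))
  invisible(x)
}

#' Shape-normalize similarity profiles
#'
#' Centers each cell's correlation profile to mean 0 and scales it to unit
#' variance, so only the profile's shape over pseudotime bins — not its
#' overall correlation level — enters prediction. Constant profiles are
#' flagged degenerate and left unnormalized.
#'
#' @param sim a [similarity_profiles()] result.
#' @return The input with the `normalized` matrix filled in.
#' @export
normalize_profiles <- function(sim) {
  raw <- sim$raw
  mu <- rowMeans(raw)
  s <- apply(raw, 1, sd)
  flat <- !is.na(s) & s == 0
  sim$degenerate <- sim$degenerate | flat
  norm <- (raw - mu) / s
  norm[sim$degenerate, ] <- NA_real_
  sim$normalized <- norm
  sim
}

#' Flag out-of-distribution query cells
#'
#' A cell is out-of-distribution when its raw profile resembles no reference
#' pseudotime position: maximum raw correlation below `c_min`, or profile
#' prominence (maximum minus median) below `prominence_min`.
#'
#' @param sim a [similarity_profiles()] result (raw profiles).
#' @param c_min minimum acceptable peak correlation (default 0.2).
#' @param prominence_min minimum peak-over-median prominence (default 0.05).
#' @return Logical vector named by cell id (`NA` for degenerate cells).
#' @export
flag_out_of_distribution <- function(sim, c_min = 0.2, prominence_min = 0.05) {
  mx <- apply(sim$raw, 1, max)
  md <- apply(sim$raw, 1, median)
  out <- mx < c_min | (mx - md) < prominence_min
  setNames(as.logical(out), sim$cell_ids)
}
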