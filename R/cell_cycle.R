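#' Score cells for cell-cycle phase gene programs
#'
#' Expression-bin-matched gene-set scoring: the score of a cell for a phase
#' gene set is the mean log-normalized expression of the set minus the mean
#' of a control set drawn from the same average-expression bins as the phase
#' genes. Cells strongly expressing G2/M genes relative to expression-matched
#' controls are cycling candidates.
#'
#' @param x a `ptx_expr` with a lognorm layer.
#' @param s_genes,g2m_genes character vectors of S-phase and G2/M-phase gene
#'   symbols; symbols absent from `x` are ignored (an error is raised only if
#'   a whole set is absent).
#' @param n_bins number of average-expression bins used to match controls.
#' @param n_ctrl controls drawn per phase gene.
#' @param seed integer seed for control sampling.
#' @return A tibble with columns `cell_id`, `s_score`, `g2m_score`.
#' @export
score_cell_cycle <- function(x, s_genes, g2m_genes, n_bins = 25, n_ctrl = 50,
                             seed = 1L) {
  ln <- lognorm_layer(x)
  tibble(
    cell_id = colnames(ln),
    s_score = score_gene_set(ln, s_genes, n_bins, n_ctrl, seed),
    g2m_score = score_gene_set(ln, g2m_genes, n_bins, n_ctrl, seed + 1L)
  )
}

score_gene_set <- function(ln, genes, n_bins, n_ctrl, seed) {
  genes <- intersect(genes, rownames(ln))
  if (length(genes) == 0) stop("gene set has no genes in the matrix")
  gene_means <- Matrix::rowMeans(ln)
  # rank-based bins are robust to heavy ties at zero
  bins <- cut(rank(gene_means, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- rownames(ln)
  ctrl <- with_local_seed(seed, {
    unlist(lapply(genes, function(g) {
      pool <- names(bins)[bins == bins[[g]]]
      pool <- setdiff(pool, g)
      if (length(pool) == 0) return(character())
      pool[sample.int(length(pool), min(n_ctrl, length(pool)))]
    }))
  })
  ctrl <- unique(ctrl)
  set_mean <- Matrix::colMeans(ln[genes, , drop = FALSE])
  ctrl_mean <- if (length(ctrl)) {
    Matrix::colMeans(ln[ctrl, , drop = FALSE])
  } else {
    rep(0, ncol(ln))
  }
  as.numeric(set_mean - ctrl_mean)
}

#' Flag cycling cells from G2/M scores
#'
#' A cell is called cycling when its G2/M score strictly exceeds the cutoff
#' (default 0.1).
#'
#' @param g2m_scores numeric vector of per-cell G2/M scores.
#' @param cutoff score threshold; strict inequality.
#' @return Logical vector, `TRUE` for cycling cells.
#' @export
flag_cycling <- function(g2m_scores, cutoff = 0.1) {
  as.logical(g2m_scores > cutoff)
}

# evaluate expr under a temporary RNG state so callers' streams are untouched
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
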