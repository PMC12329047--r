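#' Reference-query bin correlation matrix
#'
#' Bins the query cells along their aligned pseudotime with the same
#' equal-width bins as the reference and correlates every reference bin mean
#' with every query bin mean over the shared gene panel.
#'
#' @param binned_ref a [bin_reference()] result.
#' @param query a `ptx_expr` (log-normalized on the fly).
#' @param query_pt named numeric vector of aligned query pseudotimes
#'   (`NA` cells are ignored).
#' @param genes gene panel; defaults to the reference bin panel.
#' @param min_cells_per_bin query bins with fewer cells are dropped.
#' @return Matrix of Pearson correlations, reference bins x query bins.
#' @export
dtw_matrix <- function(binned_ref, query, query_pt, genes = NULL,
                       min_cells_per_bin = 5) {
  if (is.null(genes)) genes <- binned_ref$genes
  if (inherits(genes, "data.frame")) genes <- genes$gene
  if (is.null(query$lognorm)) query <- log_normalize(query)
  shared <- intersect(genes, intersect(rownames(query$lognorm),
                                       rownames(binned_ref$bin_means)))
  if (length(shared) == 0) stop("no shared genes between reference and query")
  shared <- sort(shared)  # canonical order for bit-stable means
  pt <- query_pt[!is.na(query_pt)]
  cells <- sort(intersect(names(pt), colnames(query$lognorm)))
  pt <- pt[cells]
  edges <- binned_ref$bin_edges
  n_bins <- binned_ref$n_bins
  bin <- pmin(findInterval(pt, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  keep <- which(counts >= min_cells_per_bin)
  if (length(keep) < 5) stop("fewer than 5 surviving query bins")
  ln <- as.matrix(query$lognorm[shared, cells, drop = FALSE])
  qmeans <- vapply(keep, function(b) rowMeans(ln[, bin == b, drop = FALSE]),
                   numeric(length(shared)))
  m <- cor(binned_ref$bin_means[shared, , drop = FALSE], qmeans)
  dimnames(m) <- list(colnames(binned_ref$bin_means), paste0("qbin", keep))
  m
}

#' Maximal-correlation traceback through a DTW matrix
#'
#' Dynamic-programming path from the top-left to the bottom-right corner of
#' the reference x query correlation matrix, with moves down, right, or
#' diagonal, minimizing the accumulated correlation distance `1 - r` along
#' the path (equivalently: maximizing summed correlation penalized by path
#' length, so detours must earn their keep). Ties are broken in favour of the
#' diagonal move; a constant matrix therefore yields the plain diagonal. A
#' faithful alignment concentrates high correlations near the diagonal,
#' giving a short path with a high mean correlation.
#'
#' @param m finite numeric matrix (reference bins x query bins).
#' @return A `ptx_dtw` object: `path` (two-column index matrix), `score`
#'   (summed correlation along the path), `cost` (summed `1 - r`, the
#'   minimized objective), `mean_corr`, `path_length`, `diag_deviation`
#'   (mean `|i/B_ref - j/B_query|` along the path), and the input `matrix`.
#' @export
traceback_max_correlation <- function(m) {
  if (!all(is.finite(m))) stop("matrix must be finite")
  nr <- nrow(m); nc <- ncol(m)
  cost <- matrix(Inf, nr, nc)
  # move code: 0 start, 1 diagonal, 2 up (ref step), 3 left (query step)
  move <- matrix(0L, nr, nc)
  cost[1, 1] <- 1 - m[1, 1]
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (i == 1 && j == 1) next
      diag_c <- if (i > 1 && j > 1) cost[i - 1, j - 1] else Inf
      up_c <- if (i > 1) cost[i - 1, j] else Inf
      left_c <- if (j > 1) cost[i, j - 1] else Inf
      best <- min(diag_c, up_c, left_c)
      cost[i, j] <- best + (1 - m[i, j])
      move[i, j] <- if (diag_c <= best) 1L else if (up_c <= best) 2L else 3L
    }
  }
  path <- matrix(NA_integer_, nr + nc, 2)
  i <- nr; j <- nc; k <- 0L
  repeat {
    k <- k + 1L
    path[k, ] <- c(i, j)
    mv <- move[i, j]
    if (mv == 0L) break
    if (mv == 1L) { i <- i - 1; j <- j - 1 }
    else if (mv == 2L) i <- i - 1
    else j <- j - 1
  }
  path <- path[k:1, , drop = FALSE]
  colnames(path) <- c("ref_bin", "query_bin")
  vals <- m[path]
  structure(
    list(matrix = m, path = path, score = sum(vals), cost = cost[nr, nc],
         path_length = nrow(path), mean_corr = mean(vals),
         diag_deviation = mean(abs(path[, 1] / nr - path[, 2] / nc))),
    class = "ptx_dtw"
  )
}

#' @export
print.ptx_dtw <- function(x, ...) {
  cat(sprintf("<ptx_dtw> %dx%d, path length %d, mean corr %.3f, diag dev %.3f\n",
              nrow(x$matrix), ncol(x$matrix), x$path_length, x$mean_corr,
              x$diag_deviation))
  invisible(x)
}

#' Tidy a DTW traceback path
#' @param x a `ptx_dtw` object.
#' @param ... unused.
#' @export
tidy.ptx_dtw <- function(x, ...) {
  tibble(ref_bin = x$path[, 1], query_bin = x$path[, 2],
         correlation = x$matrix[x$path])
}

#' @rdname tidy.ptx_dtw
#' @export
glance.ptx_dtw <- function(x, ...) {
  tibble(score = x$score, cost = x$cost, mean_corr = x$mean_corr,
         path_length = x$path_length, diag_deviation = x$diag_deviation)
}

#' Permutation test of alignment quality
#'
#' Reruns the whole alignment pipeline — reference binning, self-masked
#' training profiles, perceptron retraining, query prediction, query binning,
#' DTW traceback — once with the trajectory gene set (observed) and `n_perm`
#' times with random gene sets of identical size matched to the trajectory
#' set's reference expression deciles (trajectory genes excluded from the
#' pool). The statistic is the mean correlation along the traceback path; the
#' empirical P-value uses the add-one rule, so it can never be exactly zero.
#'
#' @param query a `ptx_expr`.
#' @param ref a [reference_lineage()].
#' @param genes trajectory gene set (`ptx_geneset` tibble or character).
#' @param n_perm number of permutations (>= 19).
#' @param seed integer seed.
#' @param n_bins,min_cells_per_bin reference binning parameters.
#' @param hidden,l2 perceptron configuration reused for every retraining
#'   (defaults: a single compact configuration — the permutation replicates
#'   the pipeline at fixed hyperparameters).
#' @param epochs,learning_rate perceptron training schedule.
#' @return A `ptx_permutation` object with `observed`, `permuted`, `p_value`,
#'   `n_perm`, `seed`, and the observed `ptx_dtw`.
#' @export
permutation_pvalue <- function(query, ref, genes, n_perm = 100, seed = 1L,
                               n_bins = 50, min_cells_per_bin = 10,
                               hidden = c(32, 16), l2 = 1e-3,
                               epochs = 150, learning_rate = 0.015) {
  if (n_perm < 19) stop("n_perm must be >= 19")
  if (inherits(genes, "data.frame")) genes <- genes$gene
  if (is.null(query$lognorm)) query <- log_normalize(query)
  ln <- ref_lognorm(ref)
  genes <- intersect(genes, rownames(ln))
  gene_means <- Matrix::rowMeans(ln[, noncycling_cells(ref), drop = FALSE])
  dec_breaks <- quantile(gene_means, probs = seq(0, 1, 0.1), names = FALSE)
  decile <- cut(gene_means, breaks = unique(dec_breaks), include.lowest = TRUE,
                labels = FALSE)
  names(decile) <- names(gene_means)
  levs <- sort(unique(decile))
  target_hist <- table(factor(decile[genes], levels = levs))
  pool <- setdiff(names(decile), genes)
  pool_by_dec <- split(pool, factor(decile[pool], levels = levs))
  need <- as.numeric(target_hist)
  avail <- vapply(as.character(levs), function(d) length(pool_by_dec[[d]]),
                  numeric(1), USE.NAMES = FALSE)
  if (sum(need) > sum(avail)) {
    deficient <- levs[need > avail]
    stop("not enough non-trajectory genes in expression decile(s): ",
         paste(deficient, collapse = ", "))
  }
  # deciles the panel majority-occupies cannot supply a same-size matched
  # draw; borrow the shortfall from the nearest deciles with surplus
  if (any(need > avail)) {
    borrowed_from <- integer()
    for (d in which(need > avail)) {
      short <- need[d] - avail[d]
      need[d] <- avail[d]
      others <- order(abs(seq_along(levs) - d))
      for (o in others) {
        if (short == 0) break
        give <- min(short, avail[o] - need[o])
        if (give > 0) {
          need[o] <- need[o] + give
          short <- short - give
          borrowed_from <- union(borrowed_from, o)
        }
      }
    }
    warning("expression-matched sampling borrowed from adjacent decile(s) ",
            paste(levs[borrowed_from], collapse = ", "),
            " for over-occupied decile(s)")
  }
  target_hist <- setNames(need, as.character(levs))

  run_once <- function(gene_set, run_seed) {
    binned <- bin_reference(ref, gene_set, n_bins, min_cells_per_bin)
    prof <- self_similarity_profiles(ref, binned)
    sim <- normalize_profiles(prof)
    ok <- !sim$degenerate
    X <- sim$normalized[ok, , drop = FALSE]
    y <- ref$pseudotime[rownames(X)]
    fit <- mlp_train(X, y, hidden[1], hidden[2], l2, epochs, learning_rate,
                     1e-7, 30L, as.integer(run_seed))
    qsim <- normalize_profiles(similarity_profiles(query, binned))
    qpt <- rep(NA_real_, length(qsim$cell_ids))
    names(qpt) <- qsim$cell_ids
    okq <- !qsim$degenerate
    qpt[okq] <- clip01(mlp_forward(fit, qsim$normalized[okq, , drop = FALSE]))
    m <- dtw_matrix(binned, query, qpt, gene_set,
                    min_cells_per_bin = min_cells_per_bin)
    traceback_max_correlation(m)
  }

  obs <- run_once(genes, seed)
  perm_sets <- with_local_seed(seed + 1L, {
    lapply(seq_len(n_perm), function(i) {
      unlist(lapply(names(target_hist), function(d) {
        k <- target_hist[[d]]
        if (k == 0) return(character())
        cand <- pool_by_dec[[d]]
        cand[sample.int(length(cand), k)]
      }), use.names = FALSE)
    })
  })
  permuted <- vapply(seq_len(n_perm), function(i) {
    res <- tryCatch(run_once(perm_sets[[i]], seed + 1L + i)$mean_corr,
                    error = function(e) NA_real_)
    res
  }, numeric(1))
  permuted_ok <- permuted[is.finite(permuted)]
  p <- (1 + sum(permuted_ok >= obs$mean_corr)) / (1 + length(permuted_ok))
  structure(
    list(observed = obs$mean_corr, permuted = permuted, p_value = p,
         n_perm = n_perm, seed = seed, dtw = obs),
    class = "ptx_permutation"
  )
}

#' @export
print.ptx_permutation <- function(x, ...) {
  cat(sprintf("<ptx_permutation> observed %.3f vs %d permutations, p = %.4g\n",
              x$observed, x$n_perm, x$p_value))
  invisible(x)
}

#' @rdname tidy.ptx_dtw
#' @export
glance.ptx_permutation <- function(x, ...) {
  tibble(observed = x$observed, p_value = x$p_value, n_perm = x$n_perm,
         permuted_mean = mean(x$permuted, na.rm = TRUE), seed = x$seed)
}

#' Pseudotime coherence with expression geometry
#'
#' Correlates pairwise cell distances in a principal-component subspace with
#' pairwise rank distances of pseudotime. Rank distances make the statistic
#' invariant to monotone re-parameterizations of pseudotime, so orderings
#' from different trajectory methods are comparable.
#'
#' @param x a `ptx_expr`.
#' @param pt per-cell pseudotime (named or aligned with the cells).
#' @param n_components principal components used (default 10).
#' @return Pearson correlation between PCA distances and pseudotime rank
#'   distances.
#' @export
pseudotime_coherence <- function(x, pt, n_components = 10) {
  if (is.null(x$lognorm)) x <- log_normalize(x)
  if (!is.null(names(pt))) {
    cells <- intersect(colnames(x$lognorm), names(pt))
    pt <- pt[cells]
  } else {
    cells <- colnames(x$lognorm)
  }
  pt <- pt[!is.na(pt)]
  cells <- names(pt)
  if (length(cells) < 3) stop("need >= 3 cells with pseudotime")
  if (var(pt) == 0) stop("constant pseudotime")
  expr <- t(as.matrix(x$lognorm[, cells, drop = FALSE]))
  k <- min(n_components, ncol(expr), nrow(expr) - 1)
  pcs <- prcomp(expr, rank. = k, center = TRUE, scale. = FALSE)$x
  d_pca <- as.numeric(dist(pcs))
  d_rank <- as.numeric(dist(rank(pt)))
  cor(d_pca, d_rank)
}
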