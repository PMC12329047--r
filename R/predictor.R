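#' Train the pseudotime predictor on reference self-similarity
#'
#' Computes self-masked similarity profiles for every non-cycling reference
#' cell (each cell is excluded from its own bin's mean so its training
#' profile carries no leakage), shape-normalizes them, and trains a
#' three-layer perceptron (two tanh hidden layers, scalar linear output) to
#' regress the known reference pseudotime. Hyperparameters — hidden sizes and
#' L2 penalty — are chosen by 5-fold cross-validated grid search minimizing
#' mean squared error; the winning configuration is refit on all profiles.
#'
#' @param ref a [reference_lineage()].
#' @param binned a [bin_reference()] of the same reference.
#' @param genes trajectory gene panel (defaults to the binned panel).
#' @param seed integer seed; training is deterministic given it.
#' @param hidden list of `c(h1, h2)` hidden-layer sizes to search.
#' @param l2 numeric vector of L2 penalties to search.
#' @param cv_folds folds of the grid-search cross-validation.
#' @param epochs maximum training epochs of the final refit (early stopping
#'   on loss plateau).
#' @param cv_epochs epoch budget per cross-validation fit; smaller than
#'   `epochs` since the fold fits only rank configurations.
#' @param learning_rate Adam step size.
#' @param min_cells minimum non-cycling reference cells required.
#' @return A `ptalign_predictor` object.
#' @export
train_predictor <- function(ref, binned, genes = NULL, seed = 1L,
                            hidden = list(c(32, 16), c(64, 32), c(128, 64)),
                            l2 = c(1e-4, 1e-3, 1e-2),
                            cv_folds = 5, epochs = 300,
                            cv_epochs = max(60, epochs %/% 4),
                            learning_rate = 0.015, min_cells = 200) {
  cells <- noncycling_cells(ref)
  if (length(cells) < min_cells) {
    stop("need >= ", min_cells, " non-cycling reference cells")
  }
  prof <- self_similarity_profiles(ref, binned, genes)
  sim <- normalize_profiles(prof)
  ok <- !sim$degenerate
  X <- sim$normalized[ok, , drop = FALSE]
  y <- ref$pseudotime[rownames(X)]

  grid <- expand.grid(h = seq_along(hidden), l2 = l2)
  folds <- with_local_seed(seed, sample(rep_len(seq_len(cv_folds), nrow(X))))
  cv_mse <- vapply(seq_len(nrow(grid)), function(g) {
    h <- hidden[[grid$h[g]]]
    lam <- grid$l2[g]
    mse <- vapply(seq_len(cv_folds), function(k) {
      tr <- folds != k
      fit <- mlp_train(X[tr, , drop = FALSE], y[tr], h[1], h[2], lam,
                       cv_epochs, learning_rate, 1e-7, 20L,
                       as.integer(seed + 7L * g + k))
      pred <- clip01(mlp_forward(fit, X[!tr, , drop = FALSE]))
      mean((pred - y[!tr])^2)
    }, numeric(1))
    if (any(!is.finite(mse))) {
      stop(sprintf("non-finite CV loss at grid point hidden=(%d,%d) l2=%g",
                   h[1], h[2], lam))
    }
    mean(mse)
  }, numeric(1))
  best <- which.min(cv_mse)
  h <- hidden[[grid$h[best]]]
  lam <- grid$l2[best]
  fit <- mlp_train(X, y, h[1], h[2], lam, epochs, learning_rate, 1e-7, 30L,
                   as.integer(seed))
  structure(
    list(fit = fit, hidden = h, l2 = lam, cv_mse = cv_mse, grid = grid,
         grid_hidden = hidden,
         training_loss = fit$loss, n_bins = ncol(X), seed = seed,
         epochs = epochs, learning_rate = learning_rate, fitted = TRUE),
    class = "ptalign_predictor"
  )
}

# reference self-profiles with self-masking: a cell's own bin mean is
# recomputed without the cell before correlating
self_similarity_profiles <- function(ref, binned, genes = NULL) {
  if (is.null(genes)) genes <- binned$genes
  if (inherits(genes, "data.frame")) genes <- genes$gene
  genes <- intersect(genes, rownames(binned$bin_means))
  ln <- ref_lognorm(ref)
  cells <- noncycling_cells(ref)
  q <- as.matrix(ln[genes, cells, drop = FALSE])
  b <- binned$bin_means[genes, , drop = FALSE]
  degenerate <- apply(q, 2, function(v) var(v) == 0)
  raw <- matrix(NA_real_, ncol(q), ncol(b),
                dimnames = list(colnames(q), colnames(b)))
  if (any(!degenerate)) {
    raw[!degenerate, ] <- cor(q[, !degenerate, drop = FALSE], b)
  }
  # adjust the own-bin entry cell by cell
  bin_of <- binned$cell_bin[cells]
  col_of <- match(bin_of, binned$bin_index)
  sums <- b * 0
  for (j in seq_along(binned$bin_index)) {
    sums[, j] <- b[, j] * binned$bin_counts[j]
  }
  for (i in seq_along(cells)) {
    j <- col_of[i]
    if (is.na(j) || degenerate[i]) next
    n_j <- binned$bin_counts[j]
    if (n_j <= 1) next
    masked <- (sums[, j] - q[, i]) / (n_j - 1)
    raw[i, j] <- suppressWarnings(cor(q[, i], masked))
  }
  structure(
    list(cell_ids = colnames(q), raw = raw, normalized = NULL,
         degenerate = setNames(degenerate, colnames(q)),
         bin_centers = binned$bin_centers),
    class = "ptx_similarity"
  )
}

#' Predict pseudotime from normalized similarity profiles
#'
#' @param model a fitted [train_predictor()] object.
#' @param sim a [normalize_profiles()]-normalized `ptx_similarity`.
#' @return Named numeric vector of predicted pseudotimes clipped to `[0,1]`;
#'   `NA` for degenerate cells.
#' @export
predict_pseudotime <- function(model, sim) {
  if (!isTRUE(model$fitted)) stop("predictor is not fitted")
  if (is.null(sim$normalized)) stop("similarity profiles are not normalized")
  if (ncol(sim$normalized) != model$n_bins) {
    stop(sprintf("bin-count mismatch: model expects %d bins, profiles have %d",
                 model$n_bins, ncol(sim$normalized)))
  }
  out <- rep(NA_real_, length(sim$cell_ids))
  names(out) <- sim$cell_ids
  ok_cells <- sort(sim$cell_ids[!sim$degenerate])  # canonical row order
  if (length(ok_cells)) {
    pred <- clip01(mlp_forward(model$fit,
                               sim$normalized[ok_cells, , drop = FALSE]))
    out[ok_cells] <- pred
  }
  out
}

clip01 <- function(x) pmin(1, pmax(0, as.numeric(x)))

#' @export
print.ptalign_predictor <- function(x, ...) {
  cat(sprintf(
    "<ptalign_predictor> %d bins -> (%d,%d) tanh -> 1; l2=%g, train MSE %.4g\n",
    x$n_bins, x$hidden[1], x$hidden[2], x$l2, x$training_loss))
  invisible(x)
}

#' Tidy the predictor's hyperparameter search
#'
#' @param x a `ptalign_predictor`.
#' @param ... unused.
#' @return Tibble of grid points with cross-validated MSE and the chosen row
#'   flagged.
#' @export
tidy.ptalign_predictor <- function(x, ...) {
  tibble(
    hidden1 = vapply(x$grid$h, function(i) x$grid_hidden[[i]][1], numeric(1)),
    hidden2 = vapply(x$grid$h, function(i) x$grid_hidden[[i]][2], numeric(1)),
    l2 = x$grid$l2,
    cv_mse = x$cv_mse,
    chosen = seq_along(x$cv_mse) == which.min(x$cv_mse)
  )
}

#' One-row summary of a fitted predictor
#'
#' @param x a `ptalign_predictor`.
#' @param ... unused.
#' @export
glance.ptalign_predictor <- function(x, ...) {
  tibble(n_bins = x$n_bins, hidden1 = x$hidden[1], hidden2 = x$hidden[2],
         l2 = x$l2, training_mse = x$training_loss,
         cv_mse = min(x$cv_mse), seed = x$seed)
}

#' Broom-style generics
#'
#' `tidy()` and `glance()` generics re-exported for ptalign result objects.
#' @param x object to tidy or summarize.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
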