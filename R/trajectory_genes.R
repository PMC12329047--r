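#' Derive a stage-labelled trajectory gene set
#'
#' Selects pseudotime-predictive genes from a reference lineage in four
#' steps: (1) prefilter by global detection and per-stage enrichment;
#' (2) recursive feature elimination with a random-forest stage classifier
#' evaluated by cross-validation on a 70/30 split; (3) repeated random-subset
#' importance ranking — `n_perm` draws of `genes_per_perm` genes, each scored
#' by a random forest, importances averaged per gene over the draws in which
#' it was sampled; (4) knee-point cutoff on the descending mean-importance
#' curve. Ribosomal genes (symbols matching `^RP[LS]`, case-insensitive) are
#' removed, at most `top_per_stage` genes are kept per stage, and each gene
#' is assigned the stage where its mean expression is maximal.
#'
#' @param ref a [reference_lineage()].
#' @param stage_labels factor/character of Q/A/D labels, named by cell id or
#'   aligned with the non-cycling cells; defaults to stages from the
#'   reference pseudotime and boundaries.
#' @param cv_folds cross-validation folds used during elimination.
#' @param split training fraction of the 70/30 split.
#' @param n_perm number of random-subset importance draws.
#' @param genes_per_perm genes sampled per draw.
#' @param top_per_stage cap on genes retained per stage.
#' @param num_trees trees per random forest.
#' @param seed integer seed; the whole pipeline is deterministic given it.
#' @return A `ptx_geneset` tibble with columns `gene`, `stage`, `importance`.
#' @export
derive_trajectory_genes <- function(ref, stage_labels = NULL, cv_folds = 3,
                                    split = 0.7, n_perm = 500,
                                    genes_per_perm = 500, top_per_stage = 100,
                                    num_trees = 200, seed = 1L) {
  ln <- ref_lognorm(ref)
  cells <- noncycling_cells(ref)
  if (is.null(stage_labels)) {
    stage_labels <- setNames(
      as.character(assign_stages(ref$pseudotime, ref$boundaries)$stage),
      cells
    )
  }
  if (!is.null(names(stage_labels))) stage_labels <- stage_labels[cells]
  stage <- factor(as.character(stage_labels), levels = c("Q", "A", "D"))
  if (any(is.na(stage))) stop("stage labels must be Q/A/D for every cell")
  if (any(table(stage) < 20)) stop("every stage needs >= 20 cells")

  expr <- t(as.matrix(ln[, cells, drop = FALSE]))  # cells x genes

  ## 1. prefilter: detected in >= 1% of cells and >= 1.5x stage enrichment
  det <- Matrix::colMeans(expr > 0)
  stage_means <- vapply(levels(stage), function(s) {
    colMeans(expr[stage == s, , drop = FALSE])
  }, numeric(ncol(expr)))
  top_stage <- apply(stage_means, 1, max)
  rest_mean <- (rowSums(stage_means) - top_stage) / (ncol(stage_means) - 1)
  enriched <- top_stage >= 1.5 * rest_mean & top_stage > 0
  keep <- det >= 0.01 & enriched
  genes <- colnames(expr)[keep]
  if (length(genes) < nlevels(stage)) stop("fewer prefiltered genes than stages")

  ## 2. recursive feature elimination on a 70/30 split
  genes <- rfe_select(expr[, genes, drop = FALSE], stage, split, cv_folds,
                      num_trees, min_genes = max(3L * top_per_stage, 30L),
                      seed = seed)

  ## 3. repeated random-subset importances
  imp_sum <- setNames(numeric(length(genes)), genes)
  imp_n <- setNames(numeric(length(genes)), genes)
  with_local_seed(seed + 1L, {
    for (i in seq_len(n_perm)) {
      draw <- if (length(genes) > genes_per_perm) {
        sample(genes, genes_per_perm)
      } else {
        genes
      }
      fit <- ranger::ranger(
        x = expr[, draw, drop = FALSE], y = stage,
        num.trees = num_trees, importance = "impurity",
        seed = seed + 1L + i, num.threads = 1
      )
      imp <- fit$variable.importance
      imp_sum[names(imp)] <- imp_sum[names(imp)] + imp
      imp_n[names(imp)] <- imp_n[names(imp)] + 1
    }
  })
  sampled <- imp_n > 0
  mean_imp <- imp_sum[sampled] / imp_n[sampled]
  ord <- order(mean_imp, decreasing = TRUE)
  ranked <- mean_imp[ord]

  ## 4. knee cutoff on the log importance curve (impurity importances are
  ## heavy-tailed; the log stabilizes the head so the knee lands at the
  ## signal/noise transition), then ribosomal filter and per-stage cap
  knee <- find_inflection(log1p(as.numeric(ranked)))
  if (!is.null(knee)) ranked <- ranked[seq_len(knee)]
  sel <- names(ranked)
  sel <- sel[!grepl("^RP[LS]", sel, ignore.case = TRUE)]
  if (length(sel) < nlevels(stage)) stop("fewer selected genes than stages")

  gene_stage <- levels(stage)[apply(stage_means[sel, , drop = FALSE], 1, which.max)]
  out <- tibble(gene = sel, stage = gene_stage,
                importance = as.numeric(ranked[sel]))
  out <- dplyr::slice_max(dplyr::group_by(out, .data$stage),
                          order_by = .data$importance,
                          n = top_per_stage, with_ties = FALSE)
  out <- dplyr::arrange(dplyr::ungroup(out), dplyr::desc(.data$importance))
  class(out) <- c("ptx_geneset", class(out))
  out
}

# RF-RFE: drop the 20% least important genes per round while held-out
# accuracy stays within one point of the best seen; stop at `min_genes`
rfe_select <- function(expr, stage, split, cv_folds, num_trees, min_genes,
                       seed) {
  genes <- colnames(expr)
  with_local_seed(seed, {
    idx <- sample.int(nrow(expr))
    n_train <- max(cv_folds, floor(split * nrow(expr)))
    train <- idx[seq_len(n_train)]
    test <- idx[-seq_len(n_train)]
    best_acc <- -Inf
    best_genes <- genes
    round <- 0L
    while (length(genes) > min_genes) {
      round <- round + 1L
      fit <- ranger::ranger(
        x = expr[train, genes, drop = FALSE], y = stage[train],
        num.trees = num_trees, importance = "impurity",
        seed = seed + 101L * round, num.threads = 1
      )
      acc <- mean(predict(fit, expr[test, genes, drop = FALSE])$predictions ==
                    stage[test])
      if (acc >= best_acc) {
        best_acc <- acc
        best_genes <- genes
      } else if (acc < best_acc - 0.02) {
        break
      }
      imp <- sort(fit$variable.importance, decreasing = TRUE)
      n_keep <- max(min_genes, ceiling(0.8 * length(genes)))
      if (n_keep >= length(genes)) break
      genes <- names(imp)[seq_len(n_keep)]
    }
    best_genes
  })
}

#' Write / read a trajectory gene set as TSV
#'
#' @param x a `ptx_geneset` tibble (columns `gene`, `stage`, optionally
#'   `importance`).
#' @param path output TSV path.
#' @export
write_geneset <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_geneset
#' @export
read_geneset <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("gene", "stage") %in% names(tab))) {
    stop("gene set table needs columns gene, stage")
  }
  out <- as_tibble(tab)
  class(out) <- c("ptx_geneset", class(out))
  out
}
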