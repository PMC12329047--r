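#' Select genes expressed across a sample cohort
#'
#' A gene is kept when the fraction of cells expressing it above a threshold
#' reaches `frac_cells` in at least `frac_samples` of the samples — genes
#' with usable dynamics in both healthy and disease contexts.
#'
#' @param samples list of `ptx_expr` objects (log-normalized on the fly).
#' @param frac_cells minimum expressing-cell fraction per sample (default 1%).
#' @param frac_samples minimum fraction of qualifying samples (default 10%).
#' @param expr_threshold lognorm value above which a cell counts as
#'   expressing (default 0).
#' @return Character vector of retained gene symbols.
#' @export
select_universal_genes <- function(samples, frac_cells = 0.01,
                                   frac_samples = 0.10, expr_threshold = 0) {
  if (length(samples) < 1) stop("need >= 1 sample")
  samples <- lapply(samples, function(s) {
    if (is.null(s$lognorm)) log_normalize(s) else s
  })
  genes <- Reduce(union, lapply(samples, function(s) rownames(s$lognorm)))
  qualifies <- vapply(samples, function(s) {
    frac <- setNames(numeric(length(genes)), genes)
    present <- intersect(genes, rownames(s$lognorm))
    frac[present] <- Matrix::rowMeans(s$lognorm[present, , drop = FALSE] >
                                        expr_threshold)
    frac >= frac_cells
  }, logical(length(genes)))
  keep <- rowMeans(as.matrix(qualifies)) >= frac_samples
  genes[keep]
}

#' Per-gene, per-sample EMD table against a reference curve
#'
#' @param sample_splines named list (gene) of named lists (sample) of
#'   `ptx_spline` objects for the disease samples.
#' @param reference_curves named list (gene) of `ptx_spline` mean reference
#'   curves (see [mean_reference_curve()]).
#' @return Tibble with columns `gene`, `sample`, `distance`, `lost`
#'   (unexpressed in the sample).
#' @export
emd_table <- function(sample_splines, reference_curves) {
  rows <- lapply(names(sample_splines), function(g) {
    ref <- reference_curves[[g]]
    if (is.null(ref)) return(NULL)
    per_sample <- sample_splines[[g]]
    tibble(
      gene = g,
      sample = names(per_sample),
      distance = vapply(per_sample, function(s) emd(ref, s), numeric(1)),
      lost = vapply(per_sample, function(s) !s$expressed, logical(1))
    )
  })
  dplyr::bind_rows(rows)
}

#' Rank recurrently dysregulated genes by mean EMD
#'
#' Filters to genes in the upper half of reference expression (by spline
#' area), not lost in more than `lost_max` of the samples, and outside the
#' trajectory gene panel; ranks survivors by mean EMD across samples
#' (descending) and calls genes above the knee of the ranked curve
#' dysregulated.
#'
#' @param gene_emd tibble from [emd_table()] (`gene`, `sample`, `distance`,
#'   `lost`).
#' @param gene_area named numeric of reference spline areas per gene.
#' @param trajectory_genes genes excluded from ranking (the alignment panel).
#' @param lost_max maximum tolerated fraction of samples with lost
#'   expression (default 0.5).
#' @return Tibble `gene`, `mean_emd`, `rank`, `dysregulated`.
#' @export
rank_dysregulated <- function(gene_emd, gene_area, trajectory_genes = character(),
                              lost_max = 0.5) {
  if (inherits(trajectory_genes, "data.frame")) {
    trajectory_genes <- trajectory_genes$gene
  }
  per_gene <- dplyr::summarise(
    dplyr::group_by(gene_emd, .data$gene),
    mean_emd = mean(.data$distance),
    lost_frac = mean(.data$lost),
    .groups = "drop"
  )
  area_cut <- median(gene_area[per_gene$gene], na.rm = TRUE)
  per_gene <- dplyr::filter(
    per_gene,
    gene_area[.data$gene] >= area_cut,
    .data$lost_frac <= lost_max,
    !(.data$gene %in% trajectory_genes)
  )
  per_gene <- dplyr::arrange(per_gene, dplyr::desc(.data$mean_emd))
  per_gene$rank <- seq_len(nrow(per_gene))
  knee <- tryCatch(find_inflection(per_gene$mean_emd), error = function(e) NULL)
  if (is.null(knee)) {
    warning("no knee found in ranked mean EMD; no gene called dysregulated")
    per_gene$dysregulated <- FALSE
  } else {
    per_gene$dysregulated <- per_gene$rank <= knee
  }
  dplyr::select(per_gene, "gene", "mean_emd", "rank", "dysregulated")
}

#' Within/between-group EMD biomarker screen
#'
#' For every gene, computes each group's mean dynamics curve, the mean EMD of
#' group members to their own group mean (within-group consistency), and the
#' EMD between the two group means. Genes whose within-group EMD exceeds
#' `within_max` in either group are dropped; survivors are ranked by the
#' between-group distance.
#'
#' @param group_a,group_b named lists (gene) of lists (sample) of
#'   `ptx_spline` objects; each group needs >= 2 samples per gene.
#' @param within_max within-group EMD tolerance (default 0.1).
#' @return Tibble `gene`, `within_a`, `within_b`, `between`, `retained`,
#'   `rank` (`NA` for dropped genes).
#' @export
group_emd_biomarkers <- function(group_a, group_b, within_max = 0.1) {
  genes <- intersect(names(group_a), names(group_b))
  rows <- lapply(genes, function(g) {
    sa <- group_a[[g]]; sb <- group_b[[g]]
    if (length(sa) < 2 || length(sb) < 2) {
      stop("each group needs >= 2 samples (gene ", g, ")")
    }
    ma <- mean_reference_curve(sa)
    mb <- mean_reference_curve(sb)
    tibble(
      gene = g,
      within_a = mean(vapply(sa, function(s) emd(ma, s), numeric(1))),
      within_b = mean(vapply(sb, function(s) emd(mb, s), numeric(1))),
      between = emd(ma, mb)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$retained <- out$within_a <= within_max & out$within_b <= within_max
  out <- dplyr::arrange(out, dplyr::desc(.data$between))
  out$rank <- NA_integer_
  out$rank[out$retained] <- rank(-out$between[out$retained],
                                 ties.method = "first")
  out
}

#' Fit dynamics splines for every gene of a sample
#'
#' Convenience wrapper: fits [fit_expression_spline()] for each gene of a
#' log-normalized sample over its aligned pseudotime.
#'
#' @param x a `ptx_expr`.
#' @param pt named per-cell pseudotime (cells with `NA` are skipped).
#' @param genes genes to fit (default: all genes of `x`).
#' @param ... passed to [fit_expression_spline()].
#' @return Named list of `ptx_spline` objects.
#' @export
fit_sample_splines <- function(x, pt, genes = NULL, ...) {
  if (is.null(x$lognorm)) x <- log_normalize(x)
  if (is.null(genes)) genes <- rownames(x$lognorm)
  cells <- intersect(colnames(x$lognorm), names(pt)[!is.na(pt)])
  ln <- as.matrix(x$lognorm[intersect(genes, rownames(x$lognorm)), cells,
                            drop = FALSE])
  ptv <- pt[cells]
  out <- lapply(rownames(ln), function(g) {
    fit_expression_spline(ptv, ln[g, ], ...)
  })
  names(out) <- rownames(ln)
  out
}
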