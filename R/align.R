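#' Align query cells onto the reference pseudotime
#'
#' End-to-end alignment of a query expression matrix into a reference
#' lineage's pseudotime coordinate: cycling cells are flagged first and never
#' aligned; remaining cells get correlation similarity profiles against the
#' binned reference, out-of-distribution and degenerate cells are excluded,
#' and the trained perceptron maps the shape-normalized profiles to
#' pseudotime. Stages are assigned from the reference boundaries.
#'
#' @param query a `ptx_expr` of query counts.
#' @param ref a [reference_lineage()].
#' @param binned a [bin_reference()] of the reference.
#' @param model a [train_predictor()] fit.
#' @param genes trajectory panel (defaults to the binned panel).
#' @param cycling logical per query cell (named), e.g. from [flag_cycling()];
#'   `NULL` disables cycling exclusion.
#' @param c_min,prominence_min out-of-distribution thresholds, see
#'   [flag_out_of_distribution()].
#' @param boundaries stage boundaries; defaults to the reference's.
#' @return A `ptalign_alignment` tibble with one row per query cell:
#'   `cell_id`, `pseudotime` (`NA` unless aligned), `stage`, `dormant`,
#'   `status` (`aligned` / `cycling` / `out_of_distribution` / `degenerate`).
#' @export
ptalign_align <- function(query, ref, binned, model, genes = NULL,
                          cycling = NULL, c_min = 0.2, prominence_min = 0.05,
                          boundaries = NULL) {
  if (is.null(boundaries)) boundaries <- ref$boundaries
  if (is.null(query$lognorm)) query <- log_normalize(query)
  cells <- cell_ids(query)
  status <- setNames(rep("aligned", length(cells)), cells)
  if (!is.null(cycling)) {
    cyc <- names(cycling)[cycling]
    status[intersect(cyc, cells)] <- "cycling"
  }
  noncyc <- names(status)[status != "cycling"]
  sub <- expression_matrix(query$counts[, noncyc, drop = FALSE],
                           query$lognorm[, noncyc, drop = FALSE])
  sim <- similarity_profiles(sub, binned, genes)
  ood <- flag_out_of_distribution(sim, c_min, prominence_min)
  status[names(sim$degenerate)[sim$degenerate]] <- "degenerate"
  ood_cells <- names(ood)[!is.na(ood) & ood]
  status[setdiff(ood_cells, names(status)[status == "degenerate"])] <-
    "out_of_distribution"
  sim <- normalize_profiles(sim)
  pt_all <- predict_pseudotime(model, sim)
  pt <- setNames(rep(NA_real_, length(cells)), cells)
  aligned <- names(status)[status == "aligned"]
  pt[aligned] <- pt_all[aligned]
  stg <- assign_stages(pt, boundaries)
  out <- tibble(
    cell_id = cells,
    pseudotime = as.numeric(pt),
    stage = stg$stage,
    dormant = stg$dormant,
    status = factor(status, levels = c("aligned", "cycling",
                                       "out_of_distribution", "degenerate"))
  )
  class(out) <- c("ptalign_alignment", class(out))
  out
}

#' QAD stage composition of an alignment
#'
#' Fractions of aligned cells per stage, optionally with cycling cells as a
#' fourth category. Out-of-distribution and degenerate cells never enter the
#' denominator.
#'
#' @param result a [ptalign_align()] tibble (or any tibble with `stage` and
#'   `status` columns).
#' @param include_cycling add a `cycling` component.
#' @return Named numeric vector over `Q`, `A`, `D` (and `cycling`) summing
#'   to 1.
#' @export
stage_composition <- function(result, include_cycling = FALSE) {
  aligned <- result$status == "aligned"
  n_cyc <- sum(result$status == "cycling")
  counts <- table(factor(result$stage[aligned], levels = c("Q", "A", "D")))
  denom <- sum(counts) + if (include_cycling) n_cyc else 0
  if (denom == 0) stop("no aligned (or cycling) cells to compose")
  out <- as.numeric(counts) / denom
  names(out) <- c("Q", "A", "D")
  if (include_cycling) out <- c(out, cycling = n_cyc / denom)
  out
}

#' Aitchison distance between compositions
#'
#' Euclidean distance between centered-log-ratio transforms. Zero components
#' are replaced by `pseudofraction` and the composition renormalized before
#' the transform.
#'
#' @param x,y non-negative compositions of equal length (>= 2) summing to 1.
#' @param pseudofraction replacement for zero components.
#' @return Non-negative scalar; symmetric in `x` and `y`.
#' @export
aitchison_distance <- function(x, y, pseudofraction = 1e-6) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2) {
    stop("compositions must have equal length >= 2")
  }
  if (any(x < 0) || any(y < 0)) stop("compositions must be non-negative")
  clr <- function(v) {
    v[v == 0] <- pseudofraction
    v <- v / sum(v)
    lv <- log(v)
    lv - mean(lv)
  }
  sqrt(sum((clr(x) - clr(y))^2))
}

#' Write an alignment to TSV
#'
#' @param result a [ptalign_align()] tibble.
#' @param path output TSV path.
#' @export
write_alignment <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
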