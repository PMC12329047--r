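#' Configuration for the synthetic lineage generator
#'
#' Describes a non-branching lineage emulating an adult stem-cell niche:
#' cells ordered by a latent pseudotime with stage-localized Gaussian-bump
#' gene programs for trajectory-informative genes, flat baselines for noise
#' genes, negative-binomial count noise with log-normal library-size
#' variation, a cycling subpopulation with an added G2/M program, optional
#' out-of-distribution cells (per-gene marginals preserved, cross-gene
#' structure destroyed), and optional dysregulated genes whose bump centers
#' are shifted in query samples.
#'
#' @param n_cells cells per generated dataset (default 2000).
#' @param n_genes total genes (default 300).
#' @param n_traj_genes trajectory-informative panel genes (default 150).
#' @param n_dynamic_genes pseudotime-dependent genes outside the trajectory
#'   panel (default 0); dysregulated genes are drawn from these, mirroring
#'   real transcriptomes where most dynamic genes are not in the alignment
#'   panel.
#' @param n_g2m_genes genes carrying the cycling program (taken from the
#'   noise genes; default 20).
#' @param pt_weights stage mixture weights (Q, A, D) of the pseudotime
#'   density (default `c(0.45, 0.3, 0.25)`, quiescence-heavy like a
#'   homeostatic niche).
#' @param amplitude,width,baseline ranges (`c(lo, hi)`) of the bump programs.
#' @param noise_baseline baseline range of the non-informative genes; spans
#'   the trajectory genes' expression range so expression-matched gene
#'   sampling has a pool in every decile.
#' @param weak_trend_frac fraction of noise genes carrying a weak
#'   low-amplitude pseudotime trend (real transcriptomes are not flat outside
#'   the trajectory program; these genes form the flat tail of importance
#'   rankings).
#' @param weak_amplitude amplitude range of the weak trends.
#' @param dispersion negative-binomial size parameter (default 2).
#' @param lib_sigma sd of the log-normal library-size factor (default 0.3).
#' @param depth mean counts per cell scale (default 2000).
#' @param cycling_fraction fraction of cells given the G2/M program.
#' @param ood_fraction fraction of query cells drawn out-of-distribution.
#' @param n_dysregulated trajectory genes with shifted programs in queries.
#' @param dys_shift pseudotime shift applied to dysregulated bump centers.
#' @param boundaries stage boundaries used for stage-conditional sampling.
#' @param seed mandatory integer seed.
#' @return A `ptx_synth_config` list.
#' @export
synth_config <- function(n_cells = 2000, n_genes = 300, n_traj_genes = 150,
                         n_dynamic_genes = 0, n_g2m_genes = 20,
                         pt_weights = c(Q = 0.45, A = 0.3, D = 0.25),
                         amplitude = c(3, 8), width = c(0.08, 0.2),
                         baseline = c(0.1, 0.5), noise_baseline = c(0.02, 1),
                         weak_trend_frac = 0.3, weak_amplitude = c(0.2, 0.8),
                         dispersion = 2,
                         lib_sigma = 0.3, depth = 2000,
                         cycling_fraction = 0.1, ood_fraction = 0,
                         n_dysregulated = 0, dys_shift = 0.45,
                         boundaries = stage_boundaries(), seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (n_traj_genes + n_dynamic_genes > n_genes) {
    stop("n_traj_genes + n_dynamic_genes must be <= n_genes")
  }
  fracs <- c(cycling_fraction, ood_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0,1]")
  if (any(pt_weights < 0) || sum(pt_weights) <= 0) {
    stop("pt_weights must be non-negative with positive sum")
  }
  structure(
    list(n_cells = n_cells, n_genes = n_genes, n_traj_genes = n_traj_genes,
         n_dynamic_genes = n_dynamic_genes,
         n_g2m_genes = min(n_g2m_genes,
                           n_genes - n_traj_genes - n_dynamic_genes),
         pt_weights = pt_weights / sum(pt_weights),
         amplitude = amplitude, width = width, baseline = baseline,
         noise_baseline = noise_baseline,
         weak_trend_frac = weak_trend_frac, weak_amplitude = weak_amplitude,
         dispersion = dispersion, lib_sigma = lib_sigma, depth = depth,
         cycling_fraction = cycling_fraction, ood_fraction = ood_fraction,
         n_dysregulated = n_dysregulated, dys_shift = dys_shift,
         boundaries = boundaries, seed = as.integer(seed)),
    class = "ptx_synth_config"
  )
}

# deterministic gene program table for a config (independent of cell draws)
synth_programs <- function(config) {
  with_local_seed(config$seed, {
    n_traj <- config$n_traj_genes
    n_dyn <- config$n_dynamic_genes
    n_noise <- config$n_genes - n_traj - n_dyn
    genes <- c(sprintf("TRAJ%03d", seq_len(n_traj)),
               if (n_dyn > 0) sprintf("DYN%03d", seq_len(n_dyn)),
               if (n_noise > 0) sprintf("NOISE%03d", seq_len(n_noise)))
    # trajectory panel: stage-localized bump centers, round-robin over the
    # stage intervals, placed in the interior so each gene is unambiguously
    # stage-specific
    b <- config$boundaries
    iv <- list(Q = c(0, b$b_qa), A = c(b$b_qa, b$b_ad), D = c(b$b_ad, 1))
    gene_stage_idx <- rep_len(1:3, n_traj)
    centers_traj <- vapply(seq_len(n_traj), function(k) {
      lohi <- iv[[gene_stage_idx[k]]]
      pad <- 0.12 * diff(lohi)
      pos <- seq(lohi[1] + pad, lohi[2] - pad,
                 length.out = max(1, sum(gene_stage_idx == gene_stage_idx[k])))
      pos[sum(gene_stage_idx[seq_len(k)] == gene_stage_idx[k])]
    }, numeric(1))
    # dynamic off-panel genes: full-strength bumps spread over pseudotime
    centers_dyn <- if (n_dyn > 0) seq(0.05, 0.95, length.out = n_dyn) else numeric()
    # weakly trended noise genes: low-amplitude bumps anywhere in [0,1]
    n_weak <- round(config$weak_trend_frac * n_noise)
    weak_idx <- if (n_weak > 0) {
      n_traj + n_dyn + sample.int(n_noise, n_weak)
    } else {
      integer()
    }
    centers <- c(centers_traj, centers_dyn, rep(NA_real_, n_noise))
    widths <- c(runif(n_traj + n_dyn, config$width[1], config$width[2]),
                rep(NA_real_, n_noise))
    # log-uniform amplitudes: expression effect sizes spread over orders of
    # magnitude, which also spreads panel genes across expression deciles
    amps <- c(exp(runif(n_traj + n_dyn, log(config$amplitude[1]),
                        log(config$amplitude[2]))),
              rep(0, n_noise))
    if (n_weak > 0) {
      centers[weak_idx] <- runif(n_weak)
      widths[weak_idx] <- runif(n_weak, config$width[1], config$width[2])
      amps[weak_idx] <- runif(n_weak, config$weak_amplitude[1],
                              config$weak_amplitude[2])
    }
    # flat noise genes: a third at the marginal mean level of a bump program
    # so every expression decile of the trajectory genes has non-trajectory
    # genes to draw from, the rest low-expressed (bulk of a transcriptome);
    # weak-trend genes sit on trajectory-like low baselines
    n_matched <- round(0.4 * n_noise)
    marginal_hi <- config$baseline[2] + config$amplitude[2] *
      config$width[2] * sqrt(2 * pi)
    matched_base <- exp(runif(n_matched, log(0.2), log(marginal_hi)))
    low_base <- exp(runif(n_noise - n_matched, log(config$noise_baseline[1]),
                          log(config$noise_baseline[2])))
    base <- c(runif(n_traj + n_dyn, config$baseline[1], config$baseline[2]),
              matched_base, low_base)
    if (n_weak > 0) {
      base[weak_idx] <- runif(n_weak, config$baseline[1], config$baseline[2])
    }
    g2m <- rep(FALSE, config$n_genes)
    if (config$n_g2m_genes > 0 && n_noise > 0) {
      g2m[n_traj + n_dyn + seq_len(config$n_g2m_genes)] <- TRUE
    }
    # dysregulated genes are drawn from the off-panel dynamic genes when
    # present (the ranking pipeline excludes the panel itself)
    dys <- rep(FALSE, config$n_genes)
    if (config$n_dysregulated > 0) {
      if (n_dyn > 0) {
        dys[n_traj + sample.int(n_dyn, min(config$n_dysregulated, n_dyn))] <- TRUE
      } else {
        dys[sample.int(n_traj, min(config$n_dysregulated, n_traj))] <- TRUE
      }
    }
    stage <- rep(NA_character_, config$n_genes)
    with_center <- !is.na(centers)
    stage[with_center] <- ifelse(
      centers[with_center] < b$b_qa, "Q",
      ifelse(centers[with_center] <= b$b_ad, "A", "D")
    )
    tibble(gene = genes, center = centers, width = widths, amplitude = amps,
           baseline = base,
           informative = rep(c(TRUE, FALSE), c(n_traj, n_dyn + n_noise)),
           dynamic = rep(c(FALSE, TRUE, FALSE), c(n_traj, n_dyn, n_noise)),
           g2m = g2m, dysregulated = dys, stage = stage)
  })
}

# shift a dysregulated center away from whichever boundary leaves room, so
# the full effect size lands inside the pseudotime range
shifted_center <- function(center, shift) {
  ifelse(center + shift <= 0.95, center + shift, center - shift)
}

program_mean <- function(programs, pt, shift_dys = 0) {
  mu <- matrix(rep(programs$baseline, length(pt)), nrow = nrow(programs))
  inf_idx <- which(!is.na(programs$center))
  centers <- ifelse(programs$dysregulated[inf_idx],
                    shifted_center(programs$center[inf_idx], shift_dys),
                    programs$center[inf_idx])
  for (k in seq_along(inf_idx)) {
    g <- inf_idx[k]
    mu[g, ] <- mu[g, ] + programs$amplitude[g] *
      exp(-(pt - centers[k])^2 / (2 * programs$width[g]^2))
  }
  mu
}

sample_stage_pt <- function(n, weights, boundaries) {
  edges <- list(Q = c(0, boundaries$b_qa),
                A = c(boundaries$b_qa, boundaries$b_ad),
                D = c(boundaries$b_ad, 1))
  stage <- sample(names(edges), n, replace = TRUE, prob = weights)
  pt <- vapply(stage, function(s) runif(1, edges[[s]][1], edges[[s]][2]),
               numeric(1))
  list(pt = unname(pt), stage = stage)
}

draw_counts <- function(mu, config) {
  n_cells <- ncol(mu)
  lib <- exp(rnorm(n_cells, 0, config$lib_sigma))
  scale <- config$depth / mean(colSums(mu))
  lam <- sweep(mu * scale, 2, lib, `*`)
  counts <- matrix(
    if (config$dispersion > 0) {
      stats::rnbinom(length(lam), mu = as.numeric(lam),
                     size = config$dispersion)
    } else {
      round(as.numeric(lam))
    },
    nrow = nrow(mu)
  )
  counts
}

#' Generate a synthetic reference lineage with ground truth
#'
#' @param config a [synth_config()].
#' @return List with `reference` (a [reference_lineage()]) and `truth`
#'   (list of tibbles `cells` and `genes`).
#' @export
make_reference <- function(config) {
  programs <- synth_programs(config)
  with_local_seed(config$seed + 1L, {
    n <- config$n_cells
    sp <- sample_stage_pt(n, config$pt_weights, config$boundaries)
    pt <- sp$pt
    cycling <- runif(n) < config$cycling_fraction
    mu <- program_mean(programs, pt)
    if (any(cycling) && any(programs$g2m)) {
      mu[programs$g2m, cycling] <- mu[programs$g2m, cycling] * 8
    }
    counts <- draw_counts(mu, config)
    dimnames(counts) <- list(programs$gene, sprintf("ref_cell%05d", seq_len(n)))
    zero <- colSums(counts) == 0
    if (any(zero)) counts[1, zero] <- 1L  # guard: every cell has signal
    x <- log_normalize(expression_matrix(counts))
    pt_named <- setNames(pt, colnames(counts))[!cycling]
    ref <- reference_lineage(x, pt_named,
                             cycling = setNames(cycling, colnames(counts)),
                             boundaries = config$boundaries)
    truth_cells <- tibble(
      cell_id = colnames(counts), pseudotime = pt, cycling = cycling,
      ood = FALSE, stage = sp$stage
    )
    list(reference = ref, truth = list(cells = truth_cells, genes = programs))
  })
}

#' Generate a synthetic query sample
#'
#' Query cells are drawn from the reference generative process with
#' stage-composition reweighting; dysregulated genes use shifted programs;
#' out-of-distribution cells are assembled gene-by-gene from independent
#' pseudotimes so each gene's marginal is preserved but the cross-gene
#' trajectory structure is destroyed.
#'
#' @param config a [synth_config()]; its `seed` fixes the gene programs
#'   (the shared "universe"), so samples from the same config share programs.
#' @param composition `(Q, A, D)` stage weights summing to 1.
#' @param shift global expression scale factor (default 1).
#' @param ood_fraction overrides `config$ood_fraction` when not `NULL`.
#' @param n_cells overrides `config$n_cells` when not `NULL`.
#' @param sample_seed seed of this sample's cell draws (distinct samples of
#'   the same universe use distinct sample seeds).
#' @param dys_shift overrides `config$dys_shift`; set 0 to draw a healthy
#'   sample in which the dysregulated genes keep their reference programs.
#' @return List with `query` (a `ptx_expr`) and `truth` (tibbles `cells`,
#'   `genes`).
#' @export
make_query_sample <- function(config, composition = c(1, 1, 1) / 3, shift = 1,
                              ood_fraction = NULL, n_cells = NULL,
                              sample_seed = config$seed + 2L,
                              dys_shift = config$dys_shift) {
  if (abs(sum(composition) - 1) > 1e-6) stop("composition must sum to 1")
  if (is.null(ood_fraction)) ood_fraction <- config$ood_fraction
  if (is.null(n_cells)) n_cells <- config$n_cells
  programs <- synth_programs(config)
  with_local_seed(sample_seed, {
    sp <- sample_stage_pt(n_cells, composition, config$boundaries)
    pt <- sp$pt
    cycling <- runif(n_cells) < config$cycling_fraction
    ood <- !cycling & runif(n_cells) < ood_fraction
    mu <- program_mean(programs, pt, shift_dys = dys_shift)
    if (any(ood)) {
      centers <- ifelse(programs$dysregulated & !is.na(programs$center),
                        shifted_center(programs$center, dys_shift),
                        programs$center)
      for (i in which(ood)) {
        pt_ind <- runif(nrow(programs))
        bump <- ifelse(
          !is.na(programs$center),
          programs$amplitude *
            exp(-(pt_ind - centers)^2 / (2 * programs$width^2)),
          0
        )
        mu[, i] <- programs$baseline + ifelse(is.na(bump), 0, bump)
      }
    }
    if (any(cycling) && any(programs$g2m)) {
      mu[programs$g2m, cycling] <- mu[programs$g2m, cycling] * 8
    }
    mu <- mu * shift
    counts <- draw_counts(mu, config)
    dimnames(counts) <- list(programs$gene, sprintf("q_cell%05d", seq_len(n_cells)))
    zero <- colSums(counts) == 0
    if (any(zero)) counts[1, zero] <- 1L
    query <- log_normalize(expression_matrix(counts))
    truth_cells <- tibble(
      cell_id = colnames(counts), pseudotime = pt, cycling = cycling,
      ood = ood, stage = sp$stage
    )
    list(query = query, truth = list(cells = truth_cells, genes = programs))
  })
}

#' Generate a cohort of query samples along a composition spectrum
#'
#' Samples are spaced from a Q-dominated to a D-dominated stage composition,
#' emulating the compositional spread of a tumor cohort; per-sample seeds are
#' derived from the master seed.
#'
#' @param n_samples number of samples (>= 2).
#' @param config a [synth_config()] (master seed).
#' @param q_end,d_end compositions at the two ends of the spectrum.
#' @param ... passed to [make_query_sample()].
#' @return List with `samples` (list of `make_query_sample()` results) and
#'   `compositions` (tibble).
#' @export
make_cohort <- function(n_samples, config,
                        q_end = c(0.7, 0.2, 0.1), d_end = c(0.1, 0.2, 0.7),
                        ...) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  alphas <- seq(0, 1, length.out = n_samples)
  samples <- lapply(seq_len(n_samples), function(i) {
    comp <- (1 - alphas[i]) * q_end + alphas[i] * d_end
    comp <- comp / sum(comp)
    out <- make_query_sample(
      config, composition = comp,
      sample_seed = (config$seed + 1009L * i) %% .Machine$integer.max, ...
    )
    out$composition <- comp
    out
  })
  comp_tbl <- dplyr::bind_rows(lapply(seq_len(n_samples), function(i) {
    tibble(sample = i, Q = samples[[i]]$composition[1],
           A = samples[[i]]$composition[2], D = samples[[i]]$composition[3])
  }))
  list(samples = samples, compositions = comp_tbl)
}

#' Write a generated dataset to disk (MTX + TSV + truth sidecar)
#'
#' @param x a `ptx_expr`.
#' @param truth truth list from the generator.
#' @param dir output directory (created).
#' @export
write_synth <- function(x, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(x$counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(as.data.frame(truth$cells),
                     file.path(dir, "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(truth$genes),
                     file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
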