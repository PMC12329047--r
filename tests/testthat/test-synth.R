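test_that("generation is deterministic and produces valid count matrices", {
  cfg <- synth_config(n_cells = 120, n_genes = 80, n_traj_genes = 20,
                      seed = 51)
  r1 <- make_reference(cfg)
  r2 <- make_reference(cfg)
  expect_identical(as.matrix(r1$reference$matrix$counts),
                   as.matrix(r2$reference$matrix$counts))
  cnt <- as.matrix(r1$reference$matrix$counts)
  expect_true(all(cnt >= 0))
  expect_true(all(cnt == round(cnt)))
  expect_true(all(colSums(cnt) > 0))
  # truth covers every cell and gene
  expect_equal(nrow(r1$truth$cells), 120)
  expect_equal(nrow(r1$truth$genes), 80)
  # cycling cells carry no pseudotime in the lineage
  cyc <- r1$truth$cells$cell_id[r1$truth$cells$cycling]
  expect_false(any(cyc %in% names(r1$reference$pseudotime)))
  expect_error(synth_config(n_cells = 10, n_genes = 5, n_traj_genes = 8,
                            seed = 1), "<=")
  expect_error(synth_config(seed = 1, cycling_fraction = 1.5), "fractions")
})

test_that("the zero-dispersion limit reproduces the program means", {
  cfg <- synth_config(n_cells = 60, n_genes = 40, n_traj_genes = 10,
                      dispersion = 0, lib_sigma = 0, cycling_fraction = 0,
                      seed = 52)
  ro <- make_reference(cfg)
  programs <- ro$truth$genes
  pt <- ro$truth$cells$pseudotime
  mu <- ptalign:::program_mean(programs, pt)
  scale <- cfg$depth / mean(colSums(mu))
  expect_equal(unname(as.matrix(ro$reference$matrix$counts)),
               unname(round(mu * scale)))
})

test_that("informative bin means track the planted program curve", {
  cfg <- synth_config(n_cells = 3000, n_genes = 60, n_traj_genes = 20,
                      cycling_fraction = 0, seed = 53)
  ro <- make_reference(cfg)
  programs <- ro$truth$genes
  g <- programs$gene[which(programs$informative)[1]]
  counts <- as.matrix(ro$reference$matrix$counts)[g, ]
  pt <- ro$truth$cells$pseudotime
  mu <- ptalign:::program_mean(programs, pt)
  scale <- cfg$depth / mean(colSums(mu))
  lam <- mu[match(g, programs$gene), ] * scale
  # binned count means stay within 3 standard errors of the NB mean
  bins <- cut(pt, seq(0, 1, 0.1), include.lowest = TRUE)
  obs <- tapply(counts, bins, mean)
  expected <- tapply(lam, bins, mean)
  n_per <- tapply(lam, bins, length)
  se <- sqrt(tapply(lam + lam^2 / cfg$dispersion, bins, mean) / n_per)
  expect_true(all(abs(obs - expected) <= 3.5 * se))
})

test_that("query samples honour composition, OOD and dysregulation requests", {
  cfg <- synth_config(n_cells = 300, n_genes = 120, n_traj_genes = 30,
                      n_dynamic_genes = 20, n_dysregulated = 5,
                      cycling_fraction = 0, seed = 54)
  q <- make_query_sample(cfg, composition = c(1, 0, 0))
  expect_true(all(q$truth$cells$pseudotime < cfg$boundaries$b_qa))
  expect_false(any(q$truth$cells$ood))

  q2 <- make_query_sample(cfg, composition = c(0.3, 0.4, 0.3),
                          ood_fraction = 0.4, sample_seed = 999)
  expect_gt(mean(q2$truth$cells$ood), 0.2)

  # the dysregulated gene's bin-mean curve peaks at the shifted center
  dys <- q$truth$genes[q$truth$genes$dysregulated, ][1, ]
  qd <- make_query_sample(cfg, composition = c(1, 1, 1) / 3,
                          n_cells = 4000, sample_seed = 1234)
  hd <- make_query_sample(cfg, composition = c(1, 1, 1) / 3,
                          n_cells = 4000, sample_seed = 1234, dys_shift = 0)
  bins <- seq(0.025, 0.975, by = 0.05)
  curve_of <- function(s) {
    cnt <- as.matrix(s$query$counts)[dys$gene, ]
    b <- cut(s$truth$cells$pseudotime, seq(0, 1, 0.05), include.lowest = TRUE)
    tapply(cnt, b, mean)
  }
  peak_q <- bins[which.max(curve_of(qd))]
  peak_h <- bins[which.max(curve_of(hd))]
  shifted <- ptalign:::shifted_center(dys$center, cfg$dys_shift)
  expect_lt(abs(peak_h - dys$center), 0.1)
  expect_lt(abs(peak_q - shifted), 0.1)
})

test_that("cohorts span the requested composition spectrum", {
  cfg <- synth_config(n_cells = 150, n_genes = 80, n_traj_genes = 20,
                      cycling_fraction = 0, seed = 55)
  co <- make_cohort(4, cfg)
  comp <- co$compositions
  expect_gt(comp$Q[1], comp$D[1])  # Q-dominated end
  expect_gt(comp$D[4], comp$Q[4])  # D-dominated end
  # distinct per-sample seeds give distinct samples
  c1 <- as.matrix(co$samples[[1]]$query$counts)
  c2 <- as.matrix(co$samples[[2]]$query$counts)
  expect_false(identical(c1, c2))
  # realized stage mix tracks the requested spectrum mean
  realized <- vapply(co$samples, function(s) {
    mean(s$truth$cells$stage == "Q")
  }, numeric(1))
  expect_equal(mean(realized), mean(comp$Q), tolerance = 0.08)
  expect_error(make_cohort(1, cfg), ">= 2")
})
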