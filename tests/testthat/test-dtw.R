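test_that("self-correlation puts ones on the diagonal of the DTW matrix", {
  u <- small_universe()
  ref <- u$ref
  # query = the reference itself, binned with the reference pseudotime
  q <- expression_matrix(ref$matrix$counts, ref$matrix$lognorm)
  m <- dtw_matrix(u$binned, q, ref$pseudotime, min_cells_per_bin = 5)
  shared <- intersect(colnames(u$binned$bin_means),
                      sub("^qbin", "bin", colnames(m)))
  for (bn in shared) {
    i <- match(bn, colnames(u$binned$bin_means))
    j <- match(sub("^bin", "qbin", bn), colnames(m))
    expect_equal(m[i, j], 1)
  }
  expect_true(all(m >= -1 - 1e-12 & m <= 1 + 1e-12))
})

test_that("cyclically shifted query bins shift the per-row argmax", {
  u <- small_universe()
  b <- u$binned
  genes <- b$genes
  B <- ncol(b$bin_means)
  k <- 3L
  # craft query cells whose expression at bin j equals the reference mean of
  # bin (j + k) mod B; each query bin gets 6 identical cells
  cells_per <- 6L
  ln <- NULL; ids <- NULL; pts <- NULL
  for (j in seq_len(B)) {
    src <- ((j - 1L + k) %% B) + 1L
    ln <- cbind(ln, matrix(rep(b$bin_means[, src], cells_per),
                           ncol = cells_per))
    ids <- c(ids, sprintf("s%02d_%d", j, seq_len(cells_per)))
    pts <- c(pts, rep(b$bin_centers[j], cells_per))
  }
  dimnames(ln) <- list(genes, ids)
  q <- expression_matrix(toy_counts(matrix(1L, nrow(ln), ncol(ln)), genes, ids), ln)
  m <- dtw_matrix(u$binned, q, setNames(pts, ids), min_cells_per_bin = 3)
  argmax <- apply(m, 1, which.max)
  expected <- ((seq_len(B) - 1L - k) %% B) + 1L  # ref bin i peaks at query bin i - k
  expect_gte(mean(argmax == expected), 0.9)
})

test_that("traceback equals exhaustive enumeration and honours tie-breaks", {
  # identity-like matrix: diagonal path, perfect mean correlation
  idm <- matrix(-1, 5, 5); diag(idm) <- 1
  d <- traceback_max_correlation(idm)
  expect_equal(d$path[, 1], 1:5)
  expect_equal(d$path[, 2], 1:5)
  expect_equal(d$mean_corr, 1)
  expect_equal(d$path_length, 5)

  # hand-set 3x3 against brute-force enumeration
  m3 <- matrix(c(0.9, -0.2, 0.1,
                 0.3, 0.8, -0.5,
                 -0.4, 0.2, 0.7), 3, 3, byrow = TRUE)
  d3 <- traceback_max_correlation(m3)
  expect_equal(d3$cost, brute_force_dtw(m3))

  # constant matrix: diagonal by tie-break, zero diagonal deviation
  dc <- traceback_max_correlation(matrix(0.5, 4, 4))
  expect_equal(dc$path[, 1], dc$path[, 2])
  expect_equal(dc$diag_deviation, 0)

  expect_error(traceback_max_correlation(matrix(c(1, NA, 0, 1), 2, 2)),
               "finite")
})

test_that("traceback score never falls below the plain diagonal path", {
  set.seed(12)
  for (i in 1:20) {
    m <- matrix(runif(36, -1, 1), 6, 6)
    d <- traceback_max_correlation(m)
    expect_gte(d$score, sum(diag(m)))
    # monotone steps only
    steps <- diff(d$path)
    expect_true(all(steps >= 0) && all(rowSums(steps) >= 1))
    expect_gte(d$path_length, 6)
    expect_equal(d$mean_corr, sum(m[d$path]) / d$path_length)
  }
})

test_that("permutation p-values follow the add-one rule and bounds", {
  u <- small_universe()
  q <- u$query$query
  pr <- permutation_pvalue(q, u$ref, u$traj, n_perm = 19, seed = 3,
                           n_bins = 15, min_cells_per_bin = 5, epochs = 60)
  expect_equal(pr$p_value,
               (1 + sum(pr$permuted >= pr$observed, na.rm = TRUE)) /
                 (1 + sum(is.finite(pr$permuted))))
  expect_gte(pr$p_value, 1 / (pr$n_perm + 1))
  expect_lte(pr$p_value, 1)
  # an in-distribution query beats all 19 permutations: p = 1/20 exactly
  expect_equal(pr$p_value, 0.05)
  expect_error(permutation_pvalue(q, u$ref, u$traj, n_perm = 5, seed = 1),
               ">= 19")
})

test_that("pseudotime coherence tracks expression geometry and its rank invariance", {
  # 1-D structured data: expression drifts monotonically along pseudotime
  set.seed(13)
  n <- 120; g <- 40
  t <- sort(runif(n))
  ln <- outer(seq_len(g) / g, t, function(a, b) 5 * a * b) +
    matrix(rnorm(g * n, 0, 0.1), g, n)
  ln <- pmax(ln, 0)
  dimnames(ln) <- list(sprintf("G%02d", 1:g), sprintf("c%03d", 1:n))
  x <- expression_matrix(toy_counts(matrix(1L, g, n), rownames(ln),
                                    colnames(ln)), ln)
  pt <- setNames(t, colnames(ln))
  coh <- pseudotime_coherence(x, pt)
  expect_gt(coh, 0.8)
  # direct recomputation oracle
  pcs <- prcomp(t(ln), rank. = 10)$x
  oracle <- cor(as.numeric(dist(pcs)), as.numeric(dist(rank(pt))))
  expect_equal(coh, oracle)
  # invariance under strictly monotone transforms
  expect_equal(pseudotime_coherence(x, pt^3), coh)
  # shuffled pseudotime decorrelates
  set.seed(14)
  expect_lt(abs(pseudotime_coherence(x, setNames(sample(t), names(pt)))), 0.25)
  expect_error(pseudotime_coherence(x, setNames(rep(0.5, n), names(pt))),
               "constant")
})
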