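test_that("end-to-end alignment labels every cell with one status", {
  u <- small_universe()
  q <- u$query
  cyc <- setNames(q$truth$cells$cycling, q$truth$cells$cell_id)
  aln <- ptalign_align(q$query, u$ref, u$binned, u$model, cycling = cyc)
  expect_equal(nrow(aln), ncol(q$query$counts))
  # cycling cells are never aligned
  expect_true(all(aln$status[aln$cell_id %in% names(cyc)[cyc]] == "cycling"))
  # stage assigned iff aligned
  expect_true(all(!is.na(aln$stage[aln$status == "aligned"])))
  expect_true(all(is.na(aln$stage[aln$status != "aligned"])))
  ok <- aln$status == "aligned"
  truth <- q$truth$cells
  expect_gte(cor(aln$pseudotime[ok], truth$pseudotime[ok]), 0.9)
  expect_gte(mean(as.character(aln$stage[ok]) == truth$stage[ok]), 0.85)
})

test_that("alignment is invariant to gene and cell order", {
  u <- small_universe()
  q <- u$query$query
  aln1 <- ptalign_align(q, u$ref, u$binned, u$model)
  set.seed(5)
  gperm <- sample(nrow(q$counts)); cperm <- sample(ncol(q$counts))
  q2 <- expression_matrix(q$counts[gperm, cperm], q$lognorm[gperm, cperm])
  aln2 <- ptalign_align(q2, u$ref, u$binned, u$model)
  merged <- merge(aln1, aln2, by = "cell_id")
  expect_identical(merged$pseudotime.x, merged$pseudotime.y)
  expect_identical(as.character(merged$status.x), as.character(merged$status.y))
})

test_that("adding out-of-distribution cells leaves other alignments untouched", {
  u <- small_universe()
  q <- u$query$query
  aln1 <- ptalign_align(q, u$ref, u$binned, u$model)
  cnt <- as.matrix(q$counts)
  set.seed(6)
  noise <- apply(cnt[, 1:40], 2, sample)
  dimnames(noise) <- list(rownames(cnt), sprintf("noise%02d", 1:40))
  q2 <- log_normalize(expression_matrix(cbind(cnt, noise)))
  aln2 <- ptalign_align(q2, u$ref, u$binned, u$model)
  shared <- intersect(aln1$cell_id, aln2$cell_id)
  pt1 <- setNames(aln1$pseudotime, aln1$cell_id)[shared]
  pt2 <- setNames(aln2$pseudotime, aln2$cell_id)[shared]
  expect_true(all(abs(pt1 - pt2) < 1e-12, na.rm = TRUE))
  expect_identical(is.na(pt1), is.na(pt2))
})

test_that("stage composition counts the right denominators", {
  res <- tibble::tibble(
    stage = factor(c(rep("Q", 10), rep("A", 10)), levels = c("Q", "A", "D")),
    status = factor(rep("aligned", 20),
                    levels = c("aligned", "cycling", "out_of_distribution",
                               "degenerate"))
  )
  expect_equal(unname(stage_composition(res)), c(0.5, 0.5, 0))

  res2 <- tibble::tibble(
    stage = factor(c(rep("Q", 8), rep("A", 8), rep("D", 4),
                     rep(NA, 4)), levels = c("Q", "A", "D")),
    status = factor(c(rep("aligned", 20), rep("cycling", 4))[1:24],
                    levels = c("aligned", "cycling", "out_of_distribution",
                               "degenerate"))
  )
  res2$status[21:24] <- "cycling"
  comp <- stage_composition(res2, include_cycling = TRUE)
  expect_equal(unname(comp), c(1 / 3, 1 / 3, 1 / 6, 1 / 6))
  expect_equal(sum(comp), 1, tolerance = 1e-9)
  # OOD cells never enter the denominator
  res3 <- res
  res3$status[1:5] <- "out_of_distribution"
  expect_equal(sum(stage_composition(res3)), 1, tolerance = 1e-9)
  res_empty <- res
  res_empty$status[] <- "out_of_distribution"
  expect_error(stage_composition(res_empty), "no aligned")
})

test_that("Aitchison distance matches its closed form and is symmetric", {
  x <- c(0.7, 0.2, 0.1); y <- c(0.1, 0.2, 0.7)
  # independent evaluation of the CLR formula
  clr <- function(v) log(v) - mean(log(v))
  expect_equal(aitchison_distance(x, y), sqrt(sum((clr(x) - clr(y))^2)))
  expect_equal(aitchison_distance(x, x), 0)
  set.seed(8)
  for (i in 1:10) {
    a <- runif(4); a <- a / sum(a)
    b <- runif(4); b <- b / sum(b)
    expect_equal(aitchison_distance(a, b), aitchison_distance(b, a))
  }
  # zero components go through the pseudofraction path
  expect_true(is.finite(aitchison_distance(c(0.5, 0.5, 0), c(0.2, 0.3, 0.5))))
  expect_error(aitchison_distance(c(-0.1, 1.1), c(0.5, 0.5)), "non-negative")
})
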