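test_that("the pseudotime grid is uniform and covers [0,1]", {
  g <- pseudotime_grid()
  expect_equal(g[1], 0)
  expect_equal(g[length(g)], 1)
  expect_true(all(abs(diff(g) - 0.05) < 1e-12))
  expect_error(pseudotime_grid(0.3), "multiple")
})

test_that("spline fitting reproduces constants and respects the bin floor", {
  set.seed(21)
  pt <- runif(2000)
  sp <- fit_expression_spline(pt, rep(2.5, 2000))
  expect_true(all(abs(sp$values - 2.5) < 1e-6))
  expect_equal(sp$area, 2.5, tolerance = 1e-6)
  expect_true(sp$expressed)
  expect_equal(simpson(sp$normalized, sp$grid), 1, tolerance = 1e-6)

  # a bin holding 19 cells is excluded from the fit
  pt2 <- c(runif(500, 0, 0.5), seq(0.96, 0.99, length.out = 19))
  sp2 <- fit_expression_spline(pt2, rexp(519), min_cells_per_bin = 20)
  last_center <- (0.95 + 1) / 2
  expect_false(any(abs(sp2$bin_centers - last_center) < 1e-9))

  # negative excursions are clipped at zero
  pt3 <- runif(3000)
  expr3 <- ifelse(pt3 > 0.45 & pt3 < 0.55, 20, 0)
  sp3 <- fit_expression_spline(pt3, expr3, smoothing = 1e-4)
  expect_true(all(sp3$values >= 0))

  expect_error(fit_expression_spline(runif(30), rexp(30),
                                     min_cells_per_bin = 20),
               "fewer than 3")
})

test_that("EMD behaves as a bounded transport metric with the loss convention", {
  a <- point_mass_spline(0.2)
  b <- point_mass_spline(0.7)
  expect_equal(emd(a, b), 0.5)
  expect_equal(emd(a, a), 0)
  expect_equal(emd(a, b), emd(b, a))

  # unexpressed genes score exactly 1 against anything
  dead <- grid_spline(rep(0, 21))
  expect_identical(emd(dead, a), 1)
  expect_identical(emd(a, dead), 1)
  expect_identical(emd(dead, dead), 1)

  # translation of a fixed shape moves the distance by the shift
  g <- pseudotime_grid()
  shape <- exp(-(g - 0.3)^2 / 0.01)
  for (delta in c(0.1, 0.25, 0.4)) {
    shifted <- exp(-(g - 0.3 - delta)^2 / 0.01)
    expect_equal(emd(grid_spline(shape), grid_spline(shifted)), delta,
                 tolerance = 0.06)
  }

  # scale invariance after area normalization
  expect_equal(emd(grid_spline(shape), grid_spline(5 * shape)), 0,
               tolerance = 1e-12)

  # triangle inequality on random curve triples
  set.seed(22)
  for (i in 1:50) {
    s <- replicate(3, grid_spline(rexp(21)), simplify = FALSE)
    d12 <- emd(s[[1]], s[[2]]); d13 <- emd(s[[1]], s[[3]])
    d23 <- emd(s[[2]], s[[3]])
    expect_lte(d12, d13 + d23 + 1e-9)
  }
  expect_error(emd(a, point_mass_spline(0.5, pseudotime_grid(0.1))), "grid")
})

test_that("mean reference curves average sample dynamics", {
  a <- point_mass_spline(0.2)
  expect_equal(mean_reference_curve(list(a))$normalized, a$normalized)
  expect_equal(mean_reference_curve(list(a, a))$normalized, a$normalized)
  b <- point_mass_spline(0.8)
  m <- mean_reference_curve(list(a, b))
  # bimodal with equal mass at both peaks
  i20 <- which.min(abs(m$grid - 0.2)); i80 <- which.min(abs(m$grid - 0.8))
  expect_equal(m$normalized[i20], m$normalized[i80])
  expect_equal(simpson(m$normalized, m$grid), 1, tolerance = 1e-9)
  dead <- grid_spline(rep(0, 21))
  expect_false(mean_reference_curve(list(dead, dead))$expressed)
})

test_that("Q-vs-D bias reflects where the curve's mass sits", {
  g <- pseudotime_grid()
  q_curve <- grid_spline(ifelse(g <= 0.25, 1, 0))
  d_curve <- grid_spline(ifelse(g >= 0.7, 1, 0))
  expect_equal(qd_bias(q_curve), 1)
  expect_equal(qd_bias(d_curve), 0)
  both <- grid_spline(ifelse(g <= 0.25 | g >= 0.73, 1, 0))
  expect_equal(qd_bias(both), 0.5, tolerance = 0.12)
  mid <- grid_spline(ifelse(g > 0.4 & g < 0.6, 1, 0))
  expect_true(is.na(qd_bias(mid)))
  expect_error(qd_bias(grid_spline(rep(0, 21))), "unexpressed")
})

test_that("area-difference ratios localize and trend with divergence", {
  g <- pseudotime_grid()
  h <- grid_spline(rep(1, 21))
  expect_equal(area_difference_ratio(h, h)$ratios$ratio, c(0, 0, 0))
  expect_equal(area_difference_ratio(h, h)$slope, 0)

  # divergence confined to late pseudotime
  late <- grid_spline(ifelse(g >= 0.7, 2, 1))
  adr <- area_difference_ratio(h, late)
  expect_gt(adr$ratios$ratio[3], adr$ratios$ratio[1])

  # steadily growing divergence gives a positive slope
  grow <- grid_spline(1 + g)
  expect_gt(area_difference_ratio(h, grow)$slope, 0)
})
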