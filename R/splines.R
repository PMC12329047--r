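#' Pseudotime evaluation grid
#'
#' Uniform grid over `[0,1]`; expression dynamics curves are evaluated and
#' compared on it.
#'
#' @param step grid spacing (default 0.05, i.e. 21 points).
#' @return Numeric vector `0, step, ..., 1`.
#' @export
pseudotime_grid <- function(step = 0.05) {
  if (step <= 0 || step > 0.5) stop("step must be in (0, 0.5]")
  n <- round(1 / step)
  if (abs(n * step - 1) > 1e-9) stop("1 must be a multiple of step")
  seq(0, 1, length.out = n + 1)
}

#' Penalized spline fit of expression over pseudotime
#'
#' Groups cells into the grid's pseudotime bins, drops bins with fewer than
#' `min_cells_per_bin` cells, and fits the per-bin mean expression with five
#' cubic B-spline basis functions under an L2 penalty on the curve's second
#' derivative. The fitted curve is evaluated on the grid, clipped at zero,
#' and its Simpson-rule area recorded; curves with positive area also carry
#' a unit-area (density) version used for transport distances.
#'
#' @param pt per-cell pseudotime in `[0,1]`.
#' @param expr per-cell expression (same length/order as `pt`).
#' @param grid a [pseudotime_grid()].
#' @param min_cells_per_bin bins with fewer cells are excluded (default 20).
#' @param smoothing weight of the second-derivative penalty (default 1).
#' @param n_basis number of B-spline basis functions (default 5).
#' @return A `ptx_spline`: `grid`, `values` (>= 0), `area`, `normalized`
#'   (unit Simpson area, or `NULL`), `expressed` (area > 0).
#' @export
fit_expression_spline <- function(pt, expr, grid = pseudotime_grid(),
                                  min_cells_per_bin = 20, smoothing = 1,
                                  n_basis = 5) {
  keep <- !is.na(pt) & !is.na(expr)
  pt <- pt[keep]; expr <- expr[keep]
  n_bins <- length(grid) - 1
  bin <- pmin(findInterval(pt, grid, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  ok_bins <- which(counts >= min_cells_per_bin)
  if (length(ok_bins) < 3) stop("fewer than 3 pseudotime bins with enough cells")
  centers <- (grid[ok_bins] + grid[ok_bins + 1]) / 2
  means <- vapply(ok_bins, function(b) mean(expr[bin == b]), numeric(1))

  basis <- spline_basis(n_basis)
  B <- basis$eval(centers)
  coefs <- solve(crossprod(B) + smoothing * basis$penalty, crossprod(B, means))
  values <- pmax(0, as.numeric(basis$eval(grid) %*% coefs))
  area <- simpson(values, grid)
  normalized <- if (area > 0) values / area else NULL
  structure(
    list(grid = grid, values = values, area = area, normalized = normalized,
         expressed = area > 0, n_basis = n_basis, smoothing = smoothing,
         bin_centers = centers, bin_means = means),
    class = "ptx_spline"
  )
}

# cubic B-spline basis on [0,1] with `n_basis` functions and the Gram matrix
# of second derivatives as the roughness penalty
spline_basis <- function(n_basis, degree = 3) {
  n_inner <- n_basis - degree - 1
  if (n_inner < 0) stop("n_basis too small for cubic splines")
  knots <- c(rep(0, degree + 1),
             if (n_inner > 0) seq(0, 1, length.out = n_inner + 2)[-c(1, n_inner + 2)],
             rep(1, degree + 1))
  eval_basis <- function(x, derivs = 0L) {
    splines::splineDesign(knots, x, ord = degree + 1,
                          derivs = rep(derivs, length(x)), outer.ok = FALSE)
  }
  fine <- seq(0, 1, length.out = 201)
  B2 <- eval_basis(fine, derivs = 2L)
  h <- fine[2] - fine[1]
  w <- simpson_weights(length(fine), h)
  penalty <- t(B2) %*% (B2 * w)
  list(eval = function(x) eval_basis(x), penalty = penalty, knots = knots)
}

simpson_weights <- function(n, h) {
  if (n %% 2 == 0) stop("Simpson rule needs an odd number of points")
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w * h / 3
}

#' Simpson-rule integral of grid values
#'
#' @param values curve values on a uniform grid with an even number of
#'   intervals.
#' @param grid the grid.
#' @return The composite-Simpson integral.
#' @export
simpson <- function(values, grid = pseudotime_grid()) {
  h <- grid[2] - grid[1]
  sum(values * simpson_weights(length(grid), h))
}

#' @export
print.ptx_spline <- function(x, ...) {
  cat(sprintf("<ptx_spline> area %.4g (%s), %d grid points\n",
              x$area, if (x$expressed) "expressed" else "unexpressed",
              length(x$grid)))
  invisible(x)
}

#' Earth Mover's Distance between expression dynamics curves
#'
#' Wasserstein-1 distance between two unit-area curves treated as densities
#' of point masses on the shared grid, computed exactly from cumulative
#' differences. Distances are bounded by 1 (the grid spans `[0,1]`). When
#' either gene/sample side is unexpressed the distance is 1 by convention —
#' loss of expression is maximal dysregulation.
#'
#' @param a,b `ptx_spline` objects on the same grid.
#' @return Distance in `[0,1]`.
#' @export
emd <- function(a, b) {
  if (!isTRUE(all.equal(a$grid, b$grid))) stop("grid mismatch between curves")
  if (!a$expressed || !b$expressed) return(1)
  wa <- a$normalized / sum(a$normalized)
  wb <- b$normalized / sum(b$normalized)
  step <- a$grid[2] - a$grid[1]
  min(1, sum(abs(cumsum(wa - wb))) * step)
}

#' Average healthy reference curve
#'
#' Pointwise mean of the expressed samples' unit-area curves, re-normalized
#' to unit area. All-unexpressed input yields an unexpressed curve.
#'
#' @param splines list of `ptx_spline` objects for one gene across samples.
#' @return A `ptx_spline` representing the mean dynamics.
#' @export
mean_reference_curve <- function(splines) {
  if (length(splines) == 0) stop("need >= 1 sample spline")
  grid <- splines[[1]]$grid
  expressed <- vapply(splines, function(s) s$expressed, logical(1))
  if (!any(expressed)) {
    return(structure(
      list(grid = grid, values = rep(0, length(grid)), area = 0,
           normalized = NULL, expressed = FALSE),
      class = "ptx_spline"
    ))
  }
  mats <- vapply(splines[expressed], function(s) s$normalized,
                 numeric(length(grid)))
  values <- rowMeans(as.matrix(mats))
  area <- simpson(values, grid)
  structure(
    list(grid = grid, values = values, area = area,
         normalized = values / area, expressed = TRUE),
    class = "ptx_spline"
  )
}

#' Quiescence-vs-differentiation expression bias
#'
#' Ratio of the curve's area over the quiescence interval `[0, b_qa]` to the
#' summed areas over quiescence and differentiation `[b_ad, 1]`. 1 means all
#' Q, 0 all D, 0.5 balanced.
#'
#' @param spline an expressed `ptx_spline`.
#' @param boundaries a [stage_boundaries()].
#' @return Value in `[0,1]`, or `NA` if both areas are zero.
#' @export
qd_bias <- function(spline, boundaries = stage_boundaries()) {
  if (!spline$expressed) stop("spline is unexpressed")
  v <- spline$normalized
  q_area <- interval_area(spline$grid, v, 0, boundaries$b_qa)
  d_area <- interval_area(spline$grid, v, boundaries$b_ad, 1)
  if (q_area + d_area == 0) return(NA_real_)
  q_area / (q_area + d_area)
}

# Simpson integral of the linear interpolant over [lo, hi]
interval_area <- function(grid, values, lo, hi) {
  xs <- seq(lo, hi, length.out = 201)
  ys <- stats::approx(grid, values, xout = xs, rule = 2)$y
  sum(ys * simpson_weights(length(xs), xs[2] - xs[1]))
}

#' Area-difference ratio across pseudotime increments
#'
#' For each pseudotime increment, integrates the absolute difference between
#' a healthy and a disease curve and divides by the maximum value attained by
#' either curve; the least-squares slope of the ratios over the increment
#' midpoints summarizes whether divergence grows along pseudotime.
#'
#' @param healthy,disease `ptx_spline` objects on the same grid (raw
#'   `values` are compared).
#' @param increments list of `c(lo, hi)` intervals; default early/middle/late
#'   thirds of `[0,1]`.
#' @return List with `ratios` (tibble: increment, lo, hi, ratio) and `slope`.
#' @export
area_difference_ratio <- function(healthy, disease,
                                  increments = list(c(0, 1 / 3),
                                                    c(1 / 3, 2 / 3),
                                                    c(2 / 3, 1))) {
  if (!isTRUE(all.equal(healthy$grid, disease$grid))) stop("grid mismatch")
  peak <- max(healthy$values, disease$values)
  if (peak == 0) return(list(ratios = NULL, slope = NA_real_))
  diff_curve <- abs(healthy$values - disease$values)
  ratios <- vapply(increments, function(iv) {
    interval_area(healthy$grid, diff_curve, iv[1], iv[2]) / peak
  }, numeric(1))
  mids <- vapply(increments, mean, numeric(1))
  slope <- if (length(ratios) >= 2) {
    as.numeric(coef(lm(ratios ~ mids))[2])
  } else {
    NA_real_
  }
  list(
    ratios = tibble(
      increment = seq_along(increments),
      lo = vapply(increments, `[`, numeric(1), 1),
      hi = vapply(increments, `[`, numeric(1), 2),
      ratio = ratios
    ),
    slope = slope
  )
}
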