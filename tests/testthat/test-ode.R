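random_params <- function() {
  u <- runif(1); v <- runif(1)
  population_params(r_act = runif(1, 0.05, 3), p_self = u,
                    p_amp = v * (1 - u), r_death = runif(1, 0.05, 3))
}

test_that("the model matrix encodes the division outcomes", {
  p <- population_params(r_act = 0.5, p_self = 0.2, p_amp = 0.6,
                         r_death = 0.3)
  m <- build_model_matrix(p)
  expect_equal(unname(m), matrix(c(
    -0.5, 2 * 0.2, 0,
    0.5, (2 * 0.6 - 1), 0,
    0, 2 * (1 - 0.2 - 0.6), -0.3
  ), 3, 3, byrow = TRUE))
  # Metzler off-diagonals for random valid parameters
  set.seed(31)
  for (i in 1:20) {
    mm <- build_model_matrix(random_params())
    off <- mm[row(mm) != col(mm)]
    expect_true(all(off >= 0))
  }
  expect_error(population_params(0.1, 0.7, 0.5, 0.1), "<= 1")
})

test_that("eigenvalues match an independent characteristic-polynomial oracle", {
  set.seed(32)
  for (i in 1:10) {
    m <- build_model_matrix(random_params())
    ev <- eigen(m, only.values = TRUE)$values
    # polyroot on det(M - xI) expanded coefficients
    cp <- c(-det(m),
            (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) +
              (m[1, 1] * m[3, 3] - m[1, 3] * m[3, 1]) +
              (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]),
            -sum(diag(m)), 1)
    roots <- polyroot(cp)
    expect_equal(sort(Re(ev)), sort(Re(roots)), tolerance = 1e-9)
  }
})

test_that("neutral division with no flux gives zero growth", {
  p <- population_params(r_act = 0, p_self = 0, p_amp = 0.5, r_death = 0)
  ge <- growth_and_equilibrium(build_model_matrix(p))
  expect_equal(ge$growth_rate, 0)
  sim <- simulate_growth(p, initial = c(0, 1, 0))
  expect_true(is.na(sim$tD))
})

test_that("equilibria are simplex points matching long-time simulation", {
  ge0 <- growth_and_equilibrium(diag(c(-1, 2, -1)))
  expect_equal(ge0$growth_rate, 2)
  expect_equal(unname(ge0$equilibrium), c(0, 1, 0))

  set.seed(33)
  for (i in 1:15) {
    p <- random_params()
    ge <- growth_and_equilibrium(build_model_matrix(p))
    expect_true(all(ge$equilibrium >= -1e-9))
    expect_equal(sum(ge$equilibrium), 1, tolerance = 1e-9)
    sim <- simulate_growth(p, initial = c(0.2, 0.5, 0.3))
    final <- unlist(sim$trajectory[nrow(sim$trajectory), c("Q", "A", "D")])
    tv <- sum(abs(final / sum(final) - ge$equilibrium)) / 2
    expect_lt(tv, 1e-3)
  }
})

test_that("growth simulation is exponential late and hits detection size", {
  p <- population_params(r_act = 0.8, p_self = 0.25, p_amp = 0.55,
                         r_death = 0.4)
  sim <- simulate_growth(p)
  expect_gt(sim$growth_rate, 0)
  expect_false(is.na(sim$tD))
  expect_lte(sim$tE, sim$tD)
  # doubling check far beyond equilibrium
  m <- build_model_matrix(p)
  t1 <- 10 * sim$tE; dt <- 2
  tot <- function(t) sum(ptalign:::propagate(m, c(1, 0, 0), t))
  expect_equal(tot(t1 + dt) / tot(t1), exp(sim$growth_rate * dt),
               tolerance = 1e-6)
  # proportions at 10 tE match the equilibrium
  st <- ptalign:::propagate(m, c(1, 0, 0), 10 * sim$tE)
  expect_lt(sum(abs(st / sum(st) - sim$equilibrium)) / 2, 1e-3)
  # non-negative states throughout
  expect_true(all(as.matrix(sim$trajectory[, c("Q", "A", "D")]) >= -1e-12))
  expect_error(simulate_growth(p, initial = c(0, 0, 0)), "positive total")
})

test_that("equilibrium composition is independent of the start state", {
  p <- population_params(r_act = 0.6, p_self = 0.3, p_amp = 0.5,
                         r_death = 0.8)
  ge <- growth_and_equilibrium(build_model_matrix(p))
  set.seed(34)
  for (i in 1:8) {
    x0 <- runif(3, 0.05, 1)
    sim <- simulate_growth(p, initial = x0)
    final <- unlist(sim$trajectory[nrow(sim$trajectory), c("Q", "A", "D")])
    expect_lt(sum(abs(final / sum(final) - ge$equilibrium)) / 2, 1e-3)
  }
})

test_that("composition fitting recovers planted equilibria deterministically", {
  p <- population_params(r_act = 0.5, p_self = 0.2, p_amp = 0.6,
                         r_death = 0.3)
  eq <- growth_and_equilibrium(build_model_matrix(p))$equilibrium
  fit <- fit_to_composition(eq, n_starts = 12, seed = 7)
  expect_true(fit$converged)
  expect_lt(sum(abs(fit$equilibrium - eq)) / 2, 0.02)
  fit2 <- fit_to_composition(eq, n_starts = 12, seed = 7)
  expect_identical(tidy(fit), tidy(fit2))
  # zero components go through the pseudofraction path without crashing
  fit0 <- fit_to_composition(c(0.6, 0.4, 0), n_starts = 6, seed = 8)
  expect_true(is.finite(fit0$residual))
  expect_error(fit_to_composition(c(0.5, 0.6, 0.1)), "sum to 1")
})

test_that("growth-rate regression on activation explains what it should", {
  r_act <- exp(seq(-2, 1, length.out = 10))
  exact <- tibble::tibble(r_act = r_act,
                          growth_rate = 0.4 * log(r_act) + 0.2)
  reg <- suppressWarnings(activation_growth_regression(exact))
  expect_equal(reg$r_squared, 1)
  # closed-form R^2 oracle for noisy data
  set.seed(35)
  noisy <- exact
  noisy$growth_rate <- noisy$growth_rate + rnorm(10, 0, 0.1)
  reg2 <- activation_growth_regression(noisy)
  expect_equal(reg2$r_squared,
               cor(noisy$growth_rate, log(noisy$r_act))^2)
  expect_error(activation_growth_regression(exact[1:2, ]), ">= 3")
  const <- tibble::tibble(r_act = rep(1, 5), growth_rate = rnorm(5))
  expect_error(activation_growth_regression(const), "constant")
})
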