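#' Population-dynamics parameters
#'
#' Rates and division-outcome probabilities of the linear
#' quiescence-activation-differentiation population model. Active cells
#' divide at rate `r_div` (fixed at 1, defining the time unit); a division
#' yields two quiescent daughters with probability `p_self` (self-renewal),
#' two active daughters with probability `p_amp` (amplification), and two
#' differentiated daughters otherwise. Quiescent cells activate at rate
#' `r_act`; differentiated cells are lost at rate `r_death`.
#'
#' @param r_act activation (Q to A) rate, >= 0.
#' @param p_self,p_amp division-outcome probabilities, `p_self + p_amp <= 1`.
#' @param r_death differentiated-cell loss rate, >= 0.
#' @param r_div division rate of active cells (time unit; default 1).
#' @return A `ptx_params` object.
#' @export
population_params <- function(r_act, p_self, p_amp, r_death, r_div = 1) {
  if (any(c(r_act, p_self, p_amp, r_death, r_div) < 0)) {
    stop("all rates and probabilities must be >= 0")
  }
  if (p_self + p_amp > 1 + 1e-12) stop("p_self + p_amp must be <= 1")
  structure(list(r_act = r_act, p_self = p_self, p_amp = p_amp,
                 r_death = r_death, r_div = r_div),
            class = "ptx_params")
}

#' @export
print.ptx_params <- function(x, ...) {
  cat(sprintf(
    "<ptx_params> r_act=%.3g p_self=%.3g p_amp=%.3g r_death=%.3g (r_div=%g)\n",
    x$r_act, x$p_self, x$p_amp, x$r_death, x$r_div))
  invisible(x)
}

#' Build the linear QAD model matrix
#'
#' Returns the generator `M` of `d(Q,A,D)/dt = M (Q,A,D)`:
#' \deqn{M = \begin{pmatrix} -r_{act} & 2 p_{self} r_{div} & 0 \\
#'   r_{act} & (2 p_{amp} - 1) r_{div} & 0 \\
#'   0 & 2 (1 - p_{self} - p_{amp}) r_{div} & -r_{death} \end{pmatrix}}
#' Off-diagonals are non-negative (Metzler), so non-negative states stay
#' non-negative and the dominant eigenvector is non-negative.
#'
#' @param params a [population_params()].
#' @return 3x3 numeric matrix with dimnames Q/A/D.
#' @export
build_model_matrix <- function(params) {
  p <- params
  m <- matrix(c(
    -p$r_act,               2 * p$p_self * p$r_div,                 0,
    p$r_act,                (2 * p$p_amp - 1) * p$r_div,            0,
    0,                      2 * (1 - p$p_self - p$p_amp) * p$r_div, -p$r_death
  ), nrow = 3, byrow = TRUE, dimnames = list(c("Q", "A", "D"),
                                             c("Q", "A", "D")))
  m
}

#' Growth rate and equilibrium composition of the model
#'
#' The asymptotic growth rate is the eigenvalue of `M` with the largest real
#' part; the equilibrium stage composition is its (non-negative) eigenvector
#' normalized to sum 1. When the dominant eigenpair is numerically unusable
#' (defective or sign-mixed), the equilibrium falls back to long-time
#' propagated proportions with a warning.
#'
#' @param m a [build_model_matrix()] matrix.
#' @return List with `growth_rate` and `equilibrium` (named, sums to 1).
#' @export
growth_and_equilibrium <- function(m) {
  e <- eigen(m)
  i <- which.max(Re(e$values))
  growth <- Re(e$values[i])
  v <- e$vectors[, i]
  usable <- max(abs(Im(v))) < 1e-9
  if (usable) {
    v <- Re(v)
    if (sum(v) < 0) v <- -v
    usable <- all(v >= -1e-9) && sum(v) > 0
  }
  if (!usable) {
    warning("dominant eigenvector unusable; using long-time simulated proportions")
    x <- c(1, 1, 1) / 3
    for (k in 1:200) {
      x <- as.numeric(Matrix::expm(Matrix::Matrix(m) * 1) %*% x)
      x <- x / sum(x)
    }
    v <- x
  }
  v <- pmax(v, 0)
  eq <- v / sum(v)
  names(eq) <- c("Q", "A", "D")
  list(growth_rate = growth, equilibrium = eq)
}

# propagate states with the matrix exponential (exact for linear systems)
propagate <- function(m, x0, times) {
  e <- eigen(m)
  V <- matrix(as.complex(e$vectors), nrow(m), ncol(m))
  vals <- as.complex(e$values)
  a <- tryCatch(solve(V, as.complex(x0)), error = function(err) NULL)
  if (!is.null(a) && all(is.finite(Mod(a)))) {
    states <- vapply(times, function(t) {
      pmax(Re(V %*% (a * exp(vals * t))), 0)
    }, numeric(3))
  } else {
    states <- vapply(times, function(t) {
      pmax(as.numeric(Matrix::expm(Matrix::Matrix(m) * t) %*% x0), 0)
    }, numeric(3))
  }
  rownames(states) <- c("Q", "A", "D")
  states
}

#' Simulate QAD population growth
#'
#' Propagates the linear model from an initial state by matrix exponential
#' (exact for linear systems) and reports when the stage proportions settle
#' into equilibrium (`tE`: first time from which the total-variation distance
#' to the equilibrium composition stays below `eps_equil`) and when the total
#' population reaches the detection size (`tD`, default 1e11 cells; `NA` when
#' the growth rate is not positive).
#'
#' @param params a [population_params()].
#' @param initial non-negative `(Q, A, D)` start state (default one quiescent
#'   cell).
#' @param n_detect detection population size (default `1e11`).
#' @param eps_equil total-variation tolerance for equilibrium (default 0.01).
#' @param n_times number of sampled time points.
#' @return A `ptx_simulation`: tibble `trajectory` (`time`, `Q`, `A`, `D`,
#'   `total`), `growth_rate`, `equilibrium`, `tE`, `tD`.
#' @export
simulate_growth <- function(params, initial = c(1, 0, 0), n_detect = 1e11,
                            eps_equil = 0.01, n_times = 400) {
  if (any(initial < 0) || sum(initial) <= 0) {
    stop("initial state must be non-negative with positive total")
  }
  m <- build_model_matrix(params)
  ge <- growth_and_equilibrium(m)
  growth <- ge$growth_rate
  # horizon: long enough to reach detection (if growing) and equilibrium
  gap <- eigen_gap(m)
  t_relax <- if (gap > 0) 20 / gap else 50
  t_detect <- if (growth > 0) {
    (log(n_detect) - log(sum(initial))) / growth * 1.2
  } else {
    0
  }
  t_end <- max(t_relax, t_detect, 10)
  times <- seq(0, t_end, length.out = n_times)
  states <- propagate(m, initial, times)
  totals <- colSums(states)
  props <- sweep(states, 2, pmax(totals, .Machine$double.xmin), `/`)
  tv <- colSums(abs(props - ge$equilibrium)) / 2
  below <- tv < eps_equil
  tE <- NA_real_
  for (k in seq_along(times)) {
    if (all(below[k:length(times)])) {
      tE <- times[k]
      break
    }
  }
  tD <- NA_real_
  if (growth > 0) {
    f <- function(t) {
      st <- propagate(m, initial, t)
      log(sum(st)) - log(n_detect)
    }
    hi <- t_end
    while (f(hi) < 0) hi <- hi * 2
    tD <- stats::uniroot(f, c(0, hi), tol = 1e-8)$root
  }
  structure(
    list(
      trajectory = tibble(time = times, Q = states[1, ], A = states[2, ],
                          D = states[3, ], total = totals),
      growth_rate = growth, equilibrium = ge$equilibrium,
      tE = tE, tD = tD, params = params, n_detect = n_detect,
      eps_equil = eps_equil
    ),
    class = "ptx_simulation"
  )
}

eigen_gap <- function(m) {
  ev <- sort(Re(eigen(m, only.values = TRUE)$values), decreasing = TRUE)
  max(ev[1] - ev[2], 1e-8)
}

#' @export
print.ptx_simulation <- function(x, ...) {
  cat(sprintf("<ptx_simulation> growth %.4g, tE %.3g, tD %s\n",
              x$growth_rate, x$tE,
              if (is.na(x$tD)) "NA (not growing)" else sprintf("%.3g", x$tD)))
  invisible(x)
}

#' @rdname tidy.ptx_dtw
#' @export
glance.ptx_simulation <- function(x, ...) {
  tibble(growth_rate = x$growth_rate,
         eq_Q = x$equilibrium[["Q"]], eq_A = x$equilibrium[["A"]],
         eq_D = x$equilibrium[["D"]], tE = x$tE, tD = x$tD)
}

#' Fit model parameters to an observed QAD composition
#'
#' Multi-start bounded minimization (L-BFGS-B) of the Aitchison distance
#' between the model's equilibrium composition and the observed stage
#' composition, over `(r_act, p_self, p_amp, r_death)` with `r_div = 1`. The
#' probabilities are parameterized as `p_self = u`, `p_amp = v (1 - u)` so
#' the simplex constraint holds by construction. A three-part composition has
#' two degrees of freedom against four parameters, so fits are reported with
#' a multi-start disagreement flag rather than claiming identifiability.
#'
#' @param observed non-negative `(Q, A, D)` composition summing to 1.
#' @param n_starts number of random multi-starts (default 25).
#' @param seed integer seed for the starts.
#' @param bounds list of `c(lo, hi)` for `r_act` and `r_death`.
#' @param pseudofraction zero-replacement for the Aitchison objective.
#' @param residual_tol residual above which the fit is flagged
#'   non-converged (default 0.05).
#' @return A `ptalign_popfit`: `params`, `residual`, `converged`,
#'   `growth_rate`, `equilibrium`, `ambiguous` (multi-start disagreement),
#'   `starts` tibble.
#' @export
fit_to_composition <- function(observed, n_starts = 25, seed = 1L,
                               bounds = list(r_act = c(1e-4, 20),
                                             r_death = c(1e-4, 20)),
                               pseudofraction = 1e-6, residual_tol = 0.05) {
  observed <- as.numeric(observed)
  if (length(observed) != 3 || any(observed < 0)) {
    stop("observed must be a non-negative (Q, A, D) composition")
  }
  if (abs(sum(observed) - 1) > 1e-6) stop("observed must sum to 1")

  unpack <- function(theta) {
    population_params(
      r_act = exp(theta[1]),
      p_self = theta[2],
      p_amp = theta[3] * (1 - theta[2]),
      r_death = exp(theta[4])
    )
  }
  objective <- function(theta) {
    ge <- growth_and_equilibrium(build_model_matrix(unpack(theta)))
    aitchison_distance(ge$equilibrium, observed, pseudofraction)
  }
  lower <- c(log(bounds$r_act[1]), 1e-6, 1e-6, log(bounds$r_death[1]))
  upper <- c(log(bounds$r_act[2]), 1 - 1e-6, 1 - 1e-6, log(bounds$r_death[2]))
  starts <- with_local_seed(seed, {
    matrix(runif(4 * n_starts, lower, upper), ncol = 4, byrow = TRUE)
  })
  fits <- lapply(seq_len(n_starts), function(i) {
    suppressWarnings(
      tryCatch(
        optim(starts[i, ], objective, method = "L-BFGS-B",
              lower = lower, upper = upper),
        error = function(e) list(par = starts[i, ], value = Inf)
      )
    )
  })
  values <- vapply(fits, function(f) f$value, numeric(1))
  best <- which.min(values)
  par <- fits[[best]]$par
  params <- unpack(par)
  ge <- growth_and_equilibrium(build_model_matrix(params))
  near <- which(values <= values[best] + 1e-4)
  par_mat <- do.call(rbind, lapply(fits[near], function(f) f$par))
  ambiguous <- length(near) > 1 &&
    any(apply(par_mat, 2, function(col) diff(range(col))) > 0.05)
  structure(
    list(
      params = params, residual = values[best],
      converged = values[best] <= residual_tol,
      growth_rate = ge$growth_rate, equilibrium = ge$equilibrium,
      observed = setNames(observed, c("Q", "A", "D")),
      ambiguous = ambiguous, seed = seed,
      starts = tibble(start = seq_len(n_starts), residual = values)
    ),
    class = "ptalign_popfit"
  )
}

#' @export
print.ptalign_popfit <- function(x, ...) {
  cat(sprintf(
    "<ptalign_popfit> residual %.4g (%s); growth %.4g; r_act=%.3g p_self=%.3g p_amp=%.3g r_death=%.3g\n",
    x$residual, if (x$converged) "converged" else "NOT converged",
    x$growth_rate, x$params$r_act, x$params$p_self, x$params$p_amp,
    x$params$r_death))
  invisible(x)
}

#' @rdname tidy.ptx_dtw
#' @export
tidy.ptalign_popfit <- function(x, ...) {
  tibble(
    term = c("r_act", "p_self", "p_amp", "r_death"),
    estimate = c(x$params$r_act, x$params$p_self, x$params$p_amp,
                 x$params$r_death)
  )
}

#' @rdname tidy.ptx_dtw
#' @export
glance.ptalign_popfit <- function(x, ...) {
  tibble(residual = x$residual, converged = x$converged,
         ambiguous = x$ambiguous, growth_rate = x$growth_rate,
         eq_Q = x$equilibrium[["Q"]], eq_A = x$equilibrium[["A"]],
         eq_D = x$equilibrium[["D"]])
}

#' Regress cohort growth rates on activation rates
#'
#' Least-squares fit of `growth_rate ~ log(r_act)` across tumors, reporting
#' the fraction of growth-rate variance explained and flagging tumors with
#' standardized residuals beyond `z_threshold` (growth driven by something
#' other than activation, e.g. increased self-renewal).
#'
#' @param cohort data frame with columns `r_act` (> 0) and `growth_rate`.
#' @param z_threshold flag residuals with `|z|` above this (default 2).
#' @return List with `r_squared`, `fit` (the `lm`), and tibble `residuals`
#'   (`r_act`, `growth_rate`, `residual`, `z`, `flagged`).
#' @export
activation_growth_regression <- function(cohort, z_threshold = 2) {
  if (nrow(cohort) < 3) stop("need >= 3 tumors")
  if (any(cohort$r_act <= 0)) stop("r_act must be > 0")
  if (var(cohort$r_act) == 0) stop("constant r_act: regression undefined")
  fit <- lm(growth_rate ~ log(r_act), data = cohort)
  r2 <- summary(fit)$r.squared
  res <- resid(fit)
  z <- if (sd(res) > 0) res / sd(res) else res * 0
  list(
    r_squared = r2,
    fit = fit,
    residuals = tibble(
      r_act = cohort$r_act, growth_rate = cohort$growth_rate,
      residual = as.numeric(res), z = as.numeric(z),
      flagged = abs(z) > z_threshold
    )
  )
}
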