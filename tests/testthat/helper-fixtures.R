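# Shared synthetic fixtures, built once per test run. Sizes are kept small:
# the fixtures exercise code paths; statistical performance is covered by the
# dedicated acceptance tests at their stated problem sizes.

fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, build(), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

small_universe <- function() {
  fixture("small_universe", function() {
    cfg <- synth_config(n_cells = 400, n_genes = 400, n_traj_genes = 40,
                        cycling_fraction = 0.08, seed = 101)
    ro <- make_reference(cfg)
    traj <- ro$truth$genes$gene[ro$truth$genes$informative]
    binned <- bin_reference(ro$reference, traj, n_bins = 20,
                            min_cells_per_bin = 5)
    model <- train_predictor(ro$reference, binned, seed = 101,
                             hidden = list(c(16, 8)), l2 = 1e-3,
                             epochs = 150, cv_epochs = 60)
    query <- make_query_sample(cfg, composition = c(0.4, 0.3, 0.3),
                               n_cells = 250, sample_seed = 20101)
    list(cfg = cfg, ref = ro$reference, truth = ro$truth, traj = traj,
         binned = binned, model = model, query = query)
  })
}

# a unit point mass on the EMD grid at position `at`
point_mass_spline <- function(at, grid = pseudotime_grid()) {
  v <- numeric(length(grid))
  v[which.min(abs(grid - at))] <- 1
  area <- simpson(v, grid)
  structure(
    list(grid = grid, values = v, area = area, normalized = v / area,
         expressed = TRUE),
    class = "ptx_spline"
  )
}

# spline object from arbitrary non-negative grid values
grid_spline <- function(values, grid = pseudotime_grid()) {
  area <- simpson(values, grid)
  structure(
    list(grid = grid, values = values, area = area,
         normalized = if (area > 0) values / area else NULL,
         expressed = area > 0),
    class = "ptx_spline"
  )
}

# brute-force enumeration of all monotone DTW paths: minimal accumulated
# correlation distance (oracle for the traceback objective)
brute_force_dtw <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  best <- Inf
  rec <- function(i, j, s) {
    s <- s + (1 - m[i, j])
    if (i == nr && j == nc) {
      best <<- min(best, s)
      return(invisible())
    }
    if (i < nr) rec(i + 1, j, s)
    if (j < nc) rec(i, j + 1, s)
    if (i < nr && j < nc) rec(i + 1, j + 1, s)
  }
  rec(1, 1, 0)
  best
}

# tiny deterministic count matrix with named dims
toy_counts <- function(mat, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(mat)))
  if (is.null(cells)) cells <- sprintf("c%02d", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, cells)
  mat
}
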