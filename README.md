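# ptalign

Reference-based pseudotime alignment and activation-state analysis of
single-cell transcriptomes.

Adult stem-cell lineages — the ventricular–subventricular zone (v-SVZ)
neural stem cell lineage in particular — order their cells along a
non-branching axis from dormant/quiescent (Q) through activated (A) to
differentiating (D) states. Tumors such as glioblastoma appear to re-use
this architecture. `ptalign` quantifies a query sample's *activation-state
architecture* by placing each cell onto a healthy reference lineage's fixed
pseudotime in `[0,1]`, instead of re-deriving a new, incomparable trajectory
per dataset. For whom: computational biologists comparing stem-cell-like
hierarchies across samples, species, or disease states.

The toolkit covers five connected analyses:

1. **Reference preparation** — per-cell log-normalization, cell-cycle
   scoring with expression-matched controls (cycling = G2/M score > 0.1),
   KDE-based stage-boundary detection on the pseudotime density, derivation
   of a stage-labelled trajectory gene panel (random-forest recursive
   feature elimination, repeated random-subset importance ranking, knee
   cutoff, ribosomal exclusion, top-100 per stage), and pseudotime binning.
2. **Alignment** — per-cell Pearson similarity profiles against the binned
   reference, shape (z-) normalization, and a small two-hidden-layer
   perceptron (5-fold cross-validated grid search; trained on self-masked
   reference profiles) mapping profiles to pseudotime. Stage calls use the
   reference cutoffs 0.141 / 0.282 / 0.676; cycling cells are excluded
   before alignment, out-of-distribution cells (peak correlation < 0.2 or
   peak prominence < 0.05) are excluded after.
3. **Alignment QC** — a reference-vs-query bin correlation matrix, a
   dynamic-programming traceback minimizing accumulated `1 - r`, and an
   empirical permutation P-value from rerunning the entire pipeline on
   expression-decile-matched random gene sets (add-one rule:
   `p = (1 + #{perm >= obs}) / (1 + n_perm)`).
4. **Expression dynamics** — penalized 5-basis spline curves of expression
   over pseudotime, area-normalized and compared by exact Wasserstein-1
   (EMD) distances on a 0.05 grid; unexpressed genes score 1. Ranking of
   recurrently dysregulated genes at a knee cutoff, within/between-group
   biomarker screens, Q-vs-D expression bias, and area-difference ratios
   across early/middle/late pseudotime.
5. **Population model** — a linear ODE on (Q, A, D) with activation rate
   `r_act`, self-renewal and amplification probabilities `p_self`, `p_amp`,
   division rate fixed at 1, and D-loss `r_death`:

   ```
   dQ/dt = -r_act Q + 2 p_self A
   dA/dt =  r_act Q + (2 p_amp - 1) A
   dD/dt =  2 (1 - p_self - p_amp) A - r_death D
   ```

   The dominant eigenvalue is the growth rate, its eigenvector the
   equilibrium composition; compositions are fit by multi-start minimization
   of the Aitchison distance; simulations report the time to compositional
   equilibrium (tE) and to a 1e11-cell detection size (tD).

A synthetic-lineage generator (`synth_config()`, `make_reference()`,
`make_query_sample()`, `make_cohort()`) with full ground-truth sidecars
makes every claim testable without external data.

## Worked example

```r
library(ptalign)

# a 2000-cell synthetic reference lineage and a 500-cell "tumor" query
cfg <- synth_config(n_cells = 2000, n_genes = 300, n_traj_genes = 150,
                    seed = 42)
ro  <- make_reference(cfg)
traj <- ro$truth$genes$gene[ro$truth$genes$informative]

binned <- bin_reference(ro$reference, traj)            # 50 pseudotime bins
model  <- train_predictor(ro$reference, binned, seed = 42)
model
#> <ptalign_predictor> 50 bins -> (32,16) tanh -> 1; l2=0.0001, train MSE 0.0005628

q   <- make_query_sample(cfg, composition = c(0.4, 0.3, 0.3), n_cells = 500,
                         sample_seed = 10042)
cyc <- setNames(q$truth$cells$cycling, q$truth$cells$cell_id)
aln <- ptalign_align(q$query, ro$reference, binned, model, cycling = cyc)

ok <- aln$status == "aligned"
cor(aln$pseudotime[ok], q$truth$cells$pseudotime[ok])
#> [1] 0.9966719
mean(as.character(aln$stage[ok]) == q$truth$cells$stage[ok])
#> [1] 0.978022
round(stage_composition(aln, include_cycling = TRUE), 3)
#>       Q       A       D cycling
#>   0.384   0.276   0.250   0.090
```

The correlation (~0.997) says the perceptron's aligned pseudotimes recover
the generative ordering almost exactly; stage accuracy (~0.98) says the
Q/A/D calls made from those pseudotimes match the ground truth; the
composition is the sample's activation-state architecture, the quantity the
downstream ODE model consumes:

```r
fit <- fit_to_composition(stage_composition(aln), seed = 1)
glance(fit)           # growth rate, equilibrium, residual
sim <- simulate_growth(fit$params)
c(sim$tE, sim$tD)     # composition settles long before detection size
autoplot(sim)
```

Alignment quality is tested by permutation:

```r
pr <- permutation_pvalue(q$query, ro$reference, traj, n_perm = 100, seed = 1)
pr$p_value            # small for a faithful alignment (minimum 1/101)
```

A command-line wrapper for shell pipelines lives at `inst/cli/ptalign.R`
(subcommands `reference`, `align`, `qc`, `popmodel`, `synth`).

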