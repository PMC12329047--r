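---
title: "Reference-based pseudotime alignment and activation-state analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based pseudotime alignment and activation-state analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptalign)
```

## The problem

Adult stem-cell niches such as the ventricular–subventricular zone (v-SVZ)
organize their cells along a non-branching lineage from dormant and quiescent
(Q) stem cells through an activated (A) compartment into differentiating (D)
progeny. Many tumors — glioblastoma prominently — appear to re-use this
architecture. A practical way to quantify a tumor's *activation-state
architecture* is to place each malignant cell onto the healthy lineage's
pseudotime axis and read off its stage. ptalign implements that mapping, a
statistical test of whether a mapping is trustworthy, a method for comparing
expression *dynamics* between aligned datasets, and a population-dynamics
model that turns observed stage compositions into growth predictions.

Conventional trajectory inference re-derives a latent ordering per dataset,
so orderings are not comparable across samples, species, or conditions.
ptalign instead treats a curated healthy lineage with a fixed pseudotime in
`[0,1]` as the coordinate system and *aligns* query cells into it.

## Alignment model

The reference is binned into `n_bins = 50` equal-width pseudotime intervals
(bins with fewer than 10 non-cycling cells are dropped) and each bin is
summarized by the mean log-normalized expression of a stage-labelled
*trajectory gene panel*. For every query cell we compute the Pearson
correlation of its panel expression with every bin mean — its *similarity
profile*. Profiles are then z-normalized per cell (mean 0, variance 1), so
only the profile's *shape* over pseudotime, not its overall correlation
level, carries information; this makes alignment robust to global expression
shifts between, say, a tumor and the healthy niche.

A small multi-layer perceptron (two tanh hidden layers, scalar linear
output) regresses reference pseudotime from reference self-similarity
profiles. Two choices matter here:

* **Self-masking.** A reference cell is removed from its own bin's mean
  before its training profile is computed; otherwise each profile contains a
  copy of the cell itself and the regressor learns a leak, not a mapping.
* **Hyperparameter search.** Hidden sizes {(32,16), (64,32), (128,64)} and
  L2 penalties {1e-4, 1e-3, 1e-2} are searched with 5-fold cross-validation
  minimizing MSE; the winner is refit on all profiles. Training uses
  full-batch Adam with seeded deterministic initialization, so a seed fixes
  the model bit-for-bit. Cross-validation fits use a reduced epoch budget
  (they only rank configurations); the final refit trains to its plateau.

Predictions are clipped to `[0,1]`. Cells flagged as cycling (G2/M score
above 0.1, scored against expression-matched control genes) are excluded
before alignment: a cycling cell's transcriptome is dominated by the cell
cycle, and the lineage pseudotime is only defined for the non-branching,
non-cycling trajectory. Cells whose raw profile resembles no reference
position — peak correlation below `c_min = 0.2` or peak-over-median
prominence below `prominence_min = 0.05` — are excluded as
out-of-distribution rather than forced onto the lineage. These thresholds
are calibrated for panels of a few hundred genes: with `G` panel genes the
null correlation scale is about `1/sqrt(G)`, so with ~240 genes noise peaks
sit safely below 0.2.

Stages are read off the aligned pseudotime using the reference cutoffs
0.282 (Q/A) and 0.676 (A/D), with 0.141 marking the dormant sub-compartment
within Q. The A interval is closed (`0.282 <= pt <= 0.676`); pseudotimes
below 0.141 are dormant Q cells. These boundaries can be re-derived for a
new reference from the pseudotime density: a Gaussian KDE (Scott's rule,
1001-point grid) is fit to the distinct pseudotime values and boundaries
are placed at the density minima between the first three modes. Duplicate
pseudotimes are collapsed first so the detection depends only on the set of
distinct values; ties in a continuous pseudotime carry no information at the
KDE's resolution. The dormant boundary is not identifiable from a
three-mode density and keeps its default (halved below the detected Q/A
boundary in the degenerate case where it would not be smaller).

## Trajectory gene panels

Panels are derived from a reference with stage labels by four steps:
(1) prefilter to genes detected in at least 1% of cells whose top
stage-mean is at least 1.5x the mean of the other stages; (2) recursive
feature elimination with a random-forest stage classifier on a 70/30 split
(drop the 20% least important genes per round while held-out accuracy stays
within two points of the best seen); (3) repeated random-subset importance
ranking — 500 draws of 500 genes by default, each scored by a random
forest, importances averaged per gene over the draws where it appeared;
(4) a knee-point cutoff on the ranked importance curve. Impurity
importances are heavy-tailed, so the knee is detected on the *log* curve;
on the raw curve the maximum-gap point lands inside the signal rather than
at the signal/noise transition. Ribosomal symbols (`RPL*`/`RPS*`,
case-insensitive) are removed, at most 100 genes are kept per stage, and
each gene is labelled with the stage where its mean expression peaks.

## Alignment quality: DTW permutation test

A query aligned with panel genes should produce bin-level expression that
warps smoothly onto the reference. We bin the query along its aligned
pseudotime with the reference's bins, correlate all reference-bin /
query-bin pairs, and trace the dynamic-programming path from corner to
corner (moves: down, right, diagonal) minimizing the accumulated
correlation distance `1 - r`. Minimizing `1 - r` rather than maximizing
summed `r` matters: with a summed-correlation objective any constant
positive matrix would favour the longest staircase path, whereas the
distance objective makes detours pay for themselves and yields the plain
diagonal on featureless input (ties break toward the diagonal move). The
path statistic is the mean correlation along the path.

Significance comes from permutations: gene sets of identical size are drawn
matched to the panel's reference expression-decile histogram (panel genes
excluded from the pool), and the *entire* pipeline — binning, self-masked
profiles, perceptron retraining, prediction, query binning, DTW — is rerun
per permuted set. Retraining is required for exchangeability: the profile
space changes with the gene set. The already-chosen hyperparameters are
reused; the grid search is part of the fixed pipeline configuration, the
weights are what must be exchangeable. The empirical P-value uses the
add-one rule, `p = (1 + #{permuted >= observed}) / (1 + n_perm)`, so `p`
can never be zero and is bounded below by `1/(n_perm + 1)`.

For benchmarking orderings produced by different methods we provide a
*pseudotime coherence* statistic: the Pearson correlation between pairwise
cell distances in a 10-component PCA subspace and pairwise rank distances
of the pseudotime. Rank distances make the statistic invariant to monotone
re-parameterizations, so methods with differently scaled pseudotimes are
comparable.

## Expression dynamics by EMD

To compare how a gene's expression *moves* along pseudotime between
conditions, each (gene, sample) is summarized as a curve: cells are grouped
into bins on a pseudotime grid with 0.05 spacing, bins with fewer than 20
cells are dropped, and the per-bin means are fit with five cubic B-spline
basis functions under an L2 penalty (weight 1.0 by default) on the curve's
second derivative. Fitted values are evaluated on the grid, clipped at
zero, and area-normalized by Simpson's rule. Two normalized curves are
compared by the Wasserstein-1 distance, computed exactly from cumulative
differences of the grid masses; distances live in `[0,1]` because the grid
spans `[0,1]`. A gene unexpressed on either side scores exactly 1 — loss of
expression is maximal dysregulation; this convention also applies when both
sides are unexpressed.

Recurrently dysregulated genes are ranked by mean EMD of each tumor against
the averaged healthy curve, after excluding genes in the lower half of
(healthy) spline area — area-normalization amplifies noise for
low-expressed genes — genes lost in more than half the tumors, and the
alignment panel itself (its genes are selected *for* conserved dynamics and
would be circular). The knee of the ranked mean-EMD curve separates
dysregulated genes from the bulk. Group biomarkers use the same machinery
within and between sample groups: genes whose within-group EMD (member vs
group mean curve) exceeds 0.1 in either group are considered incoherent and
dropped; survivors are ranked by the EMD between the two group mean curves.
The quiescence-vs-differentiation bias of a curve is its Simpson area over
`[0, 0.282]` divided by the summed areas over `[0, 0.282]` and
`[0.676, 1]`. For healthy-vs-disease comparisons at a coarser scale, the
area of the absolute curve difference within early/middle/late pseudotime
thirds, divided by the maximum value of either curve, and the slope of
those ratios across the thirds, localize where along the lineage two
datasets diverge.

## Population dynamics

The observed QAD composition of a tumor is treated as the equilibrium of a
linear ODE on states `(Q, A, D)`. Active cells divide at rate `r_div = 1`
(fixing the time unit); a division produces two quiescent daughters with
probability `p_self`, two active daughters with probability `p_amp`, and
two differentiated daughters otherwise; quiescent cells activate at rate
`r_act`; differentiated cells are lost at rate `r_death`:

$$
M = \begin{pmatrix}
-r_{act} & 2\,p_{self} & 0 \\
r_{act} & 2\,p_{amp} - 1 & 0 \\
0 & 2\,(1 - p_{self} - p_{amp}) & -r_{death}
\end{pmatrix}
$$

`M` is Metzler (non-negative off-diagonals), so non-negative states stay
non-negative and the dominant eigenpair gives the asymptotic growth rate
and a non-negative equilibrium composition. Propagation uses the matrix
exponential via the eigendecomposition — exact for linear systems — with a
dense-grid fallback when the eigenbasis is numerically unusable. `tE` is
the first time from which the total-variation distance of the stage
proportions to the equilibrium *stays* below 0.01 (first-crossing alone
would trigger on transient dips); `tD` solves `total(t) = 1e11` cells and
is undefined for non-growing parameter sets.

Fitting inverts this map: multi-start L-BFGS-B minimizes the Aitchison
distance between the model equilibrium and the observed composition over
`(r_act, p_self, p_amp, r_death)`, with the probabilities parameterized as
`p_self = u`, `p_amp = v(1-u)` so the simplex constraint holds by
construction. A three-part composition has two degrees of freedom against
four parameters, so the *parameters* are not identifiable — fits report a
multi-start disagreement flag and should be read as one representative of
an equivalence class — but the recovered *equilibrium* is well determined
(self-consistency recovers planted equilibria within 0.02 total variation).
Across valid growing parameter sets the equilibrium is reached early
relative to detection (`tE/tD < 0.2` whenever the growth rate exceeds
0.05): with a linear model the composition settles at the dominant
eigenvector on the spectral-gap timescale while the population still has
many doublings to go. Cohort-level structure is summarized by regressing
growth rate on `log(r_act)` and flagging tumors with large standardized
residuals — candidates for growth driven by self-renewal rather than
activation.

Compositions themselves are compared with the Aitchison distance (Euclidean
distance of centered-log-ratio transforms, zero components replaced by a
small pseudofraction and renormalized), the natural geometry for
compositional data.

## The synthetic lineage generator

All statistical claims are validated on generated lineages with known
truth. The generator emulates:

* a non-branching lineage: cells draw a stage from mixture weights
  (default 0.45/0.30/0.25 — quiescence-heavy, like a homeostatic niche)
  and a pseudotime uniform within the stage interval;
* gene programs: trajectory-panel genes are Gaussian bumps over pseudotime
  with stage-interior centers (log-uniform amplitudes 3–8, widths
  0.08–0.2 on baselines 0.1–0.5); optional off-panel *dynamic* genes carry
  the same program class, and dysregulated genes shift their bump center
  (by 0.45 by default, away from whichever boundary leaves room) in query
  samples only;
* background: ~30% of noise genes carry weak low-amplitude trends
  (amplitude 0.2–0.8 — real transcriptomes are not flat outside the
  panel), ~40% are flat at panel-level expression so expression-matched
  gene sampling has a pool in every decile, the rest are flat and
  low-expressed;
* counts: negative binomial (dispersion 2) around the program means with
  log-normal library-size variation (sigma 0.3) at ~2000 counts per cell;
* cycling cells (10% by default) with an 8x G2/M program on designated
  genes; out-of-distribution cells assembled gene-independently from the
  per-gene marginals, which preserves each gene's distribution but destroys
  the cross-gene trajectory structure.

Gene programs are fixed by the configuration seed (the "universe");
individual samples draw cells under separate sample seeds, so cohorts share
programs — a property the dysregulation analysis depends on.

What the generator does *not* emulate: batch effects, doublets, ambient
RNA, branching lineages, and realistic gene–gene covariance beyond the
shared pseudotime. Passing tests therefore demonstrate correctness of the
algorithms under the stated generative assumptions, not performance on any
particular real dataset.

## Problem sizes used in validation

The validation suite runs on one CPU with these sizes, chosen as the
smallest scales at which the statistical properties stabilize: pseudotime
recovery on 2000-cell references (300 genes, 150 panel genes) against
500-cell queries over 20 seeds; permutation validity on 400-cell references
(400 genes, 40 panel genes) with 100 permutations over 20 seeds per arm;
null-calibration over 200 runs with 19 permutations each on a 300-cell
reference; dysregulation recovery on a 10-sample cohort of 800-cell samples
(500 genes, 20 planted dysregulated among 60 off-panel dynamic genes) with
the cohort's compositions spanning a moderate Q-to-D range so every stage
keeps enough cells per spline bin; ODE properties over 50 random valid
parameter sets. The trajectory-panel recovery check runs at 1000 genes with
100 importance draws of 150 genes — the permutation count is reduced from
the 500x500 default, which only tightens the importance averages.

## Numerical choices and edge cases

* Correlations over gene panels are computed in a canonical (sorted) gene
  and cell order, so outputs are bit-identical under input permutations.
* Degenerate query cells (zero variance over the panel) are flagged and
  receive no pseudotime rather than an arbitrary one; constant similarity
  profiles likewise.
* The EMD treats grid curves as point masses on the grid; translation of a
  shape by a grid multiple changes the distance by exactly that amount.
* `assign_stages` is total on `[0,1]` and errors outside it; the A interval
  is closed on both ends by convention.
* Knee detection declares "no knee" on straight lines instead of returning
  an arbitrary index; callers treat that as "no cutoff".
* When the panel majority-occupies an expression decile (possible in small
  gene universes; never in a full transcriptome), a same-size matched draw
  is impossible within that decile; the shortfall is borrowed from the
  nearest deciles with surplus, with a warning. The permutation test still
  errors, listing the deficient deciles, when the total non-panel pool is
  smaller than the panel — a sign the gene universe is too small for a
  calibrated test, which should not be papered over by sampling with
  replacement.

## Known limitations

* The alignment assumes the query differentiates along (a subset of) the
  reference lineage; branching queries violate the model and should be
  split beforehand. Cycling cells are excluded rather than modelled.
* The out-of-distribution thresholds are heuristic; with small gene panels
  (tens of genes) noise correlations can exceed the 0.2 peak threshold and
  flagging loses sensitivity.
* ODE parameter fits are set-identified, not point-identified (see above);
  only equilibrium-derived quantities (growth rate, tE, tD) should be
  compared across tumors.
* The spline smoothing weight (1.0) and the "expressed" threshold
  (lognorm > 0) are pragmatic defaults exposed as arguments, not estimated
  from data.
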