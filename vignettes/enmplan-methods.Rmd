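---
title: "Methods: maximum-entropy niche modelling and minimum-set planning in enmplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy niche modelling and minimum-set planning in enmplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmplan)
```

`enmplan` chains two models that are usually run in separate tools: a
maximum-entropy species distribution model (SDM) and a Marxan-style
minimum-set prioritization. This vignette is the package's own account of
what is computed, which knobs matter, and where the design was genuinely
open.

## The suitability model

### Formulation

Given presence cells $x_1,\dots,x_m$ and a background sample $B$ of study-area
cells, the model is the Gibbs distribution over $B$,
$P_\lambda(x) = \exp(\lambda \cdot f(x)) / Z_\lambda$, fitted by minimizing

$$
-\frac1m \sum_i \lambda \cdot f(x_i) + \log Z_\lambda
  + \sum_j \beta_j |\lambda_j|,
\qquad
\beta_j = \mathrm{RM} \cdot s_{\mathrm{class}(j)} \cdot \sigma_j/\sqrt{m},
$$

the standard L1-regularized maximum-entropy estimator: among all
distributions whose feature means are within $\beta_j$ of the presence
means, it has maximum entropy. We fit by full-batch proximal gradient
(FISTA with backtracking and a momentum restart) rather than the historical
sequential-update algorithm; the optimum is the same convex minimum and the
KKT stationarity condition
$|\hat p_j - E_{P_\lambda}[f_j]| \le \beta_j + \varepsilon$ gives a direct
convergence certificate, asserted in the test suite at
$\varepsilon = 10^{-4}$.

Features are the five classic classes — linear, quadratic, product,
threshold, hinge — of min-max-normalized layers, all mapping into $[0,1]$,
with projection values clamped to the training range so novel conditions
score as at the range edge. Hinge and threshold knots sit at 10 background
quantiles per layer by default; the per-class penalty scales are
$s_{L,Q,P} = 1$, $s_T = 2$, $s_H = 0.5$, echoing the reference defaults
(threshold steps are penalized hardest because each adds a discontinuity;
hinges lightest because many small hinges approximate smooth responses).
A floor of $10^{-4}$ on $\beta_j$ keeps the problem strictly regularized
when a presence sample is tiny or a feature is near-constant. The
regularization-multiplier scan during calibration subsumes residual
differences from other implementations' exact per-class interpolation
tables, which we deliberately do not reproduce.

The background is every jointly valid cell when there are at most 10,000,
otherwise a seeded uniform sample of 10,000; presence cells are always
appended so presence probabilities are defined. The reported training gain
is $\log |B|$ minus the penalized loss; including the penalty makes gain
provably non-increasing in RM, which the suite checks on a fixed dataset.

### Outputs

Raw output sums to one over the background. Cumulative output of a cell is
100 times the raw mass of cells scoring no higher. Logistic output is
$r e^H/(1 + r e^H)$ with $H$ the background entropy of the fitted
distribution, so a uniform (no-signal) model scores exactly 0.5 everywhere —
the fixed point the suite asserts. All three transforms are strictly
monotone in each other, so rank-based measures (AUC, thresholds applied to
ranks) are transform-invariant.

### Importance diagnostics

Percent contribution attributes each optimizer step's objective decrease to
features in proportion to $|\Delta\lambda_j| \cdot |g_j|$, pools features by
source layer (products split evenly), and zeroes the attribution of features
the L1 penalty ultimately dropped — a transiently-moved weight that ends at
zero represents no retained signal. Permutation importance permutes one
layer's values jointly across presence and background cells, re-evaluates
the features, and records the training-AUC drop, normalized to 100. The two
measures disagree by design: contribution is path-dependent and correlated
layers can split it arbitrarily, permutation importance measures what the
final model loses. Jackknife refits (each layer alone; all but each layer)
reuse the full design matrix, background and penalty bounds at a tight
tolerance ($10^{-7}$) so the gains are nested-comparable:
"without" gains can then never exceed the full gain.

### The contribution prescreen and smooth noise

The variable prescreen fits one default-parameter model (RM = 1, all five
classes) and drops layers whose contribution and permutation importance are
both below a cut (1% by convention). A caution the synthetic experiments
make visible: a spatially *smooth* uninformative field is not statistically
null at realistic sample sizes — with ~200 presences and a 6-cell
correlation length, chance alignment between the noise field and the
occurrence pattern gives a default-parameter model genuine (if spurious)
hinge structure worth a few percent of contribution. The noise layer still
ranks last on both measures, but a hard 1% cut may keep it. This is the
familiar overfitting of default settings that the calibration stage exists
to remove; the prescreen's job is to discard clearly dead layers, and its
threshold should be read as a ranking cut, not a significance test.

## Calibration

Candidate models cross an RM grid (0.1–4 in steps of 0.1 by convention) with
every non-empty subset of the feature classes — 40 × 31 = 1240 candidates.
Each is fitted on a seeded 70/30 split and scored by three criteria:

* **Partial ROC.** Bootstrap AUC ratio above sensitivity $1 - E$ with
  $E = 5\%$, 500 iterations at 50% resampling by default — the established
  defaults of the procedure. $p$ is the fraction of bootstrap ratios at or
  below 1.
* **Omission rate.** The threshold is the $E$-th percentile (linear
  interpolation) of training-presence scores; OR is the share of test
  presences below it. The threshold rule is a documented choice: the "5%
  training omission" convention consistent with the ≤ 5% selection rule.
* **AICc** with $k$ = number of nonzero weights (|λ| > 1e−8), the standard
  practice for L1-regularized maximum entropy, and the likelihood taken
  under raw output renormalized over the whole valid study area.

Selection keeps significant candidates ($p < 0.05$), then those with
OR ≤ 5%, then the AICc minimum; ties go to fewer parameters, then lower RM,
then the lexicographic class string — a deterministic rule, since published
analyses report a unique winner without stating one. On small synthetic
samples the omission criterion is a near coin flip around 5%, so
`select_model(fallback_min_or = TRUE)` (used by the pipeline driver) falls
back to the lowest-omission significant candidates rather than failing; the
strict contract (an error listing nearest misses) remains the default. The
final candidate is refitted over seeded resplits (10 by convention; the
pipeline default is 3 for speed) and the logistic maps averaged cellwise.

## Habitat classes, change maps, centroids

Two thresholds classify the logistic map: MTSS (maximizing
sensitivity + specificity, presences vs background) bounds the suitable
class, and the balance threshold ("TPT") bounds the sub-suitable class by
minimizing $6\,\mathrm{omission} + 0.04\,\mathrm{cumulative} +
1.6\,\mathrm{area}$ — the balance rule of the reference implementation,
exposed as a weight argument because the criterion's name alone does not fix
the formula. Both equal exhaustive search over candidate thresholds on every
randomized test instance; ties go to the lowest threshold and class
boundaries are closed below (≥ TPT, ≥ MTSS). A reversed pair (TPT > MTSS) is
an error, never silently reordered.

Change maps binarize two classified maps under one presence rule and
partition the domain into expansion / contraction / stable / never-present.
Rates divide by the union of base and future presence — the convention that
approximately reproduces published expansion/stability percentages; it is a
documented convention, not a recoverable fact, since the published
denominators are not stated. Centroids are area-weighted means of cell
centers (area weighting keeps planar and lon/lat grids consistent);
distances use the haversine formula on a 6371 km sphere for lon/lat grids
(111.1949 km per equatorial degree, asserted in the suite) and Euclidean
distance otherwise, with bearings from north, clockwise.

## The minimum-set planner

The objective is
$\sum \mathrm{cost} + \mathrm{BLM} \sum \mathrm{boundary} +
\sum \mathrm{SPF} \cdot \mathrm{penalty} + \mathrm{costThresholdPenalty}$,
with the boundary term counting only shared selected/unselected edges and
the cost threshold off unless configured. Per-unit cost is the capped sum of
the prohibited-land-cover and protected-area fractions. The feature amount
of a unit is probability-weighted area (logistic output × cell area), so a
30% target means 30% of total probability-weighted habitat — sum semantics,
chosen because targets over areas are the planner's native meaning. The
shortfall penalty is proportional, $\mathrm{base} \cdot
\mathrm{shortfall}/\mathrm{target}$, with the base estimated by a greedy
cover (cheapest cost-per-amount first) of each target — an upper bound on
the cost of meeting the target, so ignoring a target is never cheaper than
meeting it.

Annealing flips one random available unit per move, accepting deteriorations
with probability $e^{-\Delta/T}$; $T$ starts at the 80th percentile of
absolute probe deltas (so early acceptance ≈ 80%) and cools geometrically to
$10^{-4}$ of its start. Bookkeeping is incremental, and the suite asserts
that after any move sequence the maintained objective equals recomputation
from scratch; a deterministic iterative-improvement sweep polishes the
best-seen selection, the classic second phase of minimum-set solvers. "100
iterations" is read as an ensemble of 100 independent seeded runs, since
selection-frequency maps require multiple runs; per-run moves default to
100,000. On 12-unit instances the annealer recovers the exhaustive optimum
in at least 18 of 20 seeded runs at 30,000 moves.

BLM and SPF are scale-relative: BLM multiplies boundary length in whatever
units the boundary list carries, so the published value 1.6 is meaningful
only relative to the cost scale. The synthetic demonstrations therefore
measure boundaries in shared-edge counts, putting unit costs (≤ 1) and
single-edge boundaries (1) on a comparable scale; sensitivity sweeps
(`sensitivity()`) reproduce the expected monotone responses — boundary
length falls with BLM, shortfall falls with SPF.

## The synthetic world

The generator emulates what the pipeline needs from real data and no more:
$K$ Gaussian-smoothed white-noise fields (length-scale 6 cells by default)
mixed by the Cholesky factor of a target correlation matrix, a known
logistic true-suitability surface over standardized layers, occurrences
sampled proportional to suitability with uniform within-cell placement,
future scenarios as field translations (with optional per-layer offsets),
and a rectangular planning lattice with rook adjacency and Beta(1, 4) cost
fractions (most units cheap, a few expensive). The default study — two
informative layers ($\beta = 2, 1.5$) plus one pure-noise layer on a
100 × 100 grid, 200 occurrences — is the condition under which the recovery
properties are asserted: suitable-class Jaccard overlap with truth ≥ 0.5,
informative layers outranking noise in permutation importance, and a known
10-cell eastward shift recovered within half a cell of the truth-raster
oracle. Sample correlations converge to the target within ±0.1 at 200 × 200.

What the generator does **not** emulate: spatial sampling bias, positional
error, non-logistic (e.g. interaction-driven or multimodal) responses,
anisotropic spatial structure, and real geography. Passing recovery tests
therefore demonstrates the machinery is self-consistent under its own
assumptions, not that any real-world map is correct. The true-binary cut is
fixed at 0.5, the usual reading of "probability above 0.5 is suitable".
When evaluating truth on a shifted stack, pass the base stack as
`reference` so standardization constants do not drift with the shrinking
valid mask; otherwise a pure translation would not translate the suitable
set exactly.

## Numerical choices and degenerate inputs

* Occurrence points exactly on an upper or right cell edge belong to the
  lower-index cell; one convention, shared by raster indexing and snapping,
  property-tested on random indices.
* `.asc` values are written at 6 decimals by default (`digits = NULL` gives
  `%.17g` and bit-exact round trips); the GeoTIFF writer stores float64 and
  is always bit-exact. Only the package's own single-band uncompressed
  dialect is read; anything else fails with a named reason.
* Constant layers: dropped with reason `zero_variance` by the correlation
  filter; contribute no threshold/hinge features (logged, not an error);
  are an error for response curves (no range to trace).
* AICc is returned as flagged `NA` with a reason when $n \le k + 1$.
* Thresholds break ties toward the lowest candidate; annealer best-seen
  updates require strict improvement beyond $10^{-12}$.
* Pipeline stage seeds are `seed + stage index`, decoupling stage
  randomness; two runs with one config and seed produce identical artifact
  hashes for every deterministic stage.

## Problem sizes used by the checks

The test suite and acceptance script run the default synthetic study at
100 × 100 cells with a 10,000-cell background cap, calibration subsets of
the candidate grid (a handful of RM × FC combinations), 3 replicate refits,
20-run annealing ensembles at a few thousand moves, and exhaustive planning
oracles at 12 units — sizes chosen so the whole battery completes in a few
minutes on a single core while still exercising every code path at
non-trivial scale. The full 1240-candidate enumeration is always checked;
full candidate *evaluation* at that scale is a production run, not a test.

## Known limitations

* No bias grids, categorical features, or cloglog output; single-band
  rasters only; no reprojection (all inputs must share one grid).
* Percent contribution is path-dependent (as in any gain-attribution
  scheme); prefer permutation importance for correlated layers.
* The balance-threshold weights and the change-rate denominator are
  documented conventions standing in for unstated published formulas.
* The annealer is exact only in the exhaustively checkable regime; for
  large problems it is a stochastic heuristic whose ensemble frequencies,
  not single runs, are the stable output.
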