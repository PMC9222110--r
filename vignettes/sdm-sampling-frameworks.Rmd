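---
title: "Comparing ensemble SDMs across sampling frameworks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ensemble SDMs across sampling frameworks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmcompare)
```

## The problem

Species distribution models (SDMs) link occurrence records of a species --
here, questing hard-bodied ticks -- to gridded environmental predictors and
return, for every raster cell, the probability that conditions there are
suitable. Because the five common algorithm families (logistic regression,
boosted regression trees, random forests, multivariate adaptive regression
splines, and maximum-entropy models) make different assumptions, practice
has converged on *ensembles*: each fitted model's probability surface is
dichotomized at its own threshold and the binary maps are summed into a
consensus score of 0-5, the number of algorithms that call a cell suitable.

The question this package operationalizes is a study-design question: do
ensembles built from *designed* surveys (stratified transect flagging that
yields true presences and true absences) and ensembles built from
*convenience* samples (museum specimens and public submissions, which yield
presence-only records with spatial sampling bias and geocoding positional
error) agree? Everything needed to ask that question quantitatively is
implemented here: the raster substrate, bioclimatic predictors, the five
model adapters behind a single contract, consensus stacking, map-agreement
statistics, and omission-error classification -- plus a synthetic-landscape
generator so the whole pipeline runs end-to-end with no external data.

## Agreement statistics

Two consensus maps on a common grid are compared cell by cell. The
cross-tabulation `cells[b, a]` collects the area scored `a` by one map and
`b` by the other (a 6x6 table for a five-model ensemble). From the cell
proportions `p_ij` with marginals `p_i.` and `p_.j`, Cohen's kappa is

    Po = sum_ij w_ij p_ij,   Pe = sum_ij w_ij p_i. p_.j,
    kappa = (Po - Pe) / (1 - Pe)

with identity weights (`w_ij = 1{i=j}`, plain kappa) or linear
(`1 - |i-j|/k`) or quadratic (`1 - (i-j)^2/k^2`) weights that credit
near-agreement. Standard errors use the classical large-sample
(Fleiss-Cohen-Everitt) variance of the weighted kappa estimate, with the
number of classified units supplied explicitly as the pixel count. Verbal
labels follow the conventional thresholds: below 0 no agreement, 0-0.20
slight (0.20 inclusive), above 0.20 to 0.40 fair, above 0.40 moderate or
better.

Two caveats are deliberate. First, pixel-level independence is assumed by
the SE formula, exactly as in the field's standard usage; neighboring cells
are of course spatially correlated, so the intervals are anti-conservative.
A spatially corrected effective sample size is out of scope. Second, the
package ships the two published 6x6 agreement tables as plain-text fixtures
and validates every marginal against the printed totals (to 0.5 sq km,
i.e. printed rounding) at load time. One cell of the first fixture is
stored with a corrected decimal point: the value printed in the source
table is inconsistent with that table's own printed row, column, and grand
totals by exactly a factor-of-ten digit shift, and the corrected value
restores all three marginals exactly. The fixture file documents this in a
comment. Unweighted kappa on these tables is the validated worked example
(0.060 and 0.053, as the package's tests compute); weighted variants are
provided as options but no published weighted value is asserted, because
the source's several reported kappa values are mutually inconsistent and
only the unweighted ones recompute from the printed tables.

## The model layer

All five algorithms satisfy one adapter contract: consume a training table
of (label, predictors), return a score function into [0, 1]. Labels are 1
for presences and 0 for absences *or* background points; the
maximum-entropy member is implemented as L1-regularized logistic
discrimination of presences against the same 0-labeled rows the other
algorithms see, which is the appropriate equivalence when background data
are shared across algorithms rather than being MaxEnt-private.

Defaults, all exposed through `hyperparameters`:

* **LR** -- `stats::glm`, binomial, no tuning.
* **BRT** -- gradient boosting (xgboost), learning rate 0.01, depth 3,
  subsample 0.8; the tree count is chosen once per training table by
  cross-validated early stopping (cap 500) so every fold refit uses the
  same count. A fixed `nrounds` can be supplied for small runs.
* **RF** -- probability forest (ranger), 500 trees.
* **MARS** -- a forward-stepwise hinge-basis learner with knots at marginal
  quantiles (5 per predictor), a cap of 21 basis functions, backward
  pruning by the classical GCV criterion (penalty 3 effective parameters
  per term), and a final binomial-link refit of the pruned basis. The
  adapter interface is the stable surface; the learner is pluggable.
* **MaxEnt-equivalent** -- `glmnet` lasso logistic, penalty chosen by CV.

Cross-validation is 10-fold (configurable), stratified, and the fold
assignment is created once per table and reused verbatim by all five
algorithms. Thresholds are selected where sensitivity equals specificity:
candidates are midpoints between consecutive distinct scores plus one
candidate below the minimum and one above the maximum; the candidate
minimizing |sensitivity - specificity| wins, ties preferring higher
sensitivity, then lower threshold. By default thresholds are computed on
pooled held-out CV scores -- training scores are optimistic and would
systematically inflate the suitable area -- but `threshold_source =
"training"` is available.

Variable screening is a greedy correlation filter: while any pair of
predictors exceeds |r| = 0.7, the member of the worst pair with the lower
univariate AUC against the label is dropped (ties drop the later name
alphabetically). It runs once per training table, before all five
algorithms; tree-based members may further ignore variables on their own.

## The raster substrate and bioclim layers

Grids are plain matrices with a cell size in meters and a lower-left
origin; 100 m cells make every cell 1 ha, and areas are always
`cells x cell_size^2`. Resampling is extent-preserving: bilinear at target
cell centers for continuous layers (edge targets clamp to the nearest
source center; when some of the four surrounding cells are nodata their
weights are renormalized, and only an all-nodata neighborhood yields
nodata) and majority vote for categorical layers with ties broken by the
lowest code -- a deterministic rule chosen because any tie rule is
arbitrary and this one is reproducible. Land-cover aggregation to the five
primary classes (forest, grass, wetlands, shrub, other) uses the same
majority-with-lowest-code rule. File I/O covers ESRI ASCII grids natively
(full-precision round trip) and TIFF with a plain-text world file for the
geometry; coordinate reference systems are never interpreted.

The 19 bioclimatic variables follow the standard naming. Conventions that
the standard leaves implicit are fixed here: quarters are all 12
consecutive 3-month windows with December-January wraparound, extremes
chosen by scanning every window with ties going to the earliest starting
month; the standard deviations in bio4 and bio15 use the population (1/12)
convention; monthly mean temperature is (tmin + tmax)/2; and isothermality
(bio3 = 100 x bio2/bio7) is returned as nodata when bio7 = 0, since the
ratio is undefined rather than zero. The package computes from one
supplied monthly climatology; building that climatology from daily series
is `aggregate_daily_to_monthly()`, which refuses partial months.

## What the synthetic generator emulates -- and what it does not

`simulate_environment()` produces spatially autocorrelated continuous
predictors by smoothing white noise with a Gaussian kernel matched to the
configured autocorrelation range and standardizing; a fifth-quantile
binning of one further field yields a 5-class land-cover layer. True
suitability is logistic in the standardized layers. This reproduces the
two features that matter for exercising the pipeline -- smooth
multicollinear predictors and a known generating model -- but not
anisotropy, long-range trends, or the mosaic structure of real land cover.

The designed survey stratifies transect starting cells across land-cover
classes in proportion to class area (largest-remainder allocation, exact
by construction), then walks a 150 m segment at a random bearing and
scores a Bernoulli detection with probability equal to the mean true
suitability along the segment. Repeat visits are collapsed into that
single detection probability, mirroring how transects are reduced to
ever-positive/never-positive in practice.

The convenience sample draws cells with probability proportional to
suitability times a sampling-effort surface `exp(-b d / max d)` decaying
with distance from a fixed "population center" (`b = bias_strength`; 0
gives uniform effort), then displaces each point isotropically by a
geocoding error. The error magnitude is log-normal -- the literature
reports ranges of mean errors, roughly 200-800 m, not a distribution
family, so a right-skewed law with occasional large errors is the
realistic single choice -- calibrated to a mean midway between the
configured mean and maximum and hard-truncated at the maximum. Background
points are drawn uniformly, exactly ten per presence by default, with any
draw sharing a 1-ha cell with a presence redrawn: the strictest reading of
the exclusion rule.

Passing tests on these landscapes show the machinery is correct and that
the qualitative design effect (bias degrades cross-method agreement) is
reproducible; they do not certify behavior on real rasters, where
predictor error, temporal mismatch, and non-stationary sampling bias all
co-occur.

## Omission analysis

A presence on a consensus-0 cell is an ensemble omission error.
"Immediately adjacent" is operationalized as the 8-connected neighborhood
of the containing cell (equivalently, nearest predicted cell center within
sqrt(2) cell widths) -- the neighborhood definition is not standardized, and
the 8-connected choice matches the within-one-pixel reading. Distances are
Euclidean to the nearest predicted cell *center*, so zero occurs only for
a point exactly on such a center. Qualitative geocoding-error categories
(obviously wrong locations, poorly formed descriptions) cannot be inferred
from coordinates and are accepted only as input metadata flags. The
temporal association of omissions uses the archive-era bins pre-1940,
1940-1959, 1960-1979, and 1980 onward in a 4x2 Pearson test (3 df; empty
bins are dropped with a warning and the df reduced).

## Problem sizes and reproducibility

Every stochastic stage takes an explicit seed and a configuration fully
determines a run; `run_pipeline()` re-run on the same config reproduces
its summary files byte for byte. The package's own test suite exercises
the end-to-end design effect at 100 x 100 cells (1 ha each) with 500
presences, a 10:1 background ratio, five seeds and three bias levels, and
5-fold cross-validation with reduced tree counts -- sizes chosen to make
the full suite a matter of minutes while keeping every class of check
(exact worked examples, property suites against brute-force oracles, and
the Monte-Carlo design experiment) at full strength. Worked examples off
the shipped agreement-table fixtures are exact and instantaneous.

## Known limitations

* Kappa inference treats pixels as independent units.
* The MARS member is a minimal hinge-basis learner: no interactions, and
  GCV pruning on the squared-error scale before the binomial refit.
* The variable filter is a documented stand-in for unpublished screening
  procedures; it is deterministic but not canonical.
* Rasters are abstract projected grids; no reprojection, no geodesy.
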