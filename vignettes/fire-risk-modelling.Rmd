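---
title: "Modelling landscape fire risk from presence-only hotspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling landscape fire risk from presence-only hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firemaxent)
```

## The estimation problem

Satellite active-fire products detect fires within ~1 km² footprints but
cannot certify absence: a cell without a detection may simply have burned
unobserved. `firemaxent` therefore treats fire mapping as a presence-only
problem. The model grid is 1 km — matching the detection footprint and a
sensible compromise between meso-scale climate variables and micro-scale
land-use variables.

Given presences $x_1,\dots,x_m$ and a background of $N$ cells describing
the available environment, the maximum-entropy estimator chooses the
distribution $q$ over the background that is as close to uniform as
possible while respecting what the presences tell us: the expected value
of each environmental feature under $q$ should match its empirical average
over the presences. In penalised form, with features
$f_j : \text{cell} \to [0,1]$,

$$\hat\lambda = \arg\max_\lambda \; \bar f^\top \lambda - \log Z(\lambda)
  - \sum_j \beta_j |\lambda_j|, \qquad
  q(x) = \frac{e^{\lambda^\top f(x)}}{Z(\lambda)},$$

where $\bar f$ is the presence feature mean and
$Z = \sum_{x \in \text{bg}} e^{\lambda^\top f(x)}$. The Karush–Kuhn–Tucker
conditions give the interpretable guarantee
$|E_q[f_j] - \bar f_j| \le \beta_j$, with equality when
$\lambda_j \ne 0$: regularization *is* the constraint relaxation. The
**gain**, $\bar f^\top\hat\lambda - \log Z + \log N - \sum_j\beta_j|\hat\lambda_j|$,
is 0 for an uninformative model and grows as the fitted distribution
concentrates on presence-like cells.

The **logistic output** maps raw suitability to a relative probability of
presence: $p = \tau e^{H} q / (1 - \tau + \tau e^{H} q)$ with prevalence
$\tau = 0.5$ and $H$ the entropy of the fitted distribution. It is a
strictly increasing transform of $q$, so rankings — and therefore AUC —
are identical under either output; the logistic scale is what the risk
classes and impact analyses consume.

## Features and regularization

Continuous covariates expand by default to linear + quadratic + forward
hinge features (4 knots at background quantiles); categorical covariates
to one indicator per declared code; pairwise products are available but
off by default, mirroring the canonical auto-feature convention for large
samples. All features are affinely scaled to $[0,1]$ over the background,
so weights are comparable and clamping is well defined.

Per-feature regularization follows
$\beta_j = r \cdot \beta_{\text{class}}(m) \cdot s_j / \sqrt{m}$, where
$r$ is the global regularization multiplier (default 1), $s_j$ the feature
standard deviation over presences, and $\beta_{\text{class}}$ a tabulated
per-class base interpolated in the presence count $m$: linear, quadratic
and product features use breakpoints
$(0,10,17,30,100) \mapsto (2.6,1.6,0.9,0.55,0.05)$; categorical indicators
$(0,10,17) \mapsto (0.65,0.5,0.25)$; hinge features a flat 0.5. Heavier
shrinkage for small samples; very mild for the thousands of hotspots
typical here.

## The solver

The objective is concave with an L1 term, solved by full-gradient proximal
ascent: a gradient step on the smooth part, soft-thresholding for the
penalty, backtracking line search with step-doubling between iterations.
The iteration cap is 500 by default (the conventional run length for this
model family) with a convergence tolerance of $10^{-6}$ on the objective
change; a model that hits the cap is returned with `converged = FALSE` and
a warning, never silently. When a caller requests high precision
(`tol < 1e-8`), a final active-set Newton polish drives the stationarity
residual to machine level — this matters for perfectly correlated
features, where first-order methods crawl. Unit tests verify the solver
against an independent convex-optimization oracle (`stats::optim`,
L-BFGS-B on the split-variable reformulation) on dozens of random small
instances, and against a hand-solved instance whose moment condition
reduces to a quadratic in $e^{\lambda/2}$.

The background is every unmasked cell when there are at most 10,000,
otherwise a seeded uniform sample of 10,000; presence cells may also be
background cells (the standard presence-background convention), and
multiple presences in one cell collapse to one record by default.
Degenerate inputs are refused early: presences on masked cells, empty
backgrounds, constant covariates (dropped with a warning, since their
scaling is undefined).

## Covariate construction

* **MCWD** — per cell, the monthly water deficit accumulates as
  $WD_n = \min(0, WD_{n-1} + P_n - 100)$ and the maximum climatological
  water deficit is the most negative value over a 12-month window; the
  100 mm/month threshold proxies evapotranspiration. Accumulation resets
  at a configurable month, defaulting to the climatologically wettest
  month (January for the synthetic seasonality); the convention is
  configurable because source datasets differ. The covariate used by the
  model is the *annual anomaly* of MCWD against a multi-year baseline that
  includes the target year; negative anomaly = drier than baseline.
* **Temperature** — annual anomaly of the mean of monthly land-surface
  temperatures; scaled-integer LST rasters decode with the standard 0.02
  factor (`decode_lst`).
* **Roads** — polylines rasterise to every touched cell (sampled at a
  quarter-cell step); the covariate is the minimum over road classes of
  Euclidean distance × class weight, defaults paved 1.0 / unpaved 0.5.
  The functional form of "distance weighted by road class" is a declared
  package decision: the smaller unpaved weight makes the dense secondary
  network dominate, consistent with unpaved roads being the stronger
  access predictor in this kind of landscape.
* **Settlements** — population-weighted 2-D quartic (biweight) kernel
  density, unit-integral kernel so the surface integrates to total
  population; bandwidth default 10 km. Kernel and bandwidth are package
  choices (no canonical values exist for this covariate).
* **Land-cover fractions** — fine categorical maps aggregate to the share
  of a class per coarse cell; the aggregation factor must divide the fine
  dimensions exactly (no silent cropping), and the coarse mean equals the
  fine mean exactly. Nodata propagates: any masked fine cell masks its
  coarse block.

## Evaluation and variable importance

AUC uses the rank-sum form with ties counted ½ — the probability that a
random presence outscores a random background cell. 25% of records are
held out per run by a seeded split. `replicate_cv` refits on $k$
leave-one-fold-out replicates (default 10) and averages the logistic maps
cell-wise; the averaged map feeds the impact analyses. The jackknife
refits with each variable alone and omitted; percent contribution
attributes the gain accumulated along the optimisation path to source
variables; permutation importance measures the training-AUC drop after
permuting one variable across presence + background points. A
`factorial_selection` helper fits per-group models (development /
environment / climate is the natural grouping here) and backward-prunes
variables whose removal changes gain by less than a tolerance (default
0.01).

## Scenarios and impacts

A scenario is a named set of replacement layers for the *dynamic*
variables only — deforestation, roads, protected areas, and the two
climate anomalies; attempting to replace a static variable is a policy
error. Projections clamp features to their training bounds and report the
clamped-area fraction, which is exactly 0 when projecting the training
stack. "With climate change" means substituting the drought-year anomaly
pair; "without", the normal-year pair — mirroring a calibration on a
drought year so that scenario projections can span more extreme
conditions. Scenario projections reuse the cross-validation replicate
models rather than refitting per scenario; both the fitted-replicate and
refit modes are reachable through the API, but replicate reuse is the
default because the scenario changes covariates, not the fire–environment
relationship.

Risk classes partition $[0,1]$ into low/moderate/high/extreme at 0.25
steps (half-open intervals, top class closed; exactly 0.5 classes as
high). "High fire risk area" uses the strict threshold $p > 0.5$.
Potential biomass loss applies $B_l = (1-\alpha) B_i$ per high-risk cell,
with $\alpha \in [0.7084, 0.90]$ spanning one-to-five-year post-fire loss
without fire recurrence; the central loss factor is the midpoint 0.1958
with half-range 0.0958. Multiple AGB datasets average cell-wise *before*
the loss equation (per-dataset totals are also reported; binning on the
averaged layer is the default of the two possible orderings and is what
the per-bin table shows). Totals use 1 km² = 100 ha and 1 Tg = 10⁶ Mg;
AGB is dry biomass, not carbon. Zonal statistics give mean ± SD of risk
per category of any categorical zoning map; area-weighted zonal means
recompose the global mean exactly, which is tested.

## The synthetic landscape

Because the real regional rasters are not redistributable, the generator
emulates their statistical structure rather than their geometry:

* spatially autocorrelated fields by FFT spectral synthesis (periodic
  boundary — adequate for statistical realism, not for map realism);
* a patchy land-cover mosaic (argmax of three correlated fields at 0.5 km,
  aggregated to fractions at 1 km);
* two paved trunk roads with jittered vertices and eight unpaved branches;
* 25 settlements placed preferentially near roads with log-normal
  populations;
* blocky protected areas, codes 1–4 on an unprotected 0 background;
* monthly rainfall with a July–November dry season, wettest month January,
  annual total ≈ 1100 mm, over 2000–2010; 2010 is generated as a drought
  year (dry-season rainfall × 0.45, +1.5 K) and 2009 as a normal/wet year;
* a true logistic suitability $p^* = \text{logistic}(\beta_0 + \sum w_v z_v)$
  on standardized covariates, whose default weights make road proximity,
  deforestation and settlement density the dominant drivers, multiplied by
  an inhibition factor 0.35 inside protected areas;
* hotspot months drawn with 50% August / 33% September weight, so ~83% of
  fires fall in the two peak months.

Derived covariates are *never* shortcut: the generator produces fine maps,
roads, settlements and monthly climate, then calls the same production
operators users call — a tested invariant. `make_scenario_fixture` builds
the three development trajectories with known directions: deforestation
growth shares one spread field with increasing multipliers (0.05 / 0.30 /
0.60), the B and C variants add one and three paved roads (C's containing
B's, so distances are ordered cell-wise), and the A variant places two new
20×20 protected blocks where the base landscape's true suitability is
highest.

What passing tests on this generator do and do not show: they demonstrate
that the estimator recovers known structure, that the evaluation is
calibrated at chance level under a null, and that the pipeline's
accounting is conservative and deterministic. They do not validate the
model against real fire regimes — real hotspot data carry detection
biases (cloud, canopy, overpass timing), covariates are cross-correlated
in ways the generator only partially mimics, and real landscapes are not
periodic Gaussian fields.

## Problem sizes and numerical choices

Defaults were chosen so a full pipeline runs in minutes on one core: a
200 × 200 km landscape at 1 km, up to 10,000 background cells, 500 solver
iterations. The calibration suite uses 20 landscape seeds for the
null-AUC check, 10 seeds at 100 × 100 for ground-truth recovery, and a
120 × 120 fixture with 3 replicates for the scenario-ordering check;
tie-breaking and boundary conventions (0.5 → high risk, strict threshold
for high-risk area, ½-tie AUC) are stated where they apply. Seeds govern
every random draw — background subsampling, splits, folds, permutations,
field synthesis — so all artifacts regenerate bit-exactly from a config
and a seed.

## Known limitations

GeoTIFF I/O is not included (no GDAL binding is required by the package);
ESRI ASCII grids carry all needed metadata. No CRS handling or
reprojection: all layers must share one grid, enforced everywhere.
Non-integer resampling ratios between fine and coarse grids are out of
scope. Sampling-bias correction for presences and endogenous simulation of
deforestation or road growth are deliberately not modelled: scenarios are
exogenous replacement layers.
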