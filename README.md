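# firemaxent

Presence-only maximum-entropy modelling of landscape fire risk, scenario
projection, and impact accounting — in R, with a synthetic-landscape
generator that provides ground truth for every stage.

## The problem

In seasonally dry tropical forest landscapes (the motivating system is a
dry-forest frontier region at the southern edge of Amazonia), wildfire risk
is driven by the interaction of land-use change — roads, deforestation,
settlement — with increasingly severe dry seasons. Satellite active-fire
detections ("hotspots", ~1 km² footprints) tell us where fire *occurred*,
but never where it reliably did not: the data are presence-only.
`firemaxent` estimates a continuous fire-occurrence probability surface
from such data, projects it onto alternative development and climate
scenarios, and converts the resulting risk maps into decision-relevant
impact numbers (areas at risk, potential aboveground-biomass loss, zonal
summaries over land-use categories).

## The model

Over a background of grid cells, the maximum-entropy estimator finds the
distribution `q(x) ∝ exp(Σⱼ λⱼ fⱼ(x))` that is as spread out as possible
subject to the defining constraint that the expectation of each
environmental feature `fⱼ` matches its empirical average over the presence
sample. Features are functions of the covariates (linear, quadratic,
forward-hinge, categorical indicators), scaled to [0, 1] over the
background. The fit maximises the L1-regularised log-likelihood

```
max_λ  (1/m) Σ_presences ln q(xᵢ)  −  Σⱼ βⱼ |λⱼ|
```

so at the optimum `|E_q[fⱼ] − f̄ⱼ| ≤ βⱼ`, with equality whenever `λⱼ ≠ 0`.
The logistic output `p = τ e^H q / (1 − τ + τ e^H q)` (prevalence τ = 0.5,
H the entropy of the fitted distribution) maps raw suitability to a
relative probability of presence in [0, 1]. Evaluation is by
presence-background ROC (AUC), jackknife gains, percent contribution and
permutation importance; projection onto scenario covariates uses feature
clamping to the training bounds.

The eight standard covariates are built from primitive inputs by the
package itself: shrubland/grassland/deforestation fractions (fine-map
aggregation), weighted Euclidean distance to paved/unpaved roads,
population-weighted settlement kernel density, categorical protected
areas, and annual anomalies of mean temperature and of the maximum
climatological water deficit, MCWD (monthly water balance against a
100 mm/month evapotranspiration proxy).

Risk maps are classified as low [0, 0.25), moderate [0.25, 0.5), high
[0.5, 0.75), extreme [0.75, 1]; potential biomass loss above the
high-risk threshold follows `B_l = (1 − α) B_i` with the proportion of
biomass remaining post-fire α ∈ [0.7084, 0.90] — a central loss factor of
0.1958 ± 0.0958.

## Worked example

```r
library(firemaxent)

land     <- generate_covariates(landscape_config(n_rows = 100, n_cols = 100, seed = 1))
truth    <- true_probability(land$stack, land$config$true_weights,
                             land$config$intercept,
                             inhibition = list(var = "protected", factor = 0.35))
hotspots <- sample_hotspots(truth, 2000, seed = 2)
parts    <- split_sample(hotspots, 0.25, seed = 3)
model    <- fit_maxent(parts$train, land$stack, seed = 4)
summary(model)
#> Maxent fire-risk model: 1298 presences, 10000 background cells
#> Features: 36 (26 with non-zero weight)
#> Regularized training gain: 0.4257  entropy: 8.7987
#> Percent contribution by variable:
#>       road_distance        mcwd_anomaly           grassland           protected
#>                37.3                13.7                13.6                12.3
#>           shrubland       deforestation  settlement_density temperature_anomaly
#>                 9.3                 8.1                 3.0                 2.7

evaluate_model(model, test = parts$test)
#> Training AUC 0.752 | test AUC 0.756 | gain 0.4257

risk <- predict(model)              # logistic output in [0, 1]
classify_risk(risk)
#>     class lower upper cells area_km2
#>       low  0.00  0.25  3598     3598
#>  moderate  0.25  0.50  3876     3876
#>      high  0.50  0.75  2517     2517
#>   extreme  0.75  1.00     9        9
#> total 10000 km2

agb_loss(risk, land$agb)
#> Potential AGB loss above p > 0.50: 6.045 Tg (envelope 3.088-9.003)
#> Loss factor 0.1958 (+/- 0.0958), high-risk area 2526 km2
```

The training gain (0.43) says the model concentrates presences about
`e^0.43 ≈ 1.5` times better than a uniform map; test AUC 0.756 means a
random hotspot outranks a random background cell ~76% of the time. Here
road distance is recovered as the leading driver — it is the strongest
weight in the generating truth. The impact report converts the cells above
p = 0.5 into a biomass-loss envelope spanning the two α endpoints.

Scenario projection swaps the dynamic layers (deforestation, roads,
protected areas, climate anomalies) and re-applies the fitted replicates:

```r
cv  <- replicate_cv(parts$train, land$stack, k = 10, seed = 5)
dry <- project_scenario(cv$models, make_scenario_fixture(land, "C_like", "dry"),  land$stack)
wet <- project_scenario(cv$models, make_scenario_fixture(land, "C_like", "wet"),  land$stack)
compare_scenarios(dry, wet)$high_risk_pct_difference   # drought amplification, %
```

`run_pipeline()` chains all of the above and writes rasters, CSV tables, a
serialized model and a manifest with seeds and checksums.

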