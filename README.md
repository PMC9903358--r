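# streamscape

Multiscale landscape prioritization for stream protection and restoration.

Stream managers increasingly ask a landscape question about a site-scale
problem: when a monitored stream site is in poor biological condition, is
the cause local, or does it sit in a degraded catchment or watershed where
site-level restoration is unlikely to hold? streamscape implements a
screening framework that answers this by crossing **biological condition**
— a Benthic Index of Biotic Integrity (B-IBI, 0–100; poor ≤ 49.98, good
≥ 73.73 under the Western Washington cuts) — with **landscape integrity**
at two spatial scales, each expressed as an indicator on \[0, 1\] (1 = high
integrity) and split at 0.5:

| quadrant (x = catchment, y = watershed) | map class | reading |
|---|---|---|
| high, high | light green | site-level action feasible; *poor* sites here are **underperforming** |
| low, high | dark green | catchment-scale restoration opportunity |
| high, low | yellow | watershed stressors dominate |
| low, low | brown | *good* sites here are **overperforming** |

A surplus of underperforming sites signals that an indicator is not
capturing the regionally important stressor. The package therefore also
implements the pipeline for *finding and substituting* a better indicator:

* **Stream networks** — dendritic segment tables with along-network
  positions, and two direction-specific traversal rules (upstream windows
  branch into tributaries; downstream windows follow the mainstem flow
  path only, truncated at the outlet; default radius 5 km).
* **Dispersal predictors** — per-site inverse-distance barrier scores
  `Σ 1/dᵢ` over typed barriers (lakes, swamps/marshes, road crossings,
  dams), habitat quantity (covered km), and source quality (mean
  probability of good condition over covered segments), plus an
  IQR-separation boxplot screen of barrier types.
* **Indicator scaling** — percentages /100; unbounded indicators
  90%-winsorized (type-7 P5/P95) then divided by their maximum;
  high/low classification with a fixed ≥ 0.5 tie rule; `1 − value`
  stressor view.
* **Model selection** — 3000-tree permutation-importance random forest,
  top-15 with |r| < 0.70 decorrelation; then centred/scaled backward–
  forward stepwise-AIC regression with iterative VIF ≤ 2.5 screening, a
  p < 0.05 significance filter, Breusch–Pagan and normality diagnostics,
  and a per-predictor univariate adjusted-R² decomposition.
* **Synthetic watersheds** — a seeded generator (networks, barriers,
  covariates, integrity indices, B-IBI samples) with known ground truth,
  including a deliberately forest-blind national-style index so the
  substitution phenomenon is reproducible end to end.

## Worked example

Simulate the 500-catchment scenario, classify sites against the
national-style indices, and substitute the regional forest indicator:

```r
library(streamscape)
sim <- simulate_watershed(scenario_config("kingcounty-analog", seed = 1))
cv  <- sim$covariates

orig <- classify_sites(cv, x = "ici", y = "iwi")
table(orig$condition, orig$quadrant)
#>        upper_right upper_left lower_left lower_right
#>   poor          56          3         11           1
#>   fair          93          2          0           0
#>   good          11          0          0           0
table(orig$performance)
#>        expected underperforming  overperforming
#>             121              56               0
```

56 of the 71 poor-condition sites sit in the high/high quadrant: the
catchment index gives no reason for their condition. Fit the regression
pipeline to find what does:

```r
fit <- fit_landscape_model(cv, "mean_bibi",
  predictors = c("pct_forest_cat", "pct_barren_ws", "pct_forest_loss_cat",
                 "sn_deposition_cat", "decoy_noise_1", "decoy_noise_2",
                 "decoy_urban_cat"))
fit
#> <landscape_model> 4 predictor(s), adj R2 = 0.629
#>                  term estimate std_error     t         p
#> 1         (Intercept)    53.52     0.635 84.24 9.20e-142
#> 2      pct_forest_cat     9.30     0.640 14.54  9.45e-32
#> 3       pct_barren_ws    -3.49     0.864 -4.03  8.27e-05
#> 4 pct_forest_loss_cat    -2.31     0.853 -2.70  7.52e-03
#> 5   sn_deposition_cat    -2.20     0.650 -3.39  8.76e-04
#> <model_diagnostics> BP = 5.717 (p = 0.221); Shapiro-Wilk p = 0.0706; ...
fit$decomposition
#>                  term direction univariate_adj_r2 sequential_r2
#> 1      pct_forest_cat  positive        0.45002105    0.45314593
#> 2       pct_barren_ws  negative        0.16793847    0.14886149
#> 3 pct_forest_loss_cat  negative        0.10241491    0.01150501
#> 4   sn_deposition_cat  negative        0.02551787    0.02416479
```

The three decoys are rejected; percent catchment forest dominates
(univariate adjusted R² 0.45 of a 0.63 model fit) with a positive sign:
more forest, better condition. Substituting it for the catchment axis:

```r
cv$forest_scaled <- scale_indicator(cv$pct_forest_cat, "percentage")
revised <- classify_sites(cv, x = "forest_scaled", y = "iwi")
table(revised$performance)
#>        expected underperforming  overperforming
#>             166              11               0
```

Underperformance drops from 56 sites to 11: most formerly unexplained
poor sites are poor-condition sites in low-forest catchments, which is
actionable information. The remaining 11 are candidates for genuinely
local causes.

A command-line front end over the same functions is provided at
`inst/scripts/streamscape` (subcommands `network validate`, `simulate`,
`dispersal`, `scale`, `classify`, `select`, `fit`).

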