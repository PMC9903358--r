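---
title: "Multiscale landscape prioritization: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale landscape prioritization: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

streamscape links stream biological condition -- summarized by a Benthic
Index of Biotic Integrity (B-IBI) on a 0–100 scale -- to landscape integrity
at two spatial scales: the local **catchment** (the land draining directly
to a stream segment) and the **watershed** (the catchment plus everything
upstream). Sites are plotted against two 0–1 integrity indicators split at
0.5, classified into quadrants, and labelled *underperforming* (poor
condition despite high integrity at both scales) or *overperforming* (good
condition despite a low-integrity watershed). The package also implements
the statistical machinery used to replace a national indicator with a
regionally important one when the national indicator fails to explain the
observed condition: network-based dispersal predictors, random-forest
importance screening, and a stepwise multiple regression with collinearity
and significance control. This vignette records the models, their
assumptions, the tunable parameters, and the choices made where the design
was genuinely open.

## The stream network and the two dispersal pathways

The network is a forest of in-trees: each segment drains to at most one
downstream segment, so flow converges at confluences and never diverges.
Divergent (braided) flow cannot be expressed in the input format, by
design; the traversal contracts below all assume dendritic topology.
Positions on the network (sites, barriers) are `(segment, offset)` pairs,
with the offset measured in kilometres from the segment's downstream end.
All distances are along-network, never Euclidean.

Aquatic insects reach a site by two pathways, and each gets its own
traversal rule:

* **Upstream window** (downstream drift, swimming, crawling by larvae and
  aquatic adults): from the site, climb into the mainstem *and every
  tributary*, branching at confluences, out to the search radius. Because
  the window branches, its total covered length regularly exceeds the
  radius.
* **Downstream window** (upstream flight by winged adults): follow the
  unique flow path below the site, truncated at the outlet, and count only
  mainstem-flagged intervals -- adult flight is assumed to proceed up the
  principal channel, never up a side tributary. Distance still accrues
  through non-mainstem portions of the flow path, so a mainstem reach
  2 km below a tributary site is reached at distance 2 km but the
  intervening tributary interval is not covered.

The default radius is 5 km in both directions, the distance beyond which
most stream insects are not observed to disperse; the boundary is
inclusive (`distance <= radius` counts), a convention fixed so tests are
bit-stable. The mainstem is an *input* flag (one headward path per
outlet), as in real hydrography, not re-derived from drainage area; the
synthetic generator flags it by always following the larger-subtree
branch. Downstream windows truncate at outlets only. We considered
additionally truncating them at large-lake barrier positions (a large lake
is where upstream flight effectively originates), but large lakes already
enter the models as their own inverse-distance predictor and truncating
the window as well would double-count the same impediment; the window
operation therefore stays barrier-free.

## Dispersal-limitation predictors

Three families of predictors are computed per site and direction:

* **In-stream connectivity**: for each barrier type (large lake, small
  lake, swamp/marsh, road crossing, dam), the sum of inverse distances
  `sum(1/d_i)` over barriers within the directional window. Nearer
  barriers weigh more; distances below `min_distance_km` (default
  0.01 km) are clamped before inversion so a co-located barrier cannot
  produce an infinite score. All road crossings are treated as equal
  impediments. Size classing of lakes happens upstream of this package;
  barriers arrive typed.
* **Habitat quantity**: total covered stream length (km) of the window.
* **Source quality**: the unweighted mean, over segments with a
  positive-length covered interval, of `p_good`, the externally modelled
  probability that the segment is in good biological condition.
  Averaging is per segment because the probabilities are segment-level
  model outputs; a length-weighted mean was considered and rejected as
  the default since it would silently reweight a model that was not fit
  per kilometre.

Barrier types are screened before entering any regression by comparing
per-site barrier counts between good- and poor-condition sites with an
interquartile-range separation statistic: the lower quartile of the
higher-median group minus the upper quartile of the other. Positive
separation at either screened radius (1 km or 5 km by default) retains
the type. Quartiles -- like every percentile in this package -- use linear
interpolation between order statistics (`stats::quantile`, type 7). A
condition group smaller than 4 sites yields "insufficient data" rather
than a screening verdict. The separation statistic is a reconstruction of
a boxplot-overlap reading and is labelled as such; it is deliberately
simple and monotone in the visual separation of the two boxes.

## Indicator scaling and classification

Arbitrary indicators are mapped to the 0–1 integrity scale by kind:
percentages are divided by 100; already-unit indices pass through;
unbounded indicators (e.g. road-crossing counts) are 90%-winsorized
(clamped to the type-7 P5/P95) and then divided by their
post-winsorization maximum, so 1.0 corresponds to the 95th-percentile cap
whenever clamping occurred -- winsorize first, then find the maximum.
Winsorization applies *only* to unbounded series. Note that type-7
winsorization is exactly idempotent only when the percentile positions
fall on order statistics of the clamped data (e.g. 101 or 201 values);
for other sizes a second application can move the caps slightly.

High/low classification splits at 0.5 with one fixed tie rule: a value of
exactly 0.5 classifies as *high*. The boundary inequalities in common use
overlap at 0.5, so a convention is unavoidable; high keeps good-integrity
semantics conservative for protection screening, and the same rule is
applied at every call site (indicator classes, quadrants, map classes).
Condition thresholds default to the Western Washington B-IBI cuts (poor
<= 49.98, good >= 73.73) and are configurable because other
jurisdictions score differently.

Map classes follow the quadrant through the (watershed, catchment) pair:
(high, high) light green, (high, low) dark green, (low, high) yellow,
(low, low) brown. The yellow/brown split of the two low-watershed cells is
a package convention -- the management reading pools the lower quadrants,
so the split only needs to be stable, and it is verified for internal
consistency rather than against an external definition. Quadrant
composition tables are computed for whatever unit the caller passes:
per-sample rows reproduce sample-based pie charts, per-site rows match
the map symbols; both views are legitimate and they differ, so the
package computes either rather than hard-wiring one.

## The selection and regression pipeline

Stage one filters a large covariate table with a 3000-tree
permutation-importance random forest (mean increase in MSE after
permuting each predictor), keeps the top 15, and then greedily
decorrelates: any retained pair with `|r| >= 0.70` loses its
lower-importance member. Stage two centres and scales all predictors to
mean 0, SD 1 (n−1 denominator), screens them by iteratively removing the
largest variance inflation factor until all VIF <= 2.5
(`VIF = 1/(1 − R²)` from regressing each predictor on the rest), and runs
a backward–forward stepwise search from the *full* model, minimizing the
Gaussian-likelihood AIC. The significance constraint (every term
p < 0.05) is enforced *after* the AIC search, by removing the worst
term and refitting until all survivors are significant -- the two
constraints are stated without an ordering in common practice, and
AIC-then-significance makes the step trace auditable. Dispersal
predictors may be entered directly at the regression stage without
passing the random-forest filter.

Diagnostics report the studentized Breusch–Pagan test, Shapiro–Wilk
normality, residual skewness/kurtosis, and a binned
residual-versus-fitted table. An exact fit returns a Breusch–Pagan
statistic of 0 by convention.

The per-predictor "variation explained" accompanying a final model is the
*univariate* adjusted R² of the simple regression of the response on each
retained predictor, reported alongside the full-model adjusted R² and
coefficient signs. Over correlated predictors these univariate values need
not (and generally do not) sum to the model fit; a sequential
order-of-entry decomposition, which does sum to the model R², is emitted
as an alternative view, and neither is asserted to be the uniquely correct
partition.

A note on what this procedure can and cannot guarantee: with the
significance filter at alpha = 0.05, each pure-noise covariate offered to
the search survives with probability near 0.05. With three decoys the
probability of recovering *exactly* the causal set is bounded by
0.95^3 ~ 0.86 no matter how strong the true effects are. The pipeline's
recovery tests therefore distinguish "every causal predictor found, with
calibrated confidence intervals" (which holds essentially always at
n = 500) from "no false inclusion ever" (which no alpha-level filter can
promise).

## What the synthetic watershed emulates

The generator exists so that every stage -- and the headline substitution
phenomenon -- is testable with known ground truth and no downloads.
Defaults, chosen once:

* **Network**: 500 segments/catchments as a random recursive in-tree,
  lognormal segment lengths (median 1.2 km, sdlog 0.6); 177 monitored
  sites, one per sampled catchment, echoing the size of the motivating
  monitoring program.
* **Covariates**: percent forest ~ 100·Beta(1.5, 1.2) (a broad urban-to-
  forested gradient); percent barren and percent forest loss from a
  two-component mixture in which a *disturbed* minority of catchments
  (probability 0.15, independent of forest cover) carries heavy stressor
  loads; a lognormal sulfur+nitrogen deposition analogue; two pure-noise
  decoys and one urban-correlated (r = 0.5) non-causal decoy. Watershed-
  scale versions are length-weighted means over the watershed, mirroring
  flow-accumulated landscape metrics without reimplementing them.
* **Response**: site latent mean B-IBI = 54 + 16·Zβ with standardized
  effects β = (+0.62 forest-catchment, −0.17 barren-watershed, −0.20
  forest-loss-catchment, −0.15 deposition-catchment), site-level noise
  SD 8, plus 3–8 yearly samples per site with within-site SD 5, clipped
  to [0, 100] (the clipped fraction is tracked and stays below 5%).
  These effect sizes put the model adjusted R² near 0.62 with the forest
  term dominating the univariate decomposition -- the regime the package
  is designed to analyse.
* **Indices**: synthetic catchment/watershed integrity =
  1 − (0.30·barren + 0.40·loss + 0.30·deposition stressors), with
  **forest weight 0**. The indices are deliberately blind to the
  covariate that drives condition: a dominant regional driver diluted out
  of a many-stressor national index is precisely the mechanism that makes
  the national indicator insufficient and the substitution informative.
  The disturbance mixture gives the indices a realistic low tail, so all
  four quadrants are occupied.
* **`p_good`**: logistic in the segment's linear predictor *plus*
  logit-scale error (SD 1). The error matters: an error-free `p_good`
  would make windowed source quality an exact transform of the causal
  covariates and collinearity screening would then eject the true forest
  predictor -- the opposite of how an independently modelled probability
  behaves.
* **Barriers**: Poisson per type and per km (road crossings 0.40/km,
  swamp/marsh 0.10, small lakes 0.05, large lakes 0.02 mainstem-only,
  dams 0.01 mainstem / 0.005 tributary), non-causal for the response.

What the generator does *not* emulate: spatial autocorrelation of land
cover, the real covariance structure of landscape metrics, the actual
national index formulas, gauged flow, or any real geography. Passing
tests therefore demonstrate that the pipeline's logic realizes the
intended mechanisms under clean conditions, not that it would recover the
same model from field data.

## Numerical conventions and degenerate inputs

* Percentiles and quartiles: `stats::quantile` type 7, project-wide.
* SDs use the n−1 denominator; AIC uses the Gaussian log-likelihood form.
* Zero-length covered intervals are dropped from windows; a window that
  covers nothing yields source quality `NA` rather than 0.
* Zero-variance predictors are dropped from standardization with a
  warning; exact collinearity surfaces as an infinite VIF and is removed
  first.
* Ties: indicator value exactly 0.5 is high; barrier distance exactly at
  the radius is included; equal screening medians take the larger of the
  two directional separations.
* Random-number use is seeded explicitly everywhere (`config$seed` with
  fixed offsets per generator stage), so identical configurations
  reproduce byte-identical tables.

## Problem sizes used by the test suite

The suite validates traversal against brute-force enumeration on 50
random networks of up to 30 segments; runs 100 replicates of the
500-sample regression recovery; 1000 replicates of the Breusch–Pagan
calibration at n = 300 (plus 200 power replicates); and one full
end-to-end run of the 500-catchment scenario including the 3000-tree
forest. These sizes keep the whole suite to a few minutes on one CPU
while leaving the Monte-Carlo assertions comfortably away from their
thresholds.

## Known limitations

* Dendritic topology only; braided channels are rejected at build time.
* The downstream pathway interprets "mainstem" through the global input
  flag, so a site on a tributary has no covered interval until its flow
  path reaches the mainstem; with flags derived relative to each site the
  covered set would differ.
* The boxplot screening statistic reconstructs a described procedure
  whose exact definition is not public; it is documented, deterministic,
  and monotone in box separation, but not guaranteed identical to the
  original.
* The quadrant framework is a screening device: it does not rank sites
  within a quadrant, and the package deliberately stops short of
  management recommendations beyond the class labels.
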