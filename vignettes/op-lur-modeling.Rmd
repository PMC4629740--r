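---
title: "Land use regression modeling of the oxidative potential of fine particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land use regression modeling of the oxidative potential of fine particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oplur)
```

## The problem

Oxidative potential (OP) — the intrinsic capacity of particulate matter to
oxidize target molecules — is a candidate exposure metric for the health
effects of fine particles that integrates particle size, surface and
composition rather than mass alone. Epidemiological use requires a spatial
exposure surface, and the standard instrument for that is land use regression
(LUR): a linear model linking annual-average concentrations measured at a
modest number of monitoring sites to GIS-derived predictors (road length,
traffic load, population density, land cover) that are available everywhere.

`oplur` implements the complete chain for a repeated short-term campaign
with two acellular OP metrics:

* `OP_DTT` — dithiothreitol consumption rate, in nmol DTT/min/m³ of sampled
  air;
* `OP_ESR` — electron-spin-resonance signal of trapped hydroxyl radicals, in
  A.U./m³.

The campaign design it targets is a two-country network of 40 sites — 10
regional background (RB), 12 urban background (UB) and 18 street (S) sites —
each sampled for three two-week periods across seasons (120 filters per
metric), with one centrally located reference site monitored in every
two-week period of the year.

## From raw filters to annual averages

Raw values are corrected by subtracting the mean field blank
(`blank_correct()`); negative or below-detection results are flagged and
retained, never dropped, because dropping them would bias low-concentration
sites upward. Each measurement is then adjusted for temporal variability by
the contemporaneous deviation of the reference site from its annual mean:

$$ y^{adj}_{ip} = y_{ip} - (r_p - \bar r), $$

a signed additive correction (`temporal_adjust()`): a period in which the
whole domain ran above its annual level pulls co-measured sites down by that
common excess. A multiplicative (ratio) variant is deliberately not offered;
for OP the seasonal component is closer to additive (combustion background)
than proportional, and the additive form keeps the adjustment exactly
zero-sum over the reference's own periods. The per-site annual average is the
arithmetic mean of the adjusted values over the periods actually measured
(`adjusted_annual_averages()`), with the period count reported.

One subtlety is worth stating precisely. If a constant is added to one period
at every site *and* at the reference site, each adjusted annual average moves
by the same small constant (the shift re-enters through the reference's
recomputed annual mean, attenuated by the number of reference periods);
between-site contrasts — the only quantity the LUR model sees — are exactly
invariant. Exact invariance of each individual average holds only when the
reference annual mean is held at its full-year value, which
`adjusted_annual_averages(reference_annual_means = ...)` supports.

## Spatial contrast analyses

`contrast_report()` reproduces the campaign's descriptive toolkit per metric:
summary statistics by site type; the spatial contrast expressed as the range
as a percentage of the mean; a one-way fixed-effects ANOVA across the three
site types; and site-type concentration ratios estimated by regressing
log concentrations on site type and exponentiating the slopes. Urban
background is the reference level, so the two slopes are directly the S/UB
and RB/UB ratios; S/RB comes from a refit with RB as reference so that it
carries its own standard error rather than a delta-method one. p-values are
two-sided t-tests on the log-scale slopes (the ANOVA is reported separately
and not used for the ratio stars). Between-metric agreement is summarised by
`squared_pearson_matrix()`, pairwise-complete, as squared Pearson
correlations.

## Regional background by inverse-distance weighting

Large-scale gradients in OP are not captured by buffer predictors, so the
regional background at each site is offered to the model as a predictor in
its own right: the inverse-distance-squared weighted mean of the annual
averages at the regional sites, always excluding the site itself when it is
regional (`regional_background()`). Estimates are convex combinations of
donor values, invariant to rigid motions of the coordinate system; a
coincident donor returns its own value (ties: their mean). Including the
background as a predictor rather than subtracting it keeps its share of the
explained variance visible in the model table.

## Supervised model development

`fit_lur()` follows the supervised forward procedure used throughout the
ESCAPE LUR literature, with every threshold exposed:

1. **Zero screening** (`screen_predictors()`): buffer variables with exact
   zeros at more than `ceiling(0.75 * N)` sites (30 of 40) are removed.
2. **Forward selection** (`forward_select()`): each remaining candidate is
   test-fitted alongside the current terms; a candidate is eligible only if
   its own slope *and* every previously entered slope keep their a-priori
   directions in the trial fit (traffic/urbanity/background `+`,
   seminatural land `-`). The eligible candidate with the highest adjusted
   R² enters if the gain exceeds `delta = 0.01`. Ties at machine precision
   are broken by the entrant's absolute t statistic, then name, so runs are
   deterministic.
3. **p-value pruning** (`prune_pvalues()`): terms with `p > 0.10` are removed
   one at a time (largest first), refitting in between; a term whose sign
   flips against its a-priori direction during refits is removed the same
   way.
4. **Collinearity** (`prune_vif()`): if any variance inflation factor
   exceeds 3, the worst offender is blacklisted and selection is *restarted*
   on the remaining pool (rather than merely refitting the survivors), since
   the offender may have shaped the whole selection path.
5. **Diagnostics**: Cook's distances flag — but never modify — models with
   `max D > 1`; Moran's I of the residuals is reported with its
   randomization-assumption expectation, variance and two-sided p.

Coefficients are reported in the standardized convention of the field: raw
slope times the predictor's P90 − P10 spread over the training sites
(linear-interpolation quantiles), so each coefficient reads as the
concentration contrast associated with a typical predictor range; the
intercept is unscaled. The per-term "cumulative adjusted R² at entry" column
reproduces the partial-R² column of campaign model tables, recomputed for
the final term order.

Numerical conventions: an exact (zero-residual) fit yields `NaN` standard
errors from `summary.lm`; such slopes are exactly determined, so their
p-values are treated as 0 and the perfect-fit warning is muffled. Moran's I
weights default to row-standardized inverse distance (1/d, zero diagonal),
configurable to binary k-nearest-neighbour.

## Validation

Two complementary estimates of predictive performance, both reported as the
squared Pearson correlation between observed and predicted values (with the
`1 - SSE/SST` variant alongside):

* **LOOCV** (`loocv()`): the *structure* is held fixed; coefficients are
  re-estimated on each N−1 subset. For an intercept-only structure the
  leave-one-out means are a degenerate affine function of the held-out
  values, so the correlation-based R² is reported as 0 by convention.
* **Holdout validation** (`holdout_validation()`): ten random splits,
  stratified 50/50 by site type (5 RB + 6 UB + 9 S in training), with the
  *entire* development pipeline rerun on each training half. Odd type counts
  put the floor in training. The summary is mean ± SE (SD of the ten split
  R² values over √10). Per-split seeds are derived from the master seed by a
  fixed counter, so requesting more splits never changes earlier ones. A
  split whose redeveloped model is empty predicts a constant and scores 0.

The holdout mean sits below the full-model R² on average — the expected
overfitting gap when models are redeveloped on 20 sites — and the test suite
asserts exactly that property over repeated simulated campaigns rather than
any fixed gap size.

## The synthetic campaign generator

No campaign data are shipped; `generate_campaign()` simulates campaigns with
the statistical structure the analysis assumes, and is itself first-class,
tested code. Design choices, all fixed once:

* **Geometry.** Sites live in a 300 km square; UB and S sites cluster
  (SD 4.5 km) around four random urban centres, RB sites are drawn uniformly
  at least 24 km from every centre — reproducing the RB/UB/S contrast
  without real GIS.
* **Predictors.** Traffic variables (road length in 500 m, traffic load in
  50 m, traffic-intensity × inverse-distance) are log-normal with
  site-type-dependent location parameters (street ≫ urban ≫ regional);
  population density within 5 km decays with distance to the nearest urban
  cluster; seminatural/forested cover is a beta-distributed share of its
  buffer, higher outside cities. Small-buffer traffic load is zeroed at 60%
  of UB and 90% of RB sites, and a decoy predictor with ~88% zeros exists
  purely to exercise the zero screen. A further log-normal decoy is
  unrelated to OP.
* **Generating model.** Per metric, the true annual surface is
  intercept + smooth polynomial regional trend + slope·(one traffic
  variable) + slope·(population density). Slopes are scaled so each local
  term's P10–P90 contribution is a sizeable fraction of the intercept, the
  balance seen in published OP models.
* **Noise.** Each two-week measurement adds seasonal offsets (winter-high
  cosine over 26 periods, centred to zero annual mean), Gaussian noise and
  the assay blank. The default noise SDs (0.59 nmol DTT/min/m³; 820 A.U./m³
  per period) were solved from the variance decomposition so that the
  generating model explains ≈ 70% of the between-site variance of the
  adjusted annual averages — the regime in which published OP models
  operate. The reference series shares the same noise model.
* **Reference site.** One extra, non-roster site at the region centre is
  monitored in all 26 periods; roster sites sample periods 5, 14 and 22
  (spring, summer, winter). Because the sampled periods' seasonal offsets do
  not average to zero, unadjusted 3-period means are biased and the temporal
  adjustment is consequential; after adjustment, noiseless campaigns
  reproduce the true annual means exactly.
* **Reproducibility.** Geometry and predictors are drawn under a
  geometry seed derived from (but distinct from) the noise seed; identical
  configurations are byte-identical, and varying the noise seed at a fixed
  geometry seed redraws only the measurements.

What the generator does *not* emulate: real GIS covariance structure between
buffer sizes of the same variable (the campaign's predictor inventory has
dozens of nested buffers; we generate one per concept), spatially correlated
measurement error, seasonal interactions between site type and temporal
offsets, co-measured elemental composition, and below-detection censoring
mechanics. Passing tests therefore demonstrate the correctness and the
statistical behaviour of the *procedure* under a faithful stylized design —
not the field performance of any particular model on real campaigns.

## Problem sizes used by the test suite

The suite exercises: structural checks on single default campaigns
(n = 40 sites); oracle equivalence on fixtures of 5–15 sites (brute-force
Moran's I, naive LOOCV loops, exhaustive forward-selection enumeration,
closed-form VIF); a constraint-satisfaction sweep over 100 simulated
campaigns; parameter recovery over 50 campaigns at the default noise level
plus exact-recovery checks on noiseless, trend-free campaigns; and the
overfitting-gap property over 30 campaigns with 10 holdout splits each.
These sizes were chosen to make the stochastic assertions stable across
seeds while keeping a full run around a minute on a single core.

## Known limitations

* The supervised protocol inherits the instability of greedy selection at
  n = 40; holdout validation makes this visible rather than fixing it.
* The correlation-based validation R² ignores calibration (an affinely
  mis-scaled predictor scores perfectly); the `1 - SSE/SST` variant is
  reported for that reason.
* Moran's I uses a normal approximation under randomization; at n = 40 with
  heavy-tailed residuals its p-values are approximate.
* Coordinates are planar meters throughout; no CRS handling is attempted.
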