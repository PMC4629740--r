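# oplur

Land use regression (LUR) modeling of the oxidative potential (OP) of fine
particles (PM2.5), from raw repeated two-week site measurements to validated
spatial exposure models.

## What problem this solves

Oxidative potential — measured here by two acellular assays, dithiothreitol
consumption (`OP_DTT`, nmol DTT/min/m³) and electron spin resonance of
trapped hydroxyl radicals (`OP_ESR`, A.U./m³) — is a candidate
health-relevant alternative to PM mass. To use it in cohort studies one
needs a model of its long-term spatial variation. `oplur` is for exposure
scientists and biostatisticians who run (or simulate) multi-site monitoring
campaigns: it turns a site roster, a long table of raw two-week
measurements, a reference-site series and a site × predictor table into
temporally adjusted annual averages, site-type contrast analyses, a
supervised direction-constrained LUR model, and cross-/holdout-validated
performance estimates.

The model at the core is ordinary least squares with supervised forward
selection under a-priori sign constraints (the ESCAPE protocol). For site
annual averages $y_i$ and candidate predictors $x_{ij}$:

$$ y_i = \beta_0 + \sum_{j \in M} \beta_j x_{ij} + \varepsilon_i $$

where the term set $M$ is grown greedily — a candidate enters only if its
slope and all previously entered slopes keep their a-priori directions and
the adjusted R² gain exceeds 0.01 — then pruned to `p ≤ 0.10` and
`VIF ≤ 3`, checked for influence (Cook's D) and residual spatial
autocorrelation (Moran's I), and validated by leave-one-out CV (fixed
structure) and 10-fold stratified 50/50 holdout validation (full
redevelopment per split). The regional background, interpolated by
inverse-distance-squared weighting over the regional sites (leave-self-out),
is offered as an ordinary candidate predictor. Coefficients are reported as
raw slope × (P90 − P10) of the predictor, the standardized convention of the
field.

Because campaign data of this kind are not generally shareable, the package
ships a tested synthetic-campaign generator emulating a 40-site two-country
design (10 regional background + 12 urban background + 18 street sites,
3 two-week periods each, a 26-period reference series), with site-type
dependent, zero-inflated GIS-style predictors and a smooth regional
gradient. See the methods vignette (`vignettes/op-lur-modeling.Rmd`) for
every modeling and design decision.

## Worked example

```r
library(oplur)

camp <- generate_campaign(campaign_config(seed = 11))
ann  <- adjusted_annual_averages(camp$measurements, camp$reference,
                                 blank_means = c(OP_DTT = 0.12, OP_ESR = 850))
wide <- annual_wide(ann)
wide <- wide[match(camp$sites$site_id, wide$site_id), ]

site_type_ratios(wide$OP_ESR, camp$sites$site_type)
#>   contrast     ratio      p_value
#> 1     S/UB 1.2238732 4.653789e-04
#> 2    RB/UB 0.8278118 3.436717e-03
#> 3     S/RB 1.4784438 2.643426e-08

reg <- regional_background(camp$sites, ann)
rb  <- reg[reg$metric == "OP_ESR", ]
tab <- add_predictor(camp$predictors, "regional_estimate_OP_ESR",
                     setNames(rb$estimate, rb$site_id),
                     direction = "+", units = "A.U./m3")
model <- fit_lur(setNames(wide$OP_ESR, wide$site_id), tab, sites = camp$sites)
model
#> Supervised LUR model (n = 40 sites)
#>         predictor std_coef  se       p cum_adj_r2
#>   traffic_load_50      855 173 1.8e-05       0.57
#>  pop_density_5000      528 192 9.3e-03       0.68
#>  ti_invdist_major      414 214 6.1e-02       0.71
#>   intercept 2709 (unscaled)
#>   Model R2 = 0.73; adjusted R2 = 0.71; RMSE = 386
#>   max VIF = 1.72; max Cook's D = 0.13; Moran's I = -0.030 (p = 0.93)
```

Street sites run ~22% above urban background and regional sites ~17% below
(both significant); the selected model explains 73% of the between-site
variance with a local traffic term, an urbanity term and a second road
variable, all sign-conforming, non-collinear, and with no residual spatial
autocorrelation. Standardized coefficients read as concentration contrasts:
moving from the 10th to the 90th percentile of traffic load within 50 m
raises predicted `OP_ESR` by 855 A.U./m³.

```r
cv <- loocv(model)
hv <- holdout_validation(setNames(wide$OP_ESR, wide$site_id), tab,
                         camp$sites, seed = 11)
#> LOOCV R2 = 0.66; RMSE = 430 A.U./m3
#> HV R2 = 0.56 +/- 0.05 (mean +/- SE, squared correlation)
```

The drop from model R² (0.73) through LOOCV (0.66) to holdout validation
(0.56) is the expected overfitting gradient when 40-site models are
redeveloped on 20-site training halves. `run_pipeline(list(seed = 11))`
chains all of the above (both metrics, artifact files, printed summary) in
one call.

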