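Package: oplur
Title: Land Use Regression Modeling of the Oxidative Potential of Fine Particles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing spatial variation of the oxidative potential
    (OP) of PM2.5 from repeated short-term monitoring campaigns, and for
    building land use regression (LUR) exposure models from the resulting
    temporally adjusted annual averages. Implements blank correction and
    reference-site temporal adjustment, site-type contrast analyses
    (range-as-percent-of-mean, one-way ANOVA, log-linear site-type ratios,
    squared Pearson correlation matrices), inverse-distance-squared regional
    background interpolation, ESCAPE-style supervised forward selection with
    a-priori direction constraints and p-value/VIF pruning, influence and
    spatial-autocorrelation diagnostics (Cook's D, Moran's I), leave-one-out
    and stratified holdout validation, and between-model prediction
    comparison at held-out receptor sites. A synthetic monitoring-campaign
    generator emulating a 40-site two-country design makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    car,
    withr,
    yaml
Config/testthat/edition: 3
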