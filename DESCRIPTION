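Package: methlss
Title: Location-Scale Regression Models for DNA Methylation Beta-Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood location-scale regression for site-level DNA
    methylation proportions: Gaussian models on raw, binary-logit (M-value) and
    arcsine-square-root (A-value) transformed beta-values, and beta regression
    in the mean-dispersion parametrisation, each with a fixed or
    covariate-dependent scale submodel. Includes Wald and resampling-based
    inference for covariate effects on methylation level and variability (a
    parametric bootstrap under the null followed by rank-based reassignment of
    the observed values), randomized-quantile-residual diagnostics, pseudo-R2
    model comparison with train/test splits, a simulation engine for type-I
    error and power of the competing models, a synthetic methylation data
    generator, and EWAS-style genome-wide screening for differentially
    methylated and differentially variable CpG sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), mgcv, mclust, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
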