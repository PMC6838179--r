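Package: vsprofiler
Title: Variation Spatial Profiling of Protein Variant Phenotype Landscapes
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns a sparse table of protein variants with paired functional
    measurements into a dense, uncertainty-quantified phenotype landscape over
    (sequence position x function) coordinates by molecular variogram analysis
    and ordinary Kriging with local neighborhoods. Includes empirical
    semivariogram computation and model fitting (spherical, linear,
    exponential, gaussian families), Kriging prediction with exact
    interpolation and Kriging variance, confidence-quantile landscape masks,
    delta-landscapes between treatment conditions, leave-one-out and k-fold
    cross-validation with inverse-variance-weighted Pearson correlation,
    per-residue projection of landscapes onto protein structures via B-factor
    annotation, and a Gaussian-random-field simulator for generating variant
    datasets with known spatial covariance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    withr,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
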