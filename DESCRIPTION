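Package: methclock
Title: Uncertainty-Aware Epigenetic Age Clocks from Bisulfite Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds DNA-methylation age-prediction models ("epigenetic
    clocks") from targeted bisulfite-amplicon read counts for populations
    where no known-age training animals exist. Quantifies CpG methylation
    with bisulfite conversion-efficiency correction, represents each
    individual's catalogue-based age estimate as a confidence-weighted
    skew-normal probability distribution, searches a grid of clock training
    designs (elastic net, random forest, support vector and generalised
    additive regression; log-age transform; stepwise CpG site selection;
    training-sample subsets and confidence weighting), and propagates age
    and methylation uncertainty by resampling into per-sample predicted-age
    distributions with 95% highest-density intervals and longitudinal
    ordinality checks. Includes a synthetic cohort generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    mgcv,
    quadprog,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
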