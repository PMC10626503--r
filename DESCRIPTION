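Package: evaccum
Title: Accumulator Microcircuit Models of Evidence Accumulation in Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and fitting of evidence-accumulation microcircuits
    (single drift-diffusion, independent-race and dependent-race accumulators)
    formulated as recurrent switching linear dynamical systems with Poisson
    spike emissions, fitted by a variational Laplace-EM algorithm. Includes
    combined-condition auROC selectivity statistics (stimulus selectivity,
    choice probability, detect probability, evidence selectivity) with
    shuffle-null significance, accumulation-latency estimation, demixed
    principal component analysis with fuzzy C-means grouping of neurons,
    sample-based AIC model comparison, intrinsic-timescale estimation from
    spike-count autocorrelations, and a synthetic two-alternative contrast
    discrimination task generator with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    minpack.lm,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
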