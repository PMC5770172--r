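Package: pomcal
Title: Calibrating Populations of Cardiac Action Potential Models to
    Biomarker Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building populations of models (POMs) of the human
    atrial action potential that reproduce the full multivariate distribution
    of experimentally measured biomarkers, rather than only their ranges.
    Provides a Courtemanche-Ramirez-Nattel (CRN) single-cell simulator with
    conductance scaling and a configurable pacing protocol, extraction and
    validation of seven standard action-potential biomarkers, multivariate
    Gaussian kernel density estimation of the biomarker joint distribution
    with a normal-reference bandwidth rule, a tempered sequential Monte Carlo
    sampler targeting densities proportional to the data density of model
    outputs, refinement of candidate populations by fixed-temperature
    Metropolis subset selection against a Jensen-Shannon divergence matrix,
    and downstream analyses (Latin-hypercube range calibration, median-model
    construction, Mann-Whitney parameter comparisons, and ion-channel block
    experiments). A synthetic-data module generates biomarker tables with the
    qualitative structure of clinical atrial datasets and fast closed-form
    surrogate forward models so the whole pipeline can be exercised end to
    end in seconds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    mclust,
    lhs,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
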