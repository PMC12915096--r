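Package: probekit
Title: Two-Tier Screening of Fluorescent Probe Candidates with a
    Solvent- and Wavelength-Conditioned Message-Passing Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering small-molecule fluorescent probe
    candidates from tabular SMILES libraries. Implements curation of
    heterogeneous photophysical datasets (canonicalization, activity-score
    labeling, duplicate merging, replicate-tolerance filtering), a directed
    bond-centric message-passing neural network conditioned on either an
    absorption/emission wavelength pair (fluorescence-activity classifier)
    or a solvent structure (regressors for seven photophysical properties),
    a two-step retrieval-then-prediction screening pipeline with threshold
    filtering, chemical-space characterization (Bemis-Murcko scaffolds,
    ECFP4 fingerprints, t-SNE), fluorescence assay curve fitting
    (Forster-Hoffmann viscosity response, one-site and Hill saturation
    binding, inhibition rates), and a synthetic fluorophore generator with
    planted structure-property rules for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    ChemmineR,
    ChemmineOB,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    utils,
    tibble,
    tidyr,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    pROC
Config/testthat/edition: 3
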