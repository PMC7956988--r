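Package: presbyfit
Title: Causal and Bayesian Modelling of Aided Consonant Identification in
    Presbycusis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for disentangling audibility-related and age-related
    deficits in aided consonant identification by elderly listeners.
    Provides a causal-DAG layer (d-separation under selection, implied
    conditional independencies, adjustment-set checks for collider bias
    induced by study inclusion), a synthetic cohort generator reproducing
    the demographic, audiometric and selection structure of a multi-site
    presbycusis study, hearing-aid gain and masker band-level computation,
    an extended speech intelligibility index (ESII) with forward masking,
    and hierarchical Bayesian guess/lapse psychometric models fitted by
    MCMC with PSIS-LOO model comparison and counterfactual effect
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
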