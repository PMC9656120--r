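Package: brainatrophy
Title: Causal and Bayesian Analysis of Brain Atrophy Proxies in Elderly Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying lifetime brain atrophy in elderly cohorts from a
    single structural MRI per subject. Parses FreeSurfer-style aseg.stats files,
    computes the brain-to-intracranial-volume ratio (Brain2ICV = TBV/eTIV) as an
    atrophy proxy, runs a descriptive and frequentist screen (group t-tests,
    mixed-type association matrix, per-predictor OLS ANOVA), fits a Bayesian
    index-variable group model with a self-contained adaptive Metropolis sampler
    (posterior contrasts, highest-density intervals, posterior predictive draws),
    and encodes the study's causal DAG to demonstrate collider structure and
    conditional-independence via nested Bayesian regressions. A seeded synthetic
    cohort generator with linear-Gaussian structural equations makes the full
    pipeline testable without any real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
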