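Package: twinfam
Title: Twin-Family Analysis of Binary Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical analysis of binary (affected/unaffected) phenotypes
    in twin-family cohorts: maximum-likelihood casewise concordance,
    pairwise correlation and Plackett odds-ratio twin-similarity models with
    delta-method confidence intervals and likelihood-ratio tests of
    monozygotic versus dizygotic differences; fixed- and random-intercept
    logistic regression for familial aggregation (co-twin, sibling, mother,
    father); and a liability-threshold ACE simulator that generates
    synthetic twin-family cohorts with closed-form expectation oracles.
    Includes cohort readers and writers, index-twin selection, and report
    rendering in the conventional twin-study table layouts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), lme4, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
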