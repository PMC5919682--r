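Package: prcapanel
Title: Germline Variant Prioritization for Hereditary Prostate Cancer Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementation of a germline variant prioritization
    workflow for multi-gene cancer predisposition panels applied to
    early-onset/familial prostate cancer cohorts. Provides the variant filter
    cascade (coverage, allele fraction, population frequency, consequence and
    clinical-database rules) with a per-variant audit trail, in-silico
    predictor consensus calling for missense and splice variants, an ACMG-AMP
    evidence combination engine with a manual evidence overlay, exact
    case-control carrier frequency tests, family-history criteria
    classification, carrier attribution and cohort accounting, plus a
    synthetic cohort generator and a packaged fixture cohort for end-to-end
    testing without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
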