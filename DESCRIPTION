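Package: olvfss
Title: Vertebral Fractural-Deformity Scoring and Hip-Fracture Screening Performance
Version: 0.1.0
Authors@R:
    person("Cohort", "Analyst", email = "analyst@example.org", role = c("aut", "cre"))
Description: Tools for extended semi-quantitative (eSQ) grading of osteoporotic-like
    vertebral fractural deformities (OLVF) from spine radiograph morphometry, the OLVF
    sum score (OLVFss) over vertebrae T3-L5 with adjacency adjustment rules, sex-specific
    baseline positivity metrics combining DXA T-score cutpoints with OLVF-based scores,
    and crude screening operating characteristics (positive predictive value, detection
    sensitivity, incidence, risk ratio) for prospective hip-fracture follow-up cohorts.
    Includes a latent-frailty synthetic cohort generator so that every pipeline stage is
    testable without access to the original cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
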