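Package: netmapr
Title: Individual-Specific Functional Network Mapping by Template Matching
Version: 0.1.0
Authors@R: person("netmapr", "Developers", role = c("aut", "cre"),
    email = "netmapr@example.org")
Description: Derives reference functional-network templates by k-means
    clustering of concatenated parcel-wise functional connectivity (FC)
    profiles with split-half stability selection of the number of networks,
    assigns each cortical vertex to its best-matching network by a
    winner-take-all correlation rule, and quantifies partition reliability
    (normalized mutual information with permutation nulls and data-amount
    titration), population consensus and variability (spatial probability,
    versatility), hemispheric laterality, and brain-behavior association
    with linear mixed-effects models and grouped cross-validated age
    prediction. Includes a synthetic-cohort generator (surfaces, planted
    network topographies, BOLD-like sessions with bursty head motion,
    behavior tables with planted effects) so the full pipeline is testable
    without restricted data, plus framewise-displacement computation with
    respiratory notch filtering and epoch-based motion censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
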