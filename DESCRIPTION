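Package: ketsim
Title: Pharmacological Dysconnectivity Templates and Similarity Coefficients
    for Seed-Based Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives a drug-induced thalamic dysconnectivity template from
    seed-based resting-state functional connectivity contrasts and scores
    individual participants against it. Implements first-level voxelwise
    seed regression on 4D BOLD-like volumes, within-participant fixed-effects
    contrasts, group one-sample t-maps with sign-flip permutation
    cluster-extent inference, normative-deviation z-scoring against healthy
    control reference regressions (site or age models), per-participant
    template similarity coefficients with Fisher r-to-z transformation, and
    the downstream group and symptom statistics (covariate-adjusted ANOVA
    contrasts with Cohen's d, interaction-dropping symptom regressions,
    Benjamini-Hochberg false discovery rate control). A synthetic-data
    generator produces cohorts, BOLD sessions, connectivity maps and symptom
    tables with the statistical structure every stage assumes, so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    emmeans,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
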