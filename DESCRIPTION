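Package: mifquant
Title: Quantitative and Spatial Profiling of the Tumor Immune
    Microenvironment from Multiplex Immunofluorescence and Immune Gene
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize the tumor immune microenvironment from
    segmented multiplex-immunofluorescence cell tables and immune-panel gene
    counts, as applied to HPV-positive and HPV-negative oropharyngeal
    carcinoma. Provides marker-based cell phenotyping, tumor-nest/stroma
    compartment assignment, compartmentalized cell densities and population
    ratios, nearest-neighbor and count-within-radius spatial proximity
    statistics, housekeeping-gene normalization with two-group differential
    expression and gene-set signature scoring, median-dichotomized
    disease-free-survival analysis (Kaplan-Meier, log-rank, univariate Cox),
    and a fully seeded synthetic cohort generator that emulates the
    HPV-status contrasts these analyses are designed to detect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
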