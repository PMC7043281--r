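Package: nafldsubtypes
Title: EMR-Based Phenotyping and Subtype Discovery for Non-Alcoholic
    Fatty Liver Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for defining a non-alcoholic fatty liver
    disease (NAFLD) cohort from multi-table electronic medical record (EMR)
    extracts and discovering clinically distinct patient subtypes. Includes
    a synthetic EMR generator with a planted latent subtype structure,
    keyword natural-language search with negation and family-history
    filtering, a rule-based electronic phenotype (persistent ALT elevation,
    diagnosis codes, exclusions, steatosis evidence), binary clinical
    featurization (phecodes, CPT groups, persistent medications, abnormal
    labs and vitals), agglomerative clustering with the Ward criterion on
    Manhattan distances, subtype profiling with false-discovery-rate
    control, competing-risk survival analysis (Kaplan-Meier, Cox,
    cumulative incidence, Fine-Gray), and subsampling-based cluster
    stability validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    cmprsk,
    mclust,
    jsonlite,
    Matrix,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
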