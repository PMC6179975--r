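Package: ricotype
Title: Cooking-Quality Ideotype Analysis for Rice Phenotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying rice accessions into cooking-quality
    ideotypes from instrument phenotypes. Extracts landmark features from
    oscillatory-rheometry traces (gel point, storage-modulus maximum and
    trough, slope features), Rapid Visco Analyser pasting curves (peak,
    trough and final viscosity with breakdown, setback and lift-off), and
    two-compression texture-profile curves (hardness, adhesiveness,
    cohesiveness, springiness); assembles replicate-averaged feature
    panels with amylose and gelatinisation-temperature class assignment;
    prunes correlation-redundant variables; groups accessions by Ward
    hierarchical clustering; fits multinomial logistic regression with
    forward-AIC variable selection, likelihood-ratio tests and pseudo-R2
    goodness of fit; ranks variables by per-cluster random-forest
    permutation importance; and summarises descriptive sensory profiles.
    Includes synthetic generators for every input so the full pipeline
    runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Matrix,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    mclust,
    mvtnorm,
    readxl,
    yaml
Config/testthat/edition: 3
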