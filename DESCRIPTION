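Package: cvtkit
Title: Concentration-Time Database Curation and Toxicokinetic Model Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, normalizing and analysing databases of in vivo
    concentration-versus-time (CvT) pharmacokinetic series. Provides an in-memory
    data model with a CSV-per-table interchange format and structural validation;
    unit and age-category normalization; closed-form one- and two-compartment
    concentration models for intravenous and oral dosing; joint maximum-likelihood
    fitting across studies with per-study error standard deviations, limit-of-
    quantification censoring and AIC model selection; technical-validation
    statistics (trapezoidal AUC, fractional AUC variability of replicate series,
    Kolmogorov-Smirnov replicate concordance, confusion-matrix metrics); a
    literature-triage toolkit (MeSH term enrichment rules and a TF-IDF consensus
    classifier ensemble); and seeded synthetic-data generators for end-to-end
    testing against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    e1071,
    glmnet,
    class,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
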