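Package: collinearEwas
Title: Multicollinearity Diagnostics for Cell-Type-Adjusted Methylation
    Association Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study how adjusting methylation-phenotype regressions
    for estimated white-blood-cell proportions can induce multicollinearity
    and apparent reversal of the direction of association. Provides a seeded
    synthetic-cohort generator with a configurable joint correlation
    structure over outcome, CpG methylation and six Houseman-style cell
    proportions; ordinary-least-squares model families with and without
    cell-type adjustment; variance inflation factors, tolerances, percent
    variance explained, condition indices and array-scale Spearman
    correlation screens; remediation strategies (dropping the highest-VIF
    cell type, principal-component substitution, residualization) together
    with their algebraic identities; and a Monte-Carlo sign-reversal
    experiment with a closed-form normal-approximation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    MASS,
    car
biocViews: DNAMethylation, Regression, StatisticalMethod, Epigenetics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
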