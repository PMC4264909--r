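Package: cytodet
Title: Expression Outlier Subgroup Discovery and Cytokine Network Analysis
    for Case-Control Cohorts
Version: 0.3.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Per-individual standardized-deviation ("z-score") outlier
    calling on log2 expression matrices with dual significance and
    fold-change thresholds, recurrence aggregation of outlier calls into
    patient subgroups, probe detection filtering and covariate-protected
    batch adjustment, cohort differential expression with
    Benjamini-Hochberg correction, cytokine co-secretion correlation
    networks compared between cohorts via the Fisher transform, delta-delta-Ct
    relative quantification, and single-SNP additive eQTL regression.
    Includes a synthetic-cohort generator that emulates the statistical
    structure the analysis assumes (planted outlier subgroups, batch
    structure, cohort-specific cytokine correlation, a Hardy-Weinberg
    eQTL), so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
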