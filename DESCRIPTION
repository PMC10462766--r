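Package: iciscreen
Title: Biomarker Screening for Immune Checkpoint Inhibitor Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes heterogeneous immune-checkpoint-inhibitor (ICI)
    gene-expression cohorts into a single quantile-normalized database,
    dichotomizes patients into responders and non-responders from RECIST
    categories or the 12-month progression-free-survival rule, stratifies
    samples into drug-class by biopsy-timing cohorts, and screens every gene
    for association with therapy response using the Mann-Whitney U test and
    ROC AUC with genome-wide Bonferroni control. Includes a synthetic
    multi-cohort generator with planted response markers of known AUC for
    end-to-end validation, panel evaluation utilities, and ROC/boxplot
    rendering for candidate genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
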