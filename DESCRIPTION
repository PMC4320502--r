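Package: leukomet
Title: Leukocyte Metagene Analysis of Bulk Tissue Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives top-k marker-gene panels per immune cell type from
    purified leukocyte expression profiles using nearest shrunken centroids
    (PAM-style), scores bulk tissue samples with a z-score metagene statistic
    (the mean of standardized expression over a cell type's marker panel),
    and tests for differential leukocyte infiltration between disease and
    control groups with two-sided t-tests. Includes a synthetic-data
    generator that emulates purified leukocyte references and bulk-tissue
    cohorts as convex mixtures of cell-type signatures with group-dependent
    cell-fraction shifts, so the whole pipeline is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
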