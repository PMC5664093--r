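Package: pcafe
Title: PCA-Based Unsupervised Feature Extraction for Case/Control Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Selects discriminating probes from a two-group expression matrix by
    embedding probes (not samples) into principal-component space, attributing
    chi-squared p-values to standardized PC scores, and Benjamini-Hochberg
    adjusting them. Selected probes are validated by one-dimensional linear
    discriminant analysis with leave-one-out cross-validation, and the mapped
    genes can be screened for survival association (median-split log-rank or
    Cox) and for gene-set over-representation (Fisher or EASE) against GMT
    collections. Includes seeded synthetic-data generators for expression
    matrices and survival cohorts with known ground truth, and an end-to-end
    pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    survival,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
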