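Package: metacouple
Title: Integrated Gene-Metabolite Correlation Screening for Cell-Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of paired metabolome and transcriptome
    profiles across a panel of cell lines. Screens all gene-metabolite pairs
    with a dual classical/robust correlation strategy (Pearson correlation
    plus the pairwise quadrant correlation), detects bivariate outlier
    samples per pair with minimum-covariance-determinant robust distances,
    recomputes correlations after outlier removal, and applies rule-based
    classification to separate steady-state gene-metabolite associations
    from single-cell-line outlier pairs that can be cross-referenced with
    mutation and copy-number tables. Also provides random-forest
    out-of-bag class-removal analysis with a random-removal null, a
    pathway-grouped annotation overlay, and a synthetic panel generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
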