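Package: archie
Title: Aggregative Trans-Association Components from Trans-eQTL Summary
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects trait-specific sets of distal (trans) target genes by
    aggregating weak trans-eQTL associations between trait-associated
    variants and distant genes.  Sparse canonical correlation analysis is
    applied to a correlation-adjusted matrix of trans-eQTL Z statistics,
    with linkage-disequilibrium and penalized co-expression matrices
    estimated from reference panels.  Includes resampling-based competitive
    and global null significance tests for the extracted components, a
    linear structural-equation simulator of cis/trans regulatory networks
    with analytically calibrated heritability for type-I error and power
    studies, and a trans-imputed expression score (TIES) regression with
    resampling tests for enrichment of trait heritability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
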