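Package: bulkscan
Title: Bulk Segregant Mapping of Parent-of-Origin Effects from Pooled
    Allele Counts
Version: 0.1.0
Authors@R:
    person("Maintainer", "bulkscan", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping parent-of-origin effects by bulk segregant
    sequencing of pooled surviving offspring. Implements a cross and seed
    viability model for imprinted maternal-effect lethality with
    multiplicative paternal rescue loci (exact expectations by gamete-class
    enumeration and forward simulation under a Haldane map), a pooled
    read-count simulator with coverage noise, replicate structure and
    segregation distortion, the SNP quality-filtering cascade used for
    pooled allele-count data, rolling-window allele-proportion profiles,
    a between-pool enrichment statistic with rolling-median smoothing and
    peak calling, and exact binomial seed-count statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
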