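Package: svcnv
Title: Tumor/Normal Structural Variant, Copy-Number and Cell-Free DNA Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end tumor/normal genome aberration analysis on mapped
    read pairs: depth-of-coverage copy-number ratio calling with
    Geary-Hinkley p-values, Parzen-Rosenblatt smoothing and per-chromosome
    Benjamini-Hochberg significance limits; structural-variant detection
    from discordant read-pair signatures with single-linkage clustering and
    strand/order filtering; a two-stage panel-of-normals window filter for
    germline subtraction; Poisson quantification of droplet and plate
    digital PCR including deletion genotyping, amplification calling and
    cfDNA breakpoint-fraction monitoring; and 5-Mbp-bin Z-score concordance
    between tumor and plasma cell-free DNA copy-number profiles. Includes a
    seeded synthetic-data generator for mate-pair and paired-end libraries
    with implanted germline and somatic aberrations, cfDNA mixtures and
    digital-PCR partition counts, plus cohort tabulation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
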