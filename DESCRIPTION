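Package: hairshed
Title: Single-Step GBLUP Genetic Evaluation of Hair Shedding Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for routine genetic evaluation of early-summer hair
    shedding score in beef cattle. Implements phenotype preparation and
    contemporary-group construction, pedigree and genomic relationship
    matrices with single-step blending (H-inverse), repeated-records and
    maternal-effect animal models estimated by average-information REML,
    LR-method validation of breeding values (bias, dispersion, accuracy),
    and genome-wide association on deregressed breeding values with
    false-discovery-rate control. Includes a synthetic-data generator that
    emulates the pedigree, genotype, and phenotype structure these models
    assume, so the whole pipeline can be exercised end-to-end against known
    simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
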