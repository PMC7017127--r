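Package: somaticmap
Title: Somatic Variant Labelling and Read-Depth Copy-Number Mapping for
    Paired Tumor-Normal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering somatic variation in a tumor genome
    against a matched normal: GC-corrected read-depth copy-number mapping
    (mappable-base binning, LOWESS bias correction, circular binary
    segmentation, Gaussian-mixture copy-state genotyping), paired
    genotype-likelihood somatic labelling with site filters, and
    cancer-gene prioritization through homolog mapping and a cancer gene
    census. Includes a seeded synthetic paired-genome generator with
    truth tables so the whole pipeline can be exercised and evaluated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
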