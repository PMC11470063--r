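Package: fcgscout
Title: Multi-Omic Detection of a PAR-Adjacent X-to-Y Translocation in Four
    Core Genotypes Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference toolkit reproducing, at desk scale, the
    evidence chain by which a duplicated pseudoautosomal-region-adjacent
    segment of the mouse X chromosome fused to the Y chromosome can be
    discovered in Four Core Genotypes (FCG) mice: negative-binomial
    pseudo-bulk dosage testing of X-linked genes in single-cell UMI counts,
    windowed whole-genome coverage normalised to the autosomal median with
    duplication segmentation, haplotype-resolved coverage in an F1
    B6 x CAST cross for parental-origin inference, split-read clustering of
    the X-Y fusion junction with repeat annotation, sci-RNA-seq3 four-barcode
    sample demultiplexing, and DNA FISH spot quantification. All inputs are
    generated by a seeded synthetic-data module with known ground truth; a
    toy exact-seed read mapper closes the loop without external aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    MASS,
    DESeq2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
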