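Package: eqtlsat
Title: Saturation Analysis of Cis-eQTL Detection Across Tissues and Sample Sizes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the number, tissue specificity, and genomic
    properties of cis expression quantitative trait loci (cis eQTLs) change
    with cohort size. Implements multi-tissue cis-eQTL calling (Kruskal-Wallis
    association scan, lead-SNP selection in a +/-1 Mb window around the
    transcription start site, permutation-based false discovery rate control),
    nested subsampling designs with sizes equally spaced on the log scale,
    classification of detected eQTLs into seven tissue-overlap classes with
    creation/deletion/move-in/move-out transition rates, and a scaling-law fit
    of sqrt(count) on log(sample size) used to extrapolate eQTL yields to
    larger cohorts. A synthetic three-tissue cohort generator with a known cis
    architecture makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
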