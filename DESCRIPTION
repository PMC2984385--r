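Package: ldlmap
Title: QTL Fine-Mapping in Half-Sib Designs by Haplotype Association and
    Linkage Disequilibrium Likelihood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fine-mapping of a bi-allelic quantitative trait locus (QTL) in
    animal half-sib family designs. Implements two complementary scans over a
    dense SNP map: a haplotype-dose association analysis with sire effects
    (maximised over flanking-marker haplotypes and marker intervals), and a
    maximum-likelihood method combining linkage information with a
    probabilistic model of linkage disequilibrium decay under Wright-Fisher
    drift, built on the Bennett multilocus disequilibrium decomposition.
    Includes a forward gene-dropping simulator of marker-QTL populations and
    half-sib designs, permutation significance thresholds, and a replicate
    harness reporting root mean squared error of the estimated QTL position
    and empirical power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
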