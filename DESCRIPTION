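Package: boarmix
Title: Domestic Pig Admixture Detection and In Silico rob(15;17)
    Karyotyping in Wild Boar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference toolkit for genome-wide detection of
    domestic pig introgression in European wild boar. Provides a
    Balding-Nichols simulator of diverged reference panels and admixed
    pedigrees carrying the rob(15;17) Robertsonian fusion, PLINK/VCF text
    genotype input and output with SNP and sample filtering, PCA with
    model-based clustering to flag recent hybrids, supervised global
    ancestry estimation by EM with bootstrap confidence intervals, a
    diploid three-way local-ancestry hidden Markov model, prediction of
    the 2n = 36/37/38 karyotype from local ancestry flanking the fused
    chromosome 15/17 centromere, and a genome scan for regions of
    unusually low wild boar ancestry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
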