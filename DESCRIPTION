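Package: tpmtstar
Title: TPMT Star-Allele Imputation, Phenotyping and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies TPMT high-risk metabolizer phenotypes from array
    genotype data. Provides a synthetic cohort simulator (population-specific
    star-allele haplotype frequencies, two array designs, Balding-Nichols
    ancestry markers, X markers), PCA plus nearest-neighbor ancestry
    inference and X-heterozygosity sex inference, a haplotype-copying hidden
    Markov model for reference-panel imputation of the two defective-allele
    SNPs rs1800460 and rs1142345 with info-score quality filtering,
    translation of genotypes into *1/*3A/*3B/*3C star-allele diplotypes and
    activity phenotypes, population frequency reporting, and validation of
    imputed against observed genotypes via confusion matrices, concordance
    and one-vs-rest sensitivity/specificity/PPV/NPV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
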