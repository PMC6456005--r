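Package: zwscan
Title: Sex-Chromosome Discovery and Dosage-Compensation Analysis from
    Coverage, Pooled SNPs, Expression and qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies Z-linked scaffolds in female-heterogametic (ZW)
    genomes from the ratio of female to male genomic read depth using
    median-anchored coverage zones, detects young, coverage-undifferentiated
    ZW strata from ZW-consistent SNP patterns in pooled RNA samples with
    DNA cross-validation and a reverse-polarity (pseudo-XY) false-positive
    control, and assesses dosage compensation of Z-specific genes from
    RPKM-quantified, quantile-normalized RNA-seq expression. Includes a
    qPCR delta-delta-Cq module for copy-number verification of Z-linkage,
    a synthetic-data generator with known ground truth for end-to-end
    validation, and a one-call pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
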