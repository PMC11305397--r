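Package: astaseq
Title: Allele-Specific Targeted Amplicon Oxidative Bisulfite Sequencing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies 5-methylcytosine and 5-hydroxymethylcytosine per CpG
    and per allele from targeted-amplicon bisulfite (BS) and oxidative
    bisulfite (OxBS) sequencing reads: gene demultiplexing by PCR primer,
    allele assignment from a bisulfite-space SNP anchor, CG/TG calling per
    CpG, BS-minus-OxBS deconvolution and the negative-5hmC clamp/discard
    rules. Also provides allele-specific expression ratios with
    informative-gene selection and reactivating/escapee classification, a
    pluripotency score, qPCR delta-CT transforms, BS/OxBS methylation-array
    beta-value processing (probe QC, deconvolution, delta-beta, DMP
    filtering), CRISPR-screen hit-selection filters, and a synthetic-data
    generator so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
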