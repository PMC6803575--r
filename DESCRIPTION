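Package: mlpa21
Title: MLPA Dosage-Quotient Analysis of Chromosome 21 Copy Number in
    Childhood BCP-ALL
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based copy-number analysis of chromosome 21 from
    Multiplex Ligation-dependent Probe Amplification (MLPA) peak tables.
    Implements two-stage Dosage Quotient (DQ) normalization against
    healthy reference samples, probe-level CNV classification by DQ
    windows, detection of contiguous amplified blocks along an ordered
    46-probe chromosome-21 panel, sample-level diagnostic calling of
    iAMP21 (intrachromosomal amplification of chromosome 21) with
    hyperdiploidy discrimination, cohort-level concordance statistics
    against FISH/karyotype truth, and a synthetic-cohort generator with
    blast-fraction dilution for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
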