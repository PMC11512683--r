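Package: ampliclone
Title: Single-Cell Targeted Amplicon Genotyping and Clonal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Error-aware somatic genotype calling from targeted single-cell
    amplicon read counts, with locus-specific scVAF thresholds derived from
    wild-type control cells co-processed on every plate. Detects and
    quantifies allelic dropout using linked germline heterozygous SNPs with
    phase inference, or from homozygous-mutant frequencies; infers clonal
    hierarchies from multi-mutation co-occurrence by exhaustive
    maximum-likelihood tree search; normalizes mutant-clone abundance across
    hematopoietic cell states relative to a reference population; applies
    rule-based driver annotation and clonal-hematopoiesis classification to
    bulk variant tables; and ships a fully parameterized simulator of
    per-cell allelic counts (PCR allelic skew, allelic dropout, sequencing
    error, coverage dispersion, empty wells) so every stage is testable with
    known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
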