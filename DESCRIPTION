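Package: anoresist
Title: Transcriptomic and Target-Site Analysis of Escalating Pyrethroid
    Resistance in Anopheles coluzzii
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for studying rapidly escalating pyrethroid
    resistance in field populations of Anopheles coluzzii. Implements
    two-colour interwoven-loop microarray differential expression
    (within-array normalization, per-probe fixed-effects linear model with
    dye term, Benjamini-Hochberg FDR), a hypothesis-driven candidate-gene
    filtering cascade with probe-to-gene collapse and hierarchical
    clustering, kdr (L1014F, N1575Y) allele-frequency estimation with exact
    confidence intervals, Fisher exact allele-survival association,
    two-locus EM haplotype phasing with haplotype-survival odds ratios, and
    efficiency-corrected ddCt qPCR relative quantification against multiple
    reference genes. A synthetic-data generator with planted ground truth
    makes every stage testable without external array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    ape
Config/testthat/edition: 3
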