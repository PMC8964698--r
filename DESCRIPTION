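Package: bequant
Title: Quantification of Base-Editing Outcomes from Amplicon Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for CRISPR base-editor outcomes measured by
    paired-end amplicon deep sequencing. Merges overlapping read pairs into
    quality-aware consensus reads, aligns them to the amplicon reference with
    affine-gap scoring, and produces quality-filtered per-protospacer-position
    base-conversion counts, editing-frequency profiles, and indel frequencies.
    On top of the per-position profiles it computes position-indexed inhibition
    rates between control and inhibitor-treated conditions, the on-target
    versus out-of-window contrast with selectivity folds and Student's t tests,
    and allele-level classification of perfectly edited outcomes. A synthetic
    base-editing read simulator with known truth supports end-to-end testing
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
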