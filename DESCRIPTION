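Package: clonovar
Title: Variant Attribution and Quality Control for Genome-Edited Clonal
    Cell Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Attributes the genetic variation observed in collections of
    genome-edited clonal cell lines (e.g. CRISPR/Cas9-, TALEN- or
    prime-edited human pluripotent stem cell clones) to its sources:
    intended on-target edits, culture-acquired founder mutations fixed at
    clonal bottlenecks, clone-private mutations, and genuine editing
    off-targets.  Provides quality filtering and cross-line exclusion of
    parental standing variation from joint-genotyped multi-sample VCFs,
    protospacer-adjacent-motif (PAM) anchored off-target site enumeration
    with mismatch tolerance, cleavage-window classification of near-site
    variants, coding-impact annotation against a transcript model,
    per-passage mutation-rate regression, loss-of-heterozygosity screening
    at edited loci from flanking heterozygous markers, quality-control
    summary rates, presence/absence phylogenetics, and a fully labelled
    synthetic-cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
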