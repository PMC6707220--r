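Package: mmchron
Title: Chronological Reconstruction of Driver Events in Multiple Myeloma Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the life history of multiple myeloma tumors
    from whole-genome sequencing derived inputs: molecular timing of clonal
    copy-number gains from the multiplicity of clonal point mutations
    (trisomy, copy-neutral LOH, and multi-gain states), bootstrap confidence
    intervals and hierarchical grouping of gains into time windows,
    Dirichlet-process binomial mixture clustering of mutations into subclones
    across serial samples, enumeration of subclone phylogenies compatible
    with the pigeonhole principle, timing of structural variants relative to
    gains via adjusted rearrangement VAFs, copy-number outcomes and phased
    SNVs, cohort-level Bradley-Terry ordering of recurrent lesions, and
    logic-gate plus exact Bayesian-network dependency analysis of binary
    driver matrices. Includes a forward simulator of tumor histories with
    known ground truth (gain times, subclone trees, SV placement, driver
    logic gates) emitting the pipeline's input formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
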