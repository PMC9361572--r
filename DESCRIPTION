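Package: ksdater
Title: Ka/Ks Estimation and Polyploidy-Event Dating for Duplicate Gene
    Families
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the evolutionary analysis of duplicate gene families
    in plant genomes: pairwise Ka/Ks estimation on in-frame codon alignments
    by the Nei-Gojobori (1986) counting method with Jukes-Cantor correction,
    divergence-time estimation from Ks under lineage-specific neutral
    substitution rates, assignment of paralogous pairs to polyploidization
    events by binning Ks against event anchors, MCScanX-style classification
    of family members into five duplication types (WGD/segmental, tandem,
    proximal, dispersed, singleton), and gene-tree/species-tree
    duplication-loss reconciliation by LCA mapping.  Includes simulators for
    codon-pair divergence, genomes with planted duplication structure, and
    gene trees with known duplication/loss histories, so every stage of the
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
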