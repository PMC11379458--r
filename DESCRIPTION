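Package: paleoERV
Title: Mining, Structural Annotation, Molecular Dating and Orthology of
    Endogenous Retrovirus Proviruses
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing clades of endogenous retroviruses
    (ERVs) in genome assemblies: reconstruction of candidate proviral loci
    from RepeatMasker annotation tracks (merging, filtering, solo-LTR and
    fragment classification, locus naming), structural annotation against
    reference elements (LTR and target-site-duplication detection, open
    reading frame intactness under a 90 percent completeness rule, shared
    internal deletion matching, recombinant-region detection and two-parent
    breakpoint scanning), molecular dating from 5'-3' LTR divergence with
    a configurable substitution clock, neighbor-joining LTR trees with
    discordant-pair flagging, cross-species presence/absence calling from
    flanking-junction intactness with oldest-common-ancestor assignment,
    insertional-polymorphism statistics from three-primer PCR genotype
    tables, spliced-junction detection from SAM alignments with spliced ORF
    translation, and quantification of two-channel reporter and infection
    assays from flow-cytometry event tables. Includes a synthetic-genome
    simulator that implants proviruses with known ground truth (ages,
    deletions, recombination, solo LTRs, decoy families, per-species
    presence) to validate every step end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
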