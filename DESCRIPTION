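Package: famscan
Title: Genome-Wide Gene-Family Mining, Orthology, Phylogeny and Expression Atlas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide annotation of a transcription-factor
    gene family, modelled on the MADS-box family workflow in plants. It discovers
    candidate family loci by six-frame translated similarity search with
    Karlin-Altschul statistics, triages them into functional genes and pseudogenes
    (internal stops, truncations, assembly gaps) with a position-specific scoring
    matrix of the family domain, curates gene models against RNA-seq coverage,
    calls one-to-one orthologs across species by reciprocal best hit, builds
    bootstrap consensus trees for subfamily and clade classification, assigns
    deterministic gene symbols following community nomenclature rules, and
    constructs a multi-platform expression atlas with Plant Ontology attribution
    and two-tier co-expression clustering. A synthetic-data module generates
    genomes, proteomes, clade-structured protein sets and expression matrices with
    known ground truth so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
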