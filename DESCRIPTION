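Package: mitomosaic
Title: Assembly and Transcript Analysis of Multichromosomal Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying plant mitochondrial genomes that exist as
    several independent circular chromosomes, modelled on the two-chromosome
    sugarcane mitogenome. Provides an iterative k-mer bait-and-assemble
    reconstruction loop, a master-circle exclusion test based on spanning-read
    support over all join paths through inter-chromosomal shared regions,
    splice-junction extraction and hotspot clustering from spliced alignments
    over concatenated chromosomes, polyadenylation-tagged degradation-island
    detection from transcript coverage, length-normalised expression
    fold-change, pairwise genome diffing with RNA-editing classification, and
    GC-signature compartment classification. A synthetic-data module generates
    toy two-chromosome mitogenomes with shared regions, long repeats,
    trans-spliced genes, plastid-derived segments and ground-truth transcript
    alignments for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
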