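Package: mitofrag
Title: Comparative Analysis of Fragmented Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing annotated animal mitochondrial genomes with
    highly rearranged and multipartite (multi-chromosome) architectures, built
    around the contrast between unipartite and bipartite mini-circle genomes in
    thrips cryptic species. Provides GenBank/FASTA input and output for
    annotated circular chromosomes, signed gene-order extraction with
    adjacency/breakpoint algebra and event classification (tRNA inversions,
    translocations, chromosome fission with feature duplication), pairwise
    homolog divergence with indel-collapse and tRNA-terminus trimming rules,
    in-silico PCR on circular templates for architecture hypothesis testing,
    an audit of NGS contig errors by contig-terminal and A/T-homopolymer
    context, and a fully seeded synthetic mitogenome generator with planted,
    recorded truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
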