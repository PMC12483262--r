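Package: mitocomp
Title: Comparative Analysis of Circular Mitochondrial Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level characterization of annotated animal mitogenomes
    (nucleotide composition, AT/GC skews, relative synonymous codon usage
    under the invertebrate mitochondrial code, start/stop codon
    classification), intraspecific divergence metrics (Kimura two-parameter
    distance, SNP density, percent identity), and distance-based phylogeny
    from concatenated protein-coding genes (neighbor joining with
    bootstrap), together with a K80 mitogenome-evolution simulator that
    provides ground-truthed fixtures for every stage. Reads GenBank flat
    files, FASTA and tab-separated feature tables; writes Newick trees and
    supermatrix exports for external likelihood tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
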