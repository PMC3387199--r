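Package: degeprimr
Title: Degenerate PCR Primer Design for Cross-Species Amplification of
    Single-Copy Nuclear Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs degenerate oligonucleotide PCR primer pairs for
    amplifying single-copy nuclear protein-coding genes across divergent
    taxa. Starting from codon alignments of 1:1 orthologous genes (or
    protein alignments back-translated onto coding sequences) and
    annotated reference genome assemblies, the package scans for
    conserved windows, builds minimal IUPAC consensus primers, applies
    degeneracy, GC-content, mononucleotide-run, melting-temperature and
    primer-dimer filters, validates candidate pairs against each genome
    (discarding primers that straddle exon/intron boundaries or amplify
    oversize products), accounts exonic and intronic nucleotides of each
    predicted amplicon, screens for secondary amplification products,
    selects overlap-limited marker sets per gene, and attaches universal
    sequencing tails. A seeded synthetic-data generator produces ortholog
    groups and annotated mini-genomes with planted conserved primer sites
    so that the entire pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
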