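Package: stopscan
Title: Genome-Wide Design and Evaluation of Stop-Codon-Introducing Cytosine
    Base Editing Guides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scans bacterial genomes for protospacers whose C-to-T editing by
    a cytosine base editor introduces a premature stop codon, under
    configurable PAM specifications (NGG, NGN, or any IUPAC 3-mer) and
    editing-window definitions. Annotates candidates with the sequence
    features that drive editing efficiency in GC-rich genomes (GC content,
    GC-motif presence in the editing window, bystander-C burden, PAM class)
    and aggregates genome-wide targeting-scope statistics. Also quantifies
    per-position base-substitution frequencies and cognate-to-bystander
    ratios from barcoded amplicon reads, and audits off-target single
    nucleotide variants by control subtraction, depth filtering,
    deamination-signature classification and genomic binning. Includes a
    seeded synthetic-data generator (genomes with planted editable codons,
    amplicon read pools with planted editing frequencies, treated/control
    variant tables) so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
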