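# Fixture builders. Everything is generated in code at test time; nothing
# binary is stored in the repository.

# genome with completely random gene content (any codons, internal ATG +
# terminal TAA only guaranteed), for oracle-equivalence testing where the
# truth comes from the brute force rather than a manifest
random_genome <- function(seed, length = 3000L, n_genes = 3L,
                          gene_length = 300L, gc = 0.72) {
  set.seed(seed)
  bases <- c("G", "C", "A", "T")
  prob <- c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)
  bg <- sample(bases, length, replace = TRUE, prob = prob)
  gap <- (length - n_genes * gene_length) %/% (n_genes + 1L)
  cds_rows <- list()
  for (g in seq_len(n_genes)) {
    gstart <- gap * g + gene_length * (g - 1L)
    n_codon <- gene_length %/% 3L
    body <- paste(sample(bases, gene_length - 6L, replace = TRUE,
                         prob = prob), collapse = "")
    gene <- paste0("ATG", body, "TAA")
    strand <- if (g %% 2L == 0L) "-" else "+"
    gg <- if (strand == "+") gene else stopscan::revcomp(gene)
    bg[(gstart + 1L):(gstart + gene_length)] <- strsplit(gg, "")[[1]]
    cds_rows[[g]] <- stopscan::cds_table(sprintf("RND_%03d", g), "rchr",
                                         gstart, gstart + gene_length,
                                         strand)
  }
  list(genome = stopscan::genome_record("rchr", paste(bg, collapse = "")),
       cds = do.call(rbind, cds_rows))
}

# minimal GenBank flatfile text for one contig
genbank_text <- function(contig = "TESTCTG1", seq, features = character()) {
  seq <- tolower(seq)
  starts <- seq(1L, nchar(seq), by = 60L)
  ori <- vapply(starts, function(s) {
    chunk <- substring(seq, s, min(s + 59L, nchar(seq)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    sprintf("%9d %s", s, paste(blocks, collapse = " "))
  }, character(1))
  c(sprintf("LOCUS       %s %d bp    DNA     linear   BCT 01-JAN-2020",
            contig, nchar(seq)),
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)),
    features,
    "ORIGIN",
    ori,
    "//")
}

gb_cds <- function(location, quals = c('/locus_tag="TST_0001"')) {
  c(sprintf("     CDS             %s", location),
    sprintf("                     %s", quals))
}

write_gff3 <- function(path, rows,
                       header = "##gff-version 3") {
  writeLines(c(header, rows), path)
}

# amplicon design with a protospacer carrying several window Cs
demo_design <- function(strand = "+") {
  # reference: 30 nt left arm + 20 nt protospacer + 30 nt right arm
  left <- "ATTAGGATTCAGGATTTACCGATTGAGATT"
  spacer_plus <- "ATGACGTCCTCAGATACGTA"   # Cs at 5, 8, 9, 11, 17 (plus)
  right <- "GGATTAGACCATTAGGATCAGGATTTAGGA"
  ref <- paste0(left, if (strand == "+") spacer_plus else
    stopscan::revcomp(spacer_plus), right)
  stopscan::amplicon_design("amp1", ref, "ACGTACGT", 31L, strand)
}
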