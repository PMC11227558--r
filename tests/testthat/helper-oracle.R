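# Independent brute-force oracle for the scanner. Shares no code with the
# package internals: editable Cs are derived by mutating each C (on either
# strand) and re-translating the affected codon with the standard genetic
# code; PAM matching goes through Biostrings::matchPattern(fixed = FALSE);
# placements are enumerated over every 23-mer on both strands.

# every (gene, reference position, reference strand) whose C->T edit turns a
# non-stop codon 2..(n-1) into a stop codon
oracle_editable_cs <- function(genome, cds) {
  GEN <- Biostrings::GENETIC_CODE
  rows <- list()
  for (i in seq_len(nrow(cds))) {
    row <- cds[i, , drop = FALSE]
    if (row$partial) next
    dna <- Biostrings::DNAString(substring(genome$seq, row$start + 1L,
                                           row$end))
    if (row$strand == "-") dna <- Biostrings::reverseComplement(dna)
    cs <- as.character(dna)
    n <- nchar(cs)
    nc <- n %/% 3L
    for (j in 0:(n - 1L)) {
      b <- substring(cs, j + 1L, j + 1L)
      if (!(b %in% c("C", "G"))) next
      k <- j %/% 3L + 1L
      if (k < 2L || k > nc - 1L) next
      cod <- substring(cs, 3L * (k - 1L) + 1L, 3L * k)
      if (grepl("N", cod)) next
      off <- j - 3L * (k - 1L) + 1L
      mut <- cod
      substr(mut, off, off) <- if (b == "C") "T" else "A"
      if (GEN[[cod]] != "*" && GEN[[mut]] == "*") {
        ref_pos <- if (row$strand == "+") row$start + j else row$end - 1L - j
        cstrand <- if (b == "C") row$strand else
          setdiff(c("+", "-"), row$strand)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = row$gene_id, ref_pos = ref_pos, strand = cstrand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), ref_pos = integer(),
               strand = character(), stringsAsFactors = FALSE)
}

# enumerate every PAM-adjacent 23-mer on both strands whose window covers an
# editable C; returns deduplicated placements per gene
oracle_scan <- function(genome, cds, pam_pattern, first, last) {
  E <- oracle_editable_cs(genome, cds)
  seq <- genome$seq
  L <- nchar(seq)
  hits <- list()
  for (str in c("+", "-")) {
    s <- if (str == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    pam1 <- Biostrings::start(Biostrings::matchPattern(
      pam_pattern, Biostrings::DNAString(s), fixed = FALSE))
    cand <- pam1 - 21L                      # 0-based 23-mer start
    cand <- cand[cand >= 0L & cand + 23L <= L]
    for (s23 in cand) {
      mer <- substring(s, s23 + 1L, s23 + 23L)
      if (grepl("N", mer, fixed = TRUE)) next
      for (p in first:last) {
        if (substring(mer, p, p) != "C") next
        ref_pos <- if (str == "+") s23 + p - 1L else L - 1L - (s23 + p - 1L)
        genes <- unique(E$gene_id[E$ref_pos == ref_pos & E$strand == str])
        for (gid in genes) {
          start <- if (str == "+") s23 else L - 20L - s23
          hits[[length(hits) + 1L]] <- data.frame(
            gene_id = gid, spacer = substring(mer, 1L, 20L),
            pam = substring(mer, 21L, 23L), strand = str,
            start = start, target_c_pos = p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene_id = character(), spacer = character(),
               pam = character(), strand = character(), start = integer(),
               target_c_pos = integer(), stringsAsFactors = FALSE)
  out[!duplicated(paste(out$gene_id, out$spacer, out$pam, out$strand,
                        out$start)), , drop = FALSE]
}

# placement-set key for comparing scanner output with the oracle or a
# truth manifest (attribution of coincident placements may differ in
# target_c_pos, so the physical placement is the comparison unit)
placement_set <- function(df) {
  sort(paste(df$gene_id, df$spacer, df$pam, df$strand, df$start))
}
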