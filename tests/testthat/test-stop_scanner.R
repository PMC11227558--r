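# Scanner: rule table, placement enumeration, deduplication, IUPAC
# filtering, and the structural properties of the emitted set.

.ps_key <- function(d) paste(d$spacer, d$pam, d$strand, d$start)

test_that("the stop-codon rule table is applied to codons 2..(n-1)", {
  cds <- cds_table("g", "c", 0, 9, "+")
  tg <- find_editable_targets("ATGCAGTAA", cds)
  expect_equal(nrow(tg), 1L)
  expect_equal(tg$codon_index, 2L)
  expect_equal(tg$codon_seq, "CAG")
  expect_equal(tg$target_strand, "coding")
  expect_equal(tg$resulting_stop, "TAG")
  expect_equal(tg$c_ref_pos, 3L)
  expect_equal(tg$c_strand, "+")

  tg <- find_editable_targets("ATGTGGTAA", cds)
  expect_equal(nrow(tg), 2L)
  expect_equal(tg$target_strand, c("template", "template"))
  expect_setequal(tg$resulting_stop, c("TGA", "TAG"))
  expect_equal(tg$c_strand, c("-", "-"))
  # TGA target is the template C pairing with codon base 3 (ref pos 5),
  # TAG with base 2 (ref pos 4)
  expect_equal(tg$c_ref_pos[tg$resulting_stop == "TGA"], 5L)
  expect_equal(tg$c_ref_pos[tg$resulting_stop == "TAG"], 4L)

  expect_equal(nrow(find_editable_targets("ATGGGTTAA", cds)), 0L)
  expect_error(find_editable_targets("ATGCAGTA", cds), "not divisible by 3")
})

test_that("start and native stop codons are never targets", {
  # CAG as codon 1 and TGG as terminal codon must be ignored
  cds <- cds_table("g", "c", 0, 12, "+")
  tg <- find_editable_targets("CAGCAGTGGTGG", cds)
  expect_equal(sort(tg$codon_index), c(2L, 3L, 3L))
})

test_that("minus-strand CDS targets map to mirrored reference coordinates", {
  # genome carries revcomp of ATGCAGTAA at [0,9): coding C is at CDS offset
  # 3, so reference position end-1-3 = 5, on the minus strand
  g <- genome_record("c", revcomp("ATGCAGTAA"))
  cds <- cds_table("g", "c", 0, 9, "-")
  tg <- find_editable_targets(extract_cds(g, cds), cds)
  expect_equal(tg$c_ref_pos, 5L)
  expect_equal(tg$c_strand, "-")
})

test_that("enumeration places the target C at each window offset and
           filters by PAM", {
  # 60-nt fixture: CDS with one CAG codon; a single AGG trinucleotide
  # planted so the target C sits at window position 5
  base <- rep("A", 60)
  cds_seq <- "ATGCAGGGTATTATTATTATTATTTAA"
  base[11:37] <- strsplit(cds_seq, "")[[1]]
  c_ref <- 13L                                  # 0-based target C
  base[(c_ref + 21 - 5 + 1):(c_ref + 21 - 5 + 3)] <- c("A", "G", "G")
  g <- genome_record("c", paste(base, collapse = ""))
  cds <- cds_table("g1", "c", 10, 37, "+")
  tg <- find_editable_targets(extract_cds(g, cds), cds)
  tg <- tg[tg$codon_seq == "CAG", , drop = FALSE]

  hits <- enumerate_protospacers(g, tg, pam_spec("NGG"), editing_window(4, 8))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$target_c_pos, 5L)
  expect_equal(substring(hits$spacer, 5, 5), "C")
  expect_equal(hits$pam, "AGG")
  expect_equal(hits$start, c_ref - 4L)

  # NGN relaxes the third base: NGG result must be a subset, and every
  # emitted PAM has G at position 2
  hitsN <- enumerate_protospacers(g, tg, pam_spec("NGN"),
                                  editing_window(4, 8))
  expect_true(all(.ps_key(hits) %in% .ps_key(hitsN)))
  expect_true(all(substring(hitsN$pam, 2, 2) == "G"))
  # brute-force check on this fixture (the CDS has no other editable codon)
  brute <- oracle_scan(g, cds, "NGN", 4, 8)
  expect_setequal(placement_set(hitsN), placement_set(brute))
})

test_that("a target C outside the window yields no protospacer", {
  # only PAM-adjacent placement puts the C at position 3 (window 4-8)
  base <- rep("A", 60)
  base[11:37] <- strsplit("ATGCAGGGTATTATTATTATTATTTAA", "")[[1]]
  c_ref <- 13L
  base[(c_ref + 21 - 3 + 1):(c_ref + 21 - 3 + 3)] <- c("T", "G", "G")
  g <- genome_record("c", paste(base, collapse = ""))
  cds <- cds_table("g1", "c", 10, 37, "+")
  tg <- find_editable_targets(extract_cds(g, cds), cds)
  tg <- tg[tg$codon_seq == "CAG", , drop = FALSE]
  hits <- enumerate_protospacers(g, tg, pam_spec("TGG"), editing_window(4, 8))
  expect_equal(nrow(hits), 0L)
})

test_that("placements running off a linear contig end are skipped, and a
           circular contig wraps around", {
  # C near the left edge: PAM-distal end of the 23-mer would be negative
  seq <- paste0("CAG", strrep("T", 37))
  g <- genome_record("c", seq)
  tg <- data.frame(gene_id = "g", contig_id = "c", codon_index = 2L,
                   codon_seq = "CAG", target_strand = "coding",
                   c_ref_pos = 0L, c_strand = "+", resulting_stop = "TAG",
                   stringsAsFactors = FALSE)
  expect_equal(nrow(enumerate_protospacers(g, tg, pam_spec("NNN"),
                                           editing_window(4, 8))), 0L)
  gc <- genome_record("c", seq, topology = "circular")
  wrapped <- enumerate_protospacers(gc, tg, pam_spec("NNN"),
                                    editing_window(4, 8))
  expect_equal(nrow(wrapped), 5L)
  expect_true(all(vapply(seq_len(5), function(i)
    substring(wrapped$spacer[i], wrapped$target_c_pos[i],
              wrapped$target_c_pos[i]) == "C", logical(1))))
})

test_that("candidates containing N anywhere in the 23-mer are dropped", {
  base <- rep("A", 60)
  base[11:37] <- strsplit("ATGCAGGGTATTATTATTATTATTTAA", "")[[1]]
  base[(13 + 21 - 5 + 1):(13 + 21 - 5 + 3)] <- c("A", "G", "G")
  base[12] <- "N"                              # inside every window spacer
  g <- suppressWarnings(genome_record("c", paste(base, collapse = "")))
  cds <- cds_table("g1", "c", 10, 37, "+")
  tg <- data.frame(gene_id = "g1", contig_id = "c", codon_index = 2L,
                   codon_seq = "CAG", target_strand = "coding",
                   c_ref_pos = 13L, c_strand = "+", resulting_stop = "TAG",
                   stringsAsFactors = FALSE)
  expect_equal(nrow(enumerate_protospacers(g, tg, pam_spec("NGG"),
                                           editing_window(4, 8))), 0L)
})

test_that("dedupe collapses identical placements and keeps distinct ones", {
  one <- data.frame(gene_id = "g", contig_id = "c", spacer = strrep("A", 20),
                    pam = "AGG", strand = "+", start = 5L, end = 25L,
                    target_c_pos = 5L, codon_index = 2L, codon_seq = "CAG",
                    target_strand = "coding", resulting_stop = "TAG",
                    stringsAsFactors = FALSE)
  two <- rbind(one, one)
  expect_equal(nrow(dedupe_protospacers(two)), 1L)
  moved <- one; moved$start <- 50L; moved$end <- 70L
  expect_equal(nrow(dedupe_protospacers(rbind(one, moved))), 2L)
  empty <- one[0, ]
  expect_equal(nrow(dedupe_protospacers(empty)), 0L)
})

test_that("IUPAC 23-mer pattern matching follows positionwise membership", {
  pat <- "NNDDTCDDDNNNNNNNNNNNCGN"
  expect_true(match_pattern("AAGATCAGAAAAAAAAAAAACGG", pat))
  # position 5 must be T
  expect_false(match_pattern("AAGAGCAGAAAAAAAAAAAACGG", pat))
  # D excludes C at positions 3-4 and 7-9
  expect_false(match_pattern("AACATCAGAAAAAAAAAAAACGG", pat))
  expect_true(match_pattern(strrep("T", 23), strrep("N", 23)))
  expect_error(match_pattern("AAA", pat), "length 23")
  expect_error(match_pattern(strrep("A", 23), "NGG"), "length 23")
})

test_that("scan of a genome without CDS features is empty", {
  g <- genome_record("c", strrep("ACGT", 100))
  cds <- cds_table(character(), character(), integer(), integer(),
                   character(), logical())
  expect_equal(nrow(scan_genome(g, cds)), 0L)
})

test_that("PAM monotonicity: NGG hits are a subset of NGN hits", {
  for (seed in 1:4) {
    rg <- random_genome(seed, length = 2500L)
    ngg <- scan_genome(rg$genome, rg$cds, pam_spec("NGG"))
    ngn <- scan_genome(rg$genome, rg$cds, pam_spec("NGN"))
    expect_true(all(placement_set(ngg) %in% placement_set(ngn)))
  }
})

test_that("widening the editing window never removes a protospacer", {
  rg <- random_genome(42, length = 3000L)
  narrow <- scan_genome(rg$genome, rg$cds, pam_spec("NGN"),
                        editing_window(5, 8))
  wide <- scan_genome(rg$genome, rg$cds, pam_spec("NGN"),
                      editing_window(4, 9))
  expect_true(all(placement_set(narrow) %in% placement_set(wide)))
  expect_gte(nrow(wide), nrow(narrow))
})

test_that("scanning the reverse-complemented genome with mirrored CDSs
           yields the coordinate-mirrored protospacer set", {
  rg <- random_genome(99, length = 2400L)
  L <- nchar(rg$genome$seq)
  fwd <- scan_genome(rg$genome, rg$cds, pam_spec("NGN"))
  rc_genome <- genome_record("rchr", revcomp(rg$genome$seq))
  rc_cds <- rg$cds
  rc_cds$start <- L - rg$cds$end
  rc_cds$end <- L - rg$cds$start
  rc_cds$strand <- ifelse(rg$cds$strand == "+", "-", "+")
  rev <- scan_genome(rc_genome, rc_cds, pam_spec("NGN"))
  # mirror the reverse scan back into forward coordinates
  mirrored <- rev
  mirrored$start <- L - rev$end
  mirrored$end <- L - rev$start
  mirrored$strand <- ifelse(rev$strand == "+", "-", "+")
  expect_setequal(placement_set(fwd), placement_set(mirrored))
})

test_that("every emitted protospacer satisfies its structural invariants", {
  w <- editing_window(4, 8)
  for (seed in 5:7) {
    rg <- random_genome(seed, length = 2000L)
    hits <- scan_genome(rg$genome, rg$cds, pam_spec("NGN"), w)
    if (nrow(hits) == 0L) next
    expect_true(all(nchar(hits$spacer) == 20L))
    expect_true(all(nchar(hits$pam) == 3L))
    expect_true(all(hits$target_c_pos >= w$first &
                      hits$target_c_pos <= w$last))
    expect_true(all(vapply(seq_len(nrow(hits)), function(i)
      substring(hits$spacer[i], hits$target_c_pos[i],
                hits$target_c_pos[i]) == "C", logical(1))))
    expect_true(all(iupac_match(hits$pam, "NGN")))
    expect_true(all((hits$pam_class == "NGG") ==
                      (substring(hits$pam, 2, 3) == "GG")))
    # spacer sequence consistent with the reference
    for (i in sample(nrow(hits), min(10, nrow(hits)))) {
      slice <- substring(rg$genome$seq, hits$start[i] + 1L, hits$end[i])
      expect_equal(hits$spacer[i],
                   if (hits$strand[i] == "+") slice else revcomp(slice))
    }
  }
})

test_that("scan output equals the mutate-and-translate brute force", {
  combos <- list(c("NGG", 4, 8), c("NGN", 4, 8), c("NGA", 5, 9))
  for (seed in 1:3) {
    rg <- random_genome(seed * 17, length = 2400L)
    for (cb in combos) {
      mine <- scan_genome(rg$genome, rg$cds, pam_spec(cb[1]),
                          editing_window(as.integer(cb[2]),
                                         as.integer(cb[3])))
      brute <- oracle_scan(rg$genome, rg$cds, cb[1], as.integer(cb[2]),
                           as.integer(cb[3]))
      expect_setequal(placement_set(mine), placement_set(brute))
    }
  }
})

test_that("the experimental-design pattern filter restricts scan output", {
  rg <- random_genome(31, length = 3000L)
  all_hits <- scan_genome(rg$genome, rg$cds, pam_spec("NGN"))
  pat <- "NNDDTCDDDNNNNNNNNNNNCGN"
  filt <- scan_genome(rg$genome, rg$cds, pam_spec("NGN"), pattern = pat)
  expect_true(all(placement_set(filt) %in% placement_set(all_hits)))
  if (nrow(filt))
    expect_true(all(match_pattern(paste0(filt$spacer, filt$pam), pat)))
  manual <- all_hits[match_pattern(paste0(all_hits$spacer, all_hits$pam),
                                   pat), ]
  expect_setequal(placement_set(filt), placement_set(manual))
})
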