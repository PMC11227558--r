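# Amplicon quantification: demultiplexing, anchored counting, frequencies,
# selectivity ratios.

test_that("design validation enforces barcode length and anchor flanks", {
  expect_error(amplicon_design("a", strrep("ACGT", 30), "ACGT", 31, "+"),
               "8-mer")
  # spacer too close to the reference edge for a 12-mer flank
  expect_error(amplicon_design("a", strrep("ACGT", 30), "ACGTACGT", 5, "+"),
               "no room")
  # non-unique left flank
  rep_ref <- paste0(strrep("ACGTACGTACGT", 2), strrep("ACGTACGTACGT", 4))
  expect_error(amplicon_design("a", rep_ref, "AAAAAAAA", 13, "+"),
               "not unique")
})

test_that("demultiplexing is exact 8-mer prefix matching", {
  d1 <- demo_design()
  d2 <- amplicon_design("amp2", d1$reference, "TTTTTTTT", 31, "+")
  reads <- data.frame(
    id = c("r1", "r2", "r3"),
    seq = c(paste0("ACGTACGT", d1$reference),
            paste0("ACGTACGA", d1$reference),    # 1 mismatch: unassigned
            paste0("TTTTTTTT", d1$reference)),
    mean_qual = 35, stringsAsFactors = FALSE)
  dmx <- demultiplex(reads, list(d1, d2))
  expect_equal(nrow(dmx$assigned$amp1), 1L)
  expect_equal(nrow(dmx$assigned$amp2), 1L)
  expect_equal(dmx$n_unassigned, 1L)
  # empty input
  empty <- demultiplex(reads[0, ], list(d1, d2))
  expect_equal(empty$n_unassigned, 0L)
  expect_equal(nrow(empty$assigned$amp1), 0L)
  # duplicate barcodes are fatal
  expect_error(demultiplex(reads, list(d1, d1)), "duplicate barcodes")
})

test_that("substitution frequency is substitution reads over anchored
           reads", {
  d <- demo_design()
  reads <- generate_reads(d, c(`8` = 0.30), n_reads = 100L, seed = 5,
                          mode = "exact")
  reads$mean_qual <- 35
  pbf <- quantify(reads, d)
  expect_equal(pbf$n_anchored, 100L)
  sf <- substitution_frequencies(pbf)
  expect_equal(sf$freq[sf$position == 8 & sf$base == "T"], 0.30)
  expect_equal(sf$freq[sf$position == 8 & sf$base == "C"], 0.70)
  # untouched reference positions stay at frequency 1 for the ref base
  expect_equal(sf$freq[sf$position == 1 & sf$base == "A"], 1)
})

test_that("zero anchored reads give undefined frequencies with a zero
           denominator", {
  d <- demo_design()
  pbf <- quantify(data.frame(id = character(), seq = character(),
                             mean_qual = numeric()), d)
  expect_equal(pbf$n_anchored, 0L)
  expect_true(all(is.na(substitution_frequencies(pbf)$freq)))
})

test_that("the denominator is conserved: assigned = anchored +
           anchor-failed + quality-failed", {
  d <- demo_design()
  good <- generate_reads(d, c(`8` = 0.5), n_reads = 40L, seed = 6,
                         mode = "exact")
  good$mean_qual <- 35
  lowq <- good[1:5, ]; lowq$mean_qual <- 10
  indel <- good[1:3, ]
  # delete one base inside the protospacer: right flank shifts, anchor fails
  indel$seq <- paste0(substring(indel$seq, 1, 45), substring(indel$seq, 47))
  all_reads <- rbind(good, lowq, indel)
  pbf <- quantify(all_reads, d, min_qual = 15)
  expect_equal(pbf$n_assigned, 48L)
  expect_equal(pbf$n_quality_failed, 5L)
  expect_equal(pbf$n_anchor_failed, 3L)
  expect_equal(pbf$n_anchored, 40L)
  expect_equal(pbf$n_assigned,
               pbf$n_anchored + pbf$n_anchor_failed + pbf$n_quality_failed)
})

test_that("quantification is invariant to read order", {
  d <- demo_design()
  reads <- generate_reads(d, c(`5` = 0.2, `8` = 0.6), n_reads = 200L,
                          seed = 7, mode = "exact")
  reads$mean_qual <- 35
  set.seed(1)
  shuffled <- reads[sample(nrow(reads)), ]
  expect_equal(quantify(reads, d)$counts, quantify(shuffled, d)$counts)
})

test_that("minus-strand designs count on the spacer-strand orientation", {
  dplus <- demo_design("+")
  dminus <- demo_design("-")
  expect_equal(dminus$ref_spacer, dplus$ref_spacer)
  # same planted frequency lands at the same spacer position either way
  for (d in list(dplus, dminus)) {
    reads <- generate_reads(d, c(`8` = 0.25), n_reads = 80L, seed = 8,
                            mode = "exact")
    reads$mean_qual <- 35
    sf <- substitution_frequencies(quantify(reads, d))
    expect_equal(sf$freq[sf$position == 8 & sf$base == "T"], 0.25)
  }
})

test_that("planted binomial frequencies are recovered within 3 binomial
           standard deviations", {
  d <- demo_design()
  n <- 2000L; p <- 0.45
  reads <- generate_reads(d, c(`8` = p), n_reads = n, seed = 11,
                          mode = "binomial")
  reads$mean_qual <- 35
  sf <- substitution_frequencies(quantify(reads, d))
  est <- sf$freq[sf$position == 8 & sf$base == "T"]
  expect_lt(abs(est - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("cognate-to-bystander ratios follow the frequency ratio with the
           documented boundary behaviour", {
  d <- demo_design()
  # construct counts directly: C at positions 5 and 8 of the reference
  pbf <- quantify(data.frame(id = character(), seq = character(),
                             mean_qual = numeric()), d)
  pbf$n_anchored <- 1000L
  pbf$counts[] <- 0L
  pbf$counts["T", 8] <- 627L     # cognate C8 -> T
  pbf$counts["T", 5] <- 100L     # bystander C5 -> T
  r <- bystander_ratio(pbf, 8, 5)
  expect_equal(r$ratio, 6.27)
  expect_equal(r$cognate_freq, 0.627)

  pbf$counts["T", 5] <- 627L
  expect_equal(bystander_ratio(pbf, 8, 5)$ratio, 1)

  pbf$counts["T", 5] <- 0L
  expect_equal(bystander_ratio(pbf, 8, 5)$ratio, Inf)

  pbf$counts["T", 8] <- 0L      # both zero: equal, ratio 1
  expect_equal(bystander_ratio(pbf, 8, 5)$ratio, 1)

  expect_error(bystander_ratio(pbf, 8, 2), "not C")
})

test_that("FASTQ round trip through the design table drives end-to-end
           quantification", {
  d <- demo_design()
  fq <- tempfile(fileext = ".fastq")
  generate_reads(d, c(`8` = 0.40), n_reads = 50L, seed = 13,
                 mode = "exact", path = fq)
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(amplicon_id = d$amplicon_id, reference = d$reference,
               barcode = d$barcode, spacer_start = d$spacer_start0 + 1L,
               strand = d$strand),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  designs <- read_designs_tsv(tsv)
  dmx <- demultiplex(fq, designs)
  expect_equal(nrow(dmx$assigned$amp1), 50L)
  sf <- substitution_frequencies(quantify(dmx$assigned$amp1, designs[[1]]))
  expect_equal(sf$freq[sf$position == 8 & sf$base == "T"], 0.40)
})
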