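# Amplicon editing quantification: barcode demultiplexing, alignment-free
# anchored per-position base counting on the protospacer, and
# cognate-to-bystander selectivity ratios. Counting is alignment-free by
# design: reads must match two fixed 12-mer flanks around the protospacer
# exactly, which excludes reads with indels in or near the window (base
# editors do not cut, so such reads are rare) and makes every count exactly
# reproducible.

.ANCHOR_LEN <- 12L

#' Define an amplicon design
#'
#' @param amplicon_id Identifier.
#' @param reference Amplicon reference sequence (without the barcode).
#' @param barcode 8-mer expected at the 5' end of every read of this
#'   amplicon.
#' @param spacer_start 1-based position of the first protospacer base in
#'   `reference` (leftmost base of the 20-mer on the forward reference).
#' @param strand Strand of the protospacer on the reference: position 1
#'   (PAM-distal) is the leftmost interval base for `"+"`, the rightmost for
#'   `"-"`.
#' @return An object of class `amplicon_design`. Fails if the protospacer
#'   does not leave room for the two 12-mer anchor flanks or if either flank
#'   is not unique in the reference.
#' @export
amplicon_design <- function(amplicon_id, reference, barcode, spacer_start,
                            strand = c("+", "-")) {
  strand <- match.arg(strand)
  reference <- .clean_seq(reference, what = amplicon_id)
  barcode <- toupper(barcode)
  if (nchar(barcode) != 8L) stop("barcode must be an 8-mer")
  s0 <- as.integer(spacer_start) - 1L            # 0-based
  if (s0 < .ANCHOR_LEN ||
      s0 + 20L + .ANCHOR_LEN > nchar(reference))
    stop("protospacer leaves no room for the 12-mer anchor flanks in ",
         amplicon_id)
  left <- substring(reference, s0 - .ANCHOR_LEN + 1L, s0)
  right <- substring(reference, s0 + 21L, s0 + 20L + .ANCHOR_LEN)
  for (fl in c(left, right)) {
    hits <- gregexpr(fl, reference, fixed = TRUE)[[1]]
    if (length(hits) != 1L)
      stop("anchor flank '", fl, "' is not unique in the reference of ",
           amplicon_id)
  }
  structure(list(amplicon_id = amplicon_id, reference = reference,
                 barcode = barcode, spacer_start0 = s0, strand = strand,
                 left_flank = left, right_flank = right,
                 ref_spacer = {
                   sp <- substring(reference, s0 + 1L, s0 + 20L)
                   if (strand == "-") revcomp(sp) else sp
                 }),
            class = "amplicon_design")
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path (gzip allowed).
#' @return Data.frame with `id`, `seq` and `mean_qual` (mean Phred score).
#' @export
read_fastq <- function(path) {
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  if (length(qs) == 0L)
    return(data.frame(id = character(), seq = character(),
                      mean_qual = numeric(), stringsAsFactors = FALSE))
  mq <- vapply(as(Biostrings::quality(qs), "IntegerList"),
               function(v) mean(v), numeric(1))
  data.frame(id = sub("\\s.*$", "", names(qs)),
             seq = as.character(qs), mean_qual = mq,
             stringsAsFactors = FALSE)
}

#' Demultiplex reads by exact 8-mer barcode prefix
#'
#' A read is assigned iff its first 8 bases exactly equal one design's
#' barcode; there is no mismatch rescue.
#'
#' @param reads Read table from [read_fastq()] (or a FASTQ path).
#' @param designs List of [amplicon_design()] with pairwise-distinct
#'   barcodes.
#' @return List with `assigned` (named list amplicon_id -> read table) and
#'   `n_unassigned`.
#' @export
demultiplex <- function(reads, designs) {
  if (is.character(reads)) reads <- read_fastq(reads)
  bcs <- vapply(designs, `[[`, "", "barcode")
  ids <- vapply(designs, `[[`, "", "amplicon_id")
  if (anyDuplicated(bcs))
    stop("duplicate barcodes across designs: ",
         paste(unique(bcs[duplicated(bcs)]), collapse = ", "))
  prefix <- substring(reads$seq, 1L, 8L)
  hit <- match(prefix, bcs)
  assigned <- lapply(seq_along(designs), function(i)
    reads[which(hit == i), , drop = FALSE])
  names(assigned) <- ids
  list(assigned = assigned, n_unassigned = sum(is.na(hit)))
}

#' Quantify per-position base frequencies for one amplicon
#'
#' Reads with mean Phred below `min_qual` are dropped first; survivors are
#' anchored by exact match of the two 12-mer flanks (the left flank must
#' occur exactly once in the read and the 12-mer following the extracted
#' 20-mer must equal the right flank). Anchored 20-mers are oriented to the
#' spacer strand (position 1 = PAM-distal) and tallied.
#'
#' @param reads Read table for this amplicon (from [demultiplex()]).
#' @param design The [amplicon_design()].
#' @param min_qual Minimum mean Phred score (default 15).
#' @return An object of class `position_base_freq`: list with `counts`
#'   (4 x 20 integer matrix, rows A/C/G/T), `ref_spacer`, and the read
#'   accounting `n_assigned = n_anchored + n_anchor_failed +
#'   n_quality_failed`.
#' @export
quantify <- function(reads, design, min_qual = 15) {
  stopifnot(inherits(design, "amplicon_design"))
  n_assigned <- nrow(reads)
  ok_q <- reads$mean_qual >= min_qual
  n_qfail <- sum(!ok_q)
  seqs <- reads$seq[ok_q]
  spacers <- character(0)
  n_afail <- 0L
  if (length(seqs)) {
    lf <- design$left_flank; rf <- design$right_flank
    hit <- gregexpr(lf, seqs, fixed = TRUE)
    ext <- vapply(seq_along(seqs), function(i) {
      h <- hit[[i]]
      if (length(h) != 1L || h[1] == -1L) return(NA_character_)
      at <- h[1] + .ANCHOR_LEN
      sp <- substring(seqs[i], at, at + 19L)
      if (nchar(sp) != 20L) return(NA_character_)
      if (substring(seqs[i], at + 20L, at + 19L + .ANCHOR_LEN) != rf)
        return(NA_character_)
      sp
    }, character(1))
    n_afail <- sum(is.na(ext))
    spacers <- ext[!is.na(ext)]
    if (design$strand == "-" && length(spacers)) spacers <- revcomp(spacers)
  }
  counts <- matrix(0L, 4L, 20L, dimnames = list(c("A", "C", "G", "T"), NULL))
  if (length(spacers)) {
    m <- matrix(unlist(strsplit(spacers, ""), use.names = FALSE), nrow = 20L)
    for (p in 1:20) {
      tb <- table(factor(m[p, ], levels = c("A", "C", "G", "T")))
      counts[, p] <- counts[, p] + as.integer(tb)
    }
  }
  structure(list(counts = counts, ref_spacer = design$ref_spacer,
                 amplicon_id = design$amplicon_id,
                 n_assigned = n_assigned, n_anchored = length(spacers),
                 n_anchor_failed = n_afail, n_quality_failed = n_qfail),
            class = "position_base_freq")
}

#' Per-position substitution frequencies
#'
#' Frequency = substitution reads / total anchored reads, per protospacer
#' position and observed base. Positions are 1..20 with PAM-distal = 1.
#'
#' @param pbf A `position_base_freq` from [quantify()].
#' @return Data.frame with `position`, `ref_base`, `base`, `count`, `freq`
#'   (NA when the denominator is 0).
#' @export
substitution_frequencies <- function(pbf) {
  stopifnot(inherits(pbf, "position_base_freq"))
  refb <- strsplit(pbf$ref_spacer, "")[[1]]
  denom <- pbf$n_anchored
  out <- data.frame(position = rep(1:20, each = 4L),
                    ref_base = rep(refb, each = 4L),
                    base = rep(rownames(pbf$counts), 20L),
                    count = as.integer(pbf$counts),
                    stringsAsFactors = FALSE)
  out$freq <- if (denom > 0) out$count / denom else NA_real_
  out
}

# frequency of one substitution at one position (helper)
.subst_freq <- function(pbf, pos, from = "C", to = "T") {
  refb <- substring(pbf$ref_spacer, pos, pos)
  if (refb != from)
    stop("reference base at position ", pos, " is ", refb, ", not ", from)
  if (pbf$n_anchored == 0L) return(NA_real_)
  unname(pbf$counts[to, pos] / pbf$n_anchored)
}

#' Cognate-to-bystander editing ratio
#'
#' Ratio of the C->T frequency at the intended (cognate) position to the
#' C->T frequency at a neighbouring bystander C; a selectivity measure
#' (ratio 1 means entirely non-selective editing).
#'
#' @param pbf A `position_base_freq` from [quantify()].
#' @param cognate_pos,bystander_pos Protospacer positions; both must be
#'   reference Cs and the denominator must be nonzero reads.
#' @return List with `cognate_pos`, `bystander_pos`, `cognate_freq`,
#'   `bystander_freq` and `ratio` (Inf when the bystander frequency is 0 and
#'   the cognate frequency positive; 1 when both frequencies are equal,
#'   including both zero).
#' @export
bystander_ratio <- function(pbf, cognate_pos, bystander_pos) {
  fc <- .subst_freq(pbf, cognate_pos, "C", "T")
  fb <- .subst_freq(pbf, bystander_pos, "C", "T")
  if (is.na(fc) || is.na(fb))
    stop("undefined frequencies: no anchored reads")
  ratio <- if (fc == fb) 1 else if (fb == 0) Inf else fc / fb
  list(cognate_pos = cognate_pos, bystander_pos = bystander_pos,
       cognate_freq = fc, bystander_freq = fb, ratio = ratio)
}

#' Read an amplicon design table
#'
#' TSV with columns `amplicon_id`, `reference`, `barcode`, `spacer_start`
#' (1-based), `strand`.
#'
#' @param path TSV path.
#' @return List of [amplicon_design()].
#' @export
read_designs_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    amplicon_design(df$amplicon_id[i], df$reference[i], df$barcode[i],
                    df$spacer_start[i], df$strand[i]))
}
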