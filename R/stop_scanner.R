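# Core scanner: enumerate protospacers whose editing window covers a C whose
# C->T conversion creates a premature stop codon.
#
# Rule table (coding-strand codon -> edited stop):
#   CAA -> TAA, CAG -> TAG, CGA -> TGA  (target C is codon base 1, coding
#   strand); TGG -> TGA or TAG via either C of the template-strand CCA
#   (first C of CCA pairs with codon base 3, second with base 2). Editing
#   the second C alone gives TAG; full conversion of the CCA can also give
#   TAA, but every single-C edit is covered by the two targets emitted.

#' PAM specification
#'
#' @param pattern IUPAC string of length 3, e.g. `"NGG"` or `"NGN"`.
#' @return An object of class `pam_spec`.
#' @export
pam_spec <- function(pattern) {
  pattern <- toupper(pattern)
  if (nchar(pattern) != 3L ||
      !all(strsplit(pattern, "")[[1]] %in% names(IUPAC_SETS)))
    stop("PAM must be an IUPAC string of length 3, got '", pattern, "'")
  structure(list(pattern = pattern), class = "pam_spec")
}

#' Editing window
#'
#' Protospacer positions (1-based, PAM-distal position = 1) at which the
#' deaminase is taken to act. The genome-wide scan default is 4-8; 5-9
#' matches the window measured for the hAPOBEC3A-based editor.
#'
#' @param first,last Window bounds, `1 <= first <= last <= 20`.
#' @return An object of class `editing_window`.
#' @export
editing_window <- function(first = 4L, last = 8L) {
  first <- as.integer(first); last <- as.integer(last)
  if (is.na(first) || is.na(last) || first < 1L || last < first || last > 20L)
    stop("invalid editing window [", first, ", ", last,
         "]; need 1 <= first <= last <= 20")
  structure(list(first = first, last = last), class = "editing_window")
}

# empty protospacer table with canonical columns
.empty_protospacers <- function() {
  data.frame(gene_id = character(), contig_id = character(),
             spacer = character(), pam = character(), strand = character(),
             start = integer(), end = integer(), target_c_pos = integer(),
             codon_index = integer(), codon_seq = character(),
             target_strand = character(), resulting_stop = character(),
             stringsAsFactors = FALSE)
}

.empty_targets <- function() {
  data.frame(gene_id = character(), contig_id = character(),
             codon_index = integer(), codon_seq = character(),
             target_strand = character(), c_ref_pos = integer(),
             c_strand = character(), resulting_stop = character(),
             stringsAsFactors = FALSE)
}

#' Find editable codons in one CDS
#'
#' Scans codons 2..(n-1) of the coding sequence (start codon and native
#' terminal stop excluded) and emits one target per CAA/CAG/CGA codon (the
#' codon's first base is the edited C, on the coding strand) and two targets
#' per TGG codon (the two Cs of the template-strand CCA opposite it).
#'
#' @param cds_seq Coding-strand sequence of the CDS, 5'->3'.
#' @param cds One row of a CDS table (gives strand and genomic interval).
#' @return A data.frame of editable targets with the reference coordinate
#'   (`c_ref_pos`, 0-based on the forward reference) and reference strand
#'   (`c_strand`) carrying each target C.
#' @export
find_editable_targets <- function(cds_seq, cds) {
  stopifnot(nrow(cds) == 1L)
  n <- nchar(cds_seq)
  if (n %% 3L != 0L)
    stop("CDS ", cds$gene_id, " length ", n, " not divisible by 3")
  n_codon <- n %/% 3L
  if (n_codon < 3L) return(.empty_targets())
  ci <- 2:(n_codon - 1L)
  codons <- substring(cds_seq, 3L * (ci - 1L) + 1L, 3L * ci)

  # offset within CDS (0-based) -> forward-reference coordinate
  to_ref <- function(j) {
    if (cds$strand == "+") cds$start + j else cds$end - 1L - j
  }
  rows <- list()
  coding_hits <- which(codons %in% c("CAA", "CAG", "CGA"))
  if (length(coding_hits)) {
    idx <- ci[coding_hits]
    stops <- c(CAA = "TAA", CAG = "TAG", CGA = "TGA")[codons[coding_hits]]
    rows[[1]] <- data.frame(
      gene_id = cds$gene_id, contig_id = cds$contig_id,
      codon_index = idx, codon_seq = codons[coding_hits],
      target_strand = "coding",
      c_ref_pos = to_ref(3L * (idx - 1L)),
      c_strand = cds$strand,
      resulting_stop = unname(stops), stringsAsFactors = FALSE)
  }
  tgg_hits <- which(codons == "TGG")
  if (length(tgg_hits)) {
    idx <- ci[tgg_hits]
    opp <- if (cds$strand == "+") "-" else "+"
    # first C of template CCA pairs with codon base 3 -> TGA;
    # second C pairs with codon base 2 -> TAG
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = cds$gene_id, contig_id = cds$contig_id,
      codon_index = rep(idx, each = 2L), codon_seq = "TGG",
      target_strand = "template",
      c_ref_pos = as.vector(rbind(to_ref(3L * (idx - 1L) + 2L),
                                  to_ref(3L * (idx - 1L) + 1L))),
      c_strand = opp,
      resulting_stop = rep(c("TGA", "TAG"), times = length(idx)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.empty_targets())
  out <- do.call(rbind, rows)
  out <- out[order(out$codon_index, match(out$resulting_stop,
                                          c("TAA", "TAG", "TGA"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate protospacer placements for editable targets
#'
#' For each target C and each window offset `p` in `[first, last]`, places a
#' 20-mer on the strand carrying the C so that the C sits at spacer position
#' `p` (PAM-distal = 1), reads the 3-mer immediately 3' of the spacer on that
#' strand, and keeps the candidate iff the PAM matches the specification and
#' the 23-mer contains no N. Placements running off a linear contig end are
#' silently skipped; on circular contigs they wrap around.
#'
#' @param genome A [genome_record()].
#' @param targets Data.frame from [find_editable_targets()] (one or more
#'   rows).
#' @param pam A [pam_spec()].
#' @param window An [editing_window()].
#' @return Protospacer table: spacer and PAM sequences (5'->3' on the spacer
#'   strand), 0-based half-open spacer interval on the forward reference,
#'   spacer strand, `target_c_pos`, and the originating target's annotation.
#'   Candidates for one target are emitted in increasing `target_c_pos`.
#' @export
enumerate_protospacers <- function(genome, targets, pam, window) {
  stopifnot(inherits(genome, "genome_record"), inherits(pam, "pam_spec"),
            inherits(window, "editing_window"))
  if (nrow(targets) == 0L) return(.empty_protospacers())
  L <- nchar(genome$seq)
  circular <- genome$topology == "circular"
  ps <- window$first:window$last
  k <- length(ps)
  n <- nrow(targets)
  # expand targets x window offsets
  ti <- rep(seq_len(n), each = k)
  p <- rep(ps, times = n)
  pos <- targets$c_ref_pos[ti]
  strand <- targets$c_strand[ti]
  if (any(pos < 0L | pos >= L)) stop("target C position outside genome")

  plus <- strand == "+"
  # 23-mer start on the forward reference
  start23 <- ifelse(plus, pos - (p - 1L), pos + (p - 1L) - 22L)
  spacer_start <- ifelse(plus, start23, start23 + 3L)

  if (circular) {
    seq2 <- paste0(genome$seq, substring(genome$seq, 1L, 22L))
    idx <- ((start23 %% L) + L) %% L
    mer23 <- .slices(seq2, idx, 23L)
    keep_bounds <- rep(TRUE, length(idx))
  } else {
    keep_bounds <- start23 >= 0L & start23 + 23L <= L
    mer23 <- rep(NA_character_, length(start23))
    mer23[keep_bounds] <- .slices(genome$seq, start23[keep_bounds], 23L)
  }
  keep <- keep_bounds & !is.na(mer23) & !grepl("N", mer23, fixed = TRUE)
  if (!any(keep)) return(.empty_protospacers())

  mer <- mer23[keep]
  minus <- !plus[keep]
  mer[minus] <- revcomp(mer[minus])
  spacer <- substring(mer, 1L, 20L)
  pam3 <- substring(mer, 21L, 23L)
  ok <- iupac_match(pam3, pam$pattern)
  if (!any(ok)) return(.empty_protospacers())

  sel <- which(keep)[ok]
  tsel <- ti[sel]
  out <- data.frame(
    gene_id = targets$gene_id[tsel], contig_id = targets$contig_id[tsel],
    spacer = spacer[ok], pam = pam3[ok],
    strand = strand[sel],
    start = as.integer(((spacer_start[sel] %% L) + L) %% L),
    end = NA_integer_,
    target_c_pos = p[sel],
    codon_index = targets$codon_index[tsel],
    codon_seq = targets$codon_seq[tsel],
    target_strand = targets$target_strand[tsel],
    resulting_stop = targets$resulting_stop[tsel],
    stringsAsFactors = FALSE)
  out$end <- out$start + 20L   # may exceed L on circular wraparound
  rownames(out) <- NULL
  out
}

# physical placement key used for deduplication
.placement_key <- function(x) {
  paste(x$contig_id, x$spacer, x$pam, x$strand, x$start, x$end, sep = "\r")
}

#' Deduplicate protospacers by physical placement
#'
#' Uniqueness key is (contig, spacer sequence, PAM, strand, genomic
#' interval); coincident placements — typically the two target Cs of one TGG
#' codon falling in the same window — are collapsed keeping the first row.
#' Order is stable.
#'
#' @param protospacers Protospacer table.
#' @return Deduplicated protospacer table.
#' @export
dedupe_protospacers <- function(protospacers) {
  if (nrow(protospacers) == 0L) return(protospacers)
  out <- protospacers[!duplicated(.placement_key(protospacers)), ,
                      drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a genome for stop-introducing protospacers
#'
#' Composition of [find_editable_targets()], [enumerate_protospacers()] and
#' [dedupe_protospacers()] over all non-partial CDS features, annotated with
#' the sequence-context features of [annotate_protospacers()]. Deduplication
#' is applied within each gene; a physical 23-mer shared by two overlapping
#' genes appears once under each (genome-level totals deduplicate across
#' genes, see [build_scope_report()]).
#'
#' @param genomes Named list of [genome_record()] (or a single record).
#' @param cds CDS table; partial features are ignored.
#' @param pam A [pam_spec()] (default NGG).
#' @param window An [editing_window()] (default 4-8).
#' @param pattern Optional IUPAC 23-mer; when given, candidates are
#'   restricted to spacer+PAM sequences matching it (see [match_pattern()]).
#' @param annotate Add classifier columns (default `TRUE`).
#' @return Annotated protospacer table ordered by (contig, gene start, codon
#'   index, target C position).
#' @export
scan_genome <- function(genomes, cds, pam = pam_spec("NGG"),
                        window = editing_window(4, 8), pattern = NULL,
                        annotate = TRUE) {
  if (inherits(genomes, "genome_record"))
    genomes <- stats::setNames(list(genomes), genomes$contig_id)
  use <- cds[!cds$partial, , drop = FALSE]
  res <- list()
  if (nrow(use)) {
    ord <- order(use$contig_id, use$start)
    use <- use[ord, , drop = FALSE]
    for (i in seq_len(nrow(use))) {
      row <- use[i, , drop = FALSE]
      g <- genomes[[row$contig_id]]
      if (is.null(g)) stop("CDS ", row$gene_id, " references unknown contig ",
                           row$contig_id)
      tg <- find_editable_targets(extract_cds(g, row), row)
      hits <- dedupe_protospacers(enumerate_protospacers(g, tg, pam, window))
      hits <- hits[order(hits$codon_index, hits$target_c_pos), , drop = FALSE]
      res[[length(res) + 1L]] <- hits
    }
  }
  out <- if (length(res)) do.call(rbind, res) else .empty_protospacers()
  if (!is.null(pattern) && nrow(out))
    out <- out[match_pattern(paste0(out$spacer, out$pam), pattern), ,
               drop = FALSE]
  rownames(out) <- NULL
  if (annotate) out <- annotate_protospacers(out, window)
  out
}
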