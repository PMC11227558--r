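# Genome and annotation I/O. Internal coordinate convention is 0-based
# half-open [start, end); GenBank and GFF3 (1-based inclusive) are converted
# on read, BED is written 0-based half-open, TSV reports 1-based inclusive.

#' Construct a genome record
#'
#' One contig's DNA sequence with its topology. The sequence is uppercased
#' and any character outside \{A,C,G,T,N\} is converted to N with a warning.
#'
#' @param contig_id Contig identifier.
#' @param seq DNA sequence (single string).
#' @param topology `"linear"` (default) or `"circular"`.
#' @return An object of class `genome_record`: a list with elements
#'   `contig_id`, `seq` and `topology`.
#' @export
genome_record <- function(contig_id, seq, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(contig_id), length(contig_id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- .clean_seq(seq, what = contig_id)
  if (nchar(seq) < 1L) stop("empty sequence for contig ", contig_id)
  structure(list(contig_id = contig_id, seq = seq, topology = topology),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s\n",
              x$contig_id, nchar(x$seq), x$topology))
  invisible(x)
}

#' Construct a CDS feature table
#'
#' @param gene_id Locus tags (or fallback identifiers).
#' @param contig_id Contig each CDS lives on.
#' @param start,end 0-based half-open interval on the contig.
#' @param strand `"+"` or `"-"`.
#' @param partial Logical; `TRUE` for features that must not be codon-scanned
#'   (joined/compound locations, out-of-frame lengths, annotated partials).
#' @return A `data.frame` with one row per CDS.
#' @export
cds_table <- function(gene_id, contig_id, start, end, strand,
                      partial = FALSE) {
  df <- data.frame(gene_id = as.character(gene_id),
                   contig_id = as.character(contig_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   partial = as.logical(partial),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    stopifnot(all(df$strand %in% c("+", "-")),
              all(df$start >= 0L), all(df$end > df$start))
  }
  df
}

# ---- GenBank flatfile -------------------------------------------------------

# parse one location string like "4..12", "complement(4..12)",
# "join(1..9,20..30)", "<1..9"; returns list(start0, end, strand, partial)
.parse_gb_location <- function(loc) {
  partial <- grepl("[<>]", loc) || grepl("join|order", loc)
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (length(nums) == 0L) return(NULL)
  list(start0 = as.integer(min(nums) - 1L), end = as.integer(max(nums)),
       strand = strand, partial = partial)
}

#' Read a GenBank flatfile
#'
#' Parses LOCUS records with their ORIGIN sequence and CDS features into the
#' internal model. `gene_id` is taken from the `locus_tag` qualifier, falling
#' back to `gene`, then `protein_id`; a CDS with none of these is skipped with
#' a warning. Compound (joined) locations are kept but flagged `partial`, as
#' are CDS features whose length is not a multiple of 3, so they are excluded
#' from codon scanning.
#'
#' @param path Path to a GenBank flatfile (one or more LOCUS records).
#' @return A list with `genomes` (list of [genome_record()]) and `cds`
#'   (a CDS table, see [cds_table()]).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_at <- grep("^LOCUS", lines)
  if (length(locus_at) == 0L)
    stop("parse error in ", path, ": no LOCUS line found (line 1)")
  rec_end <- c(locus_at[-1] - 1L, length(lines))
  genomes <- list()
  cds_rows <- list()
  for (r in seq_along(locus_at)) {
    rl <- lines[locus_at[r]:rec_end[r]]
    toks <- strsplit(trimws(rl[1]), "[[:space:]]+")[[1]]
    contig <- toks[2]
    topo <- if (any(grepl("circular", rl[1]))) "circular" else "linear"
    ori <- grep("^ORIGIN", rl)
    if (length(ori) == 0L)
      stop("parse error in ", path, ": record ", contig,
           " has no ORIGIN section (line ", locus_at[r], ")")
    seq_lines <- rl[(ori[1] + 1L):length(rl)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- gsub("[^A-Za-z]", "", paste(seq_lines, collapse = ""))
    genomes[[contig]] <- genome_record(contig, seq, topo)

    feat <- grep("^FEATURES", rl)
    if (length(feat) == 0L) next
    body <- rl[(feat[1] + 1L):(ori[1] - 1L)]
    key_at <- grep("^ {5}\\S", body)
    if (length(key_at) == 0L) next
    key_end <- c(key_at[-1] - 1L, length(body))
    for (k in seq_along(key_at)) {
      block <- body[key_at[k]:key_end[k]]
      key <- strsplit(trimws(block[1]), "[[:space:]]+")[[1]][1]
      if (key != "CDS") next
      # location may continue over lines until the first qualifier
      qual_at <- grep("^ +/", block)
      loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
      loc <- paste(trimws(sub("^ {5}CDS", "", block[1:loc_end])),
                   collapse = "")
      pl <- .parse_gb_location(loc)
      if (is.null(pl)) next
      quals <- paste(block, collapse = " ")
      getq <- function(q) {
        m <- regmatches(quals, regexpr(sprintf('/%s="?[^"/]+', q), quals))
        if (length(m) == 0L) return(NA_character_)
        sub(sprintf('/%s="?', q), "", m)
      }
      gid <- getq("locus_tag")
      if (is.na(gid)) gid <- getq("gene")
      if (is.na(gid)) gid <- getq("protein_id")
      if (is.na(gid)) {
        warning("CDS at ", loc, " has no locus_tag/gene/protein_id; skipped")
        next
      }
      partial <- pl$partial || grepl("/pseudo\\b", quals)
      if (!partial && (pl$end - pl$start0) %% 3L != 0L) {
        warning("CDS ", gid, " length not a multiple of 3; flagged partial")
        partial <- TRUE
      }
      cds_rows[[length(cds_rows) + 1L]] <-
        cds_table(gid, contig, pl$start0, pl$end, pl$strand, partial)
    }
  }
  cds <- if (length(cds_rows)) do.call(rbind, cds_rows) else
    cds_table(character(), character(), integer(), integer(), character(),
              logical())
  list(genomes = genomes, cds = cds)
}

# ---- FASTA + GFF3 -----------------------------------------------------------

#' Read a genome from FASTA with GFF3 CDS annotation
#'
#' Contigs come from the FASTA; CDS rows (type `CDS`) from the GFF3. Multiple
#' CDS rows sharing one ID (multi-exon style) are collapsed to their spanning
#' interval and flagged `partial`. A nonzero phase triggers a warning only.
#'
#' @param fasta Path to a FASTA file.
#' @param gff Path to a GFF3 file whose seqids reference the FASTA contigs.
#' @param topology Topology applied to every contig.
#' @return Same shape as [read_genbank()].
#' @export
read_fasta_gff <- function(fasta, gff, topology = "linear") {
  ss <- Biostrings::readDNAStringSet(fasta)
  names(ss) <- sub("\\s.*$", "", names(ss))
  genomes <- lapply(seq_along(ss), function(i)
    genome_record(names(ss)[i], as.character(ss[[i]]), topology))
  names(genomes) <- names(ss)

  gr <- rtracklayer::import(gff)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  if (length(gr) == 0L)
    return(list(genomes = genomes,
                cds = cds_table(character(), character(), integer(),
                                integer(), character(), logical())))
  seqid <- as.character(GenomicRanges::seqnames(gr))
  if (!all(seqid %in% names(genomes)))
    stop("GFF seqid(s) absent from FASTA: ",
         paste(unique(setdiff(seqid, names(genomes))), collapse = ", "))
  md <- as.data.frame(S4Vectors::mcols(gr))
  pick <- function(col) if (col %in% names(md)) as.character(md[[col]]) else
    rep(NA_character_, length(gr))
  gid <- pick("locus_tag")
  gid <- ifelse(is.na(gid), pick("ID"), gid)
  gid <- ifelse(is.na(gid), pick("Name"), gid)
  keep <- !is.na(gid)
  if (any(!keep))
    warning(sum(!keep), " CDS row(s) without locus_tag/ID/Name skipped")
  df <- data.frame(gene_id = gid[keep], contig_id = seqid[keep],
                   start = GenomicRanges::start(gr)[keep] - 1L,
                   end = GenomicRanges::end(gr)[keep],
                   strand = as.character(GenomicRanges::strand(gr))[keep],
                   phase = if ("phase" %in% names(md)) md$phase[keep] else 0L,
                   stringsAsFactors = FALSE)
  if (any(!is.na(df$phase) & df$phase != 0L))
    warning("nonzero GFF phase encountered; phase is not applied")
  # multi-row IDs: collapse to span, flag partial
  sp <- split(seq_len(nrow(df)), paste(df$contig_id, df$gene_id))
  rows <- lapply(sp, function(ix) {
    d <- df[ix, , drop = FALSE]
    partial <- length(ix) > 1L
    start <- min(d$start); end <- max(d$end)
    if (!partial && (end - start) %% 3L != 0L) {
      warning("CDS ", d$gene_id[1], " length not a multiple of 3; ",
              "flagged partial")
      partial <- TRUE
    }
    cds_table(d$gene_id[1], d$contig_id[1], start, end, d$strand[1], partial)
  })
  cds <- do.call(rbind, rows)
  rownames(cds) <- NULL
  cds <- cds[order(cds$contig_id, cds$start), , drop = FALSE]
  rownames(cds) <- NULL
  list(genomes = genomes, cds = cds)
}

# ---- extraction and writers -------------------------------------------------

#' Extract the coding-strand sequence of a CDS
#'
#' @param genome A [genome_record()].
#' @param cds One row of a CDS table (data.frame with `start`, `end`,
#'   `strand`).
#' @return Coding-strand DNA string, 5'->3'; for `-` strand features this is
#'   the reverse complement of the genomic slice.
#' @export
extract_cds <- function(genome, cds) {
  stopifnot(inherits(genome, "genome_record"), nrow(cds) == 1L)
  L <- nchar(genome$seq)
  if (cds$start < 0L || cds$end > L)
    stop("CDS interval [", cds$start, ",", cds$end, ") out of bounds for ",
         genome$contig_id, " (length ", L, ")")
  s <- substring(genome$seq, cds$start + 1L, cds$end)
  if (cds$strand == "-") s <- revcomp(s)
  s
}

#' Write genome records to FASTA
#'
#' @param genomes List of [genome_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  ss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(ss) <- vapply(genomes, `[[`, "", "contig_id")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# canonical guide report column order (bit-stable)
.guide_tsv_cols <- c("gene_id", "contig", "spacer", "pam", "strand",
                     "start_1based", "end_1based", "target_c_pos",
                     "codon_index", "codon_seq", "resulting_stop",
                     "gc_percent", "gc_motif_in_window", "bystander_c_count",
                     "pam_class")

#' Write a guide report TSV
#'
#' Columns are emitted in a fixed order with 1-based inclusive coordinates.
#'
#' @param guides Annotated protospacer table from [scan_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guides_tsv <- function(guides, path) {
  out <- data.frame(gene_id = guides$gene_id, contig = guides$contig_id,
                    spacer = guides$spacer, pam = guides$pam,
                    strand = guides$strand,
                    start_1based = guides$start + 1L,
                    end_1based = guides$end,
                    target_c_pos = guides$target_c_pos,
                    codon_index = guides$codon_index,
                    codon_seq = guides$codon_seq,
                    resulting_stop = guides$resulting_stop,
                    gc_percent = guides$gc_percent,
                    gc_motif_in_window = guides$gc_motif_in_window,
                    bystander_c_count = guides$bystander_c_count,
                    pam_class = guides$pam_class,
                    stringsAsFactors = FALSE)
  utils::write.table(out[, .guide_tsv_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write guides as BED6
#'
#' 0-based half-open spacer intervals;
#' `name = gene_id|codon_index|PAM`, score 0, strand of the spacer.
#'
#' @inheritParams write_guides_tsv
#' @return `path`, invisibly.
#' @export
write_guides_bed <- function(guides, path) {
  bed <- data.frame(guides$contig_id, guides$start, guides$end,
                    paste(guides$gene_id, guides$codon_index, guides$pam,
                          sep = "|"),
                    0L, guides$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a JSON summary
#'
#' @param x A list (for example a scope report).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
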