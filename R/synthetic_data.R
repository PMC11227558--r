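# Seeded synthetic fixtures with known ground truth: GC-rich genomes with
# planted editable codons and PAMs, amplicon read pools with planted
# per-position editing frequencies, and treated/control SNV tables.
#
# The truth manifest is built by direct string inspection of the finished
# sequence (Biostrings-based IUPAC matching), never by running the scanner,
# so scanner tests against the manifest are a genuine dual route.

# codons that may never appear as background filler inside a planted gene:
# the editable codons (would create unplanted targets) and the stops
.FORBIDDEN_FILL <- c("CAA", "CAG", "CGA", "TGG", "TAA", "TAG", "TGA")

.sample_bases <- function(n, gc) {
  sample(c("G", "C", "A", "T"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

# one filler codon avoiding editable/stop codons, GC-weighted
.fill_codons <- function(n, gc) {
  out <- character(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- paste0(.sample_bases(length(need), gc),
                   .sample_bases(length(need), gc),
                   .sample_bases(length(need), gc))
    ok <- !(cand %in% .FORBIDDEN_FILL)
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Specification for a synthetic genome
#'
#' @param seed Integer seed; every generated byte is a deterministic
#'   function of the spec including this seed.
#' @param length Genome length in bases.
#' @param gc_fraction Background GC fraction (default 0.72, emulating a
#'   high-GC *Streptomyces*-like genome).
#' @param n_genes Number of planted genes.
#' @param gene_length Gene length in bases, a multiple of 3, >= 30.
#' @param planted_targets List (one element per gene, recycled) of lists
#'   with fields `codon_seq` (`"CAA"`, `"CAG"`, `"CGA"` or `"TGG"`),
#'   `codon_index` (1-based codon within the CDS), `pam` (concrete 3-mer to
#'   plant, e.g. `"AGG"`) and `window_pos` (intended spacer position of the
#'   target C). Use `NULL` entries for genes without a planted target.
#' @param strands Strand per gene (recycled; default alternating).
#' @return An object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(seed, length = 10000L, gc_fraction = 0.72,
                                  n_genes = 5L, gene_length = 300L,
                                  planted_targets = list(
                                    list(codon_seq = "CAG", codon_index = 10L,
                                         pam = "AGG", window_pos = 5L)),
                                  strands = c("+", "-")) {
  stopifnot(gene_length %% 3L == 0L, gene_length >= 30L,
            gc_fraction >= 0, gc_fraction <= 1)
  if (n_genes * (gene_length + 100L) > length)
    stop("genome too short for ", n_genes, " genes of ", gene_length,
         " bases with spacing")
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 planted_targets = rep_len(planted_targets, n_genes),
                 strands = rep_len(strands, n_genes)),
            class = "synthetic_genome_spec")
}

# direct string inspection: codon composition of a gene's coding sequence
.inspect_codons <- function(cds_seq) {
  n <- nchar(cds_seq) %/% 3L
  substring(cds_seq, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
}

# manifest row(s) for one planted target under one (pam_pattern, window):
# inspect the finished genome string directly around the planted C
.manifest_for_target <- function(seq, c_ref_pos, c_strand, pam_pattern,
                                 window, gene_id, codon_index, codon_seq) {
  L <- nchar(seq)
  rows <- list()
  for (p in window[1]:window[2]) {
    if (c_strand == "+") {
      s23 <- c_ref_pos - (p - 1L)
      if (s23 < 0L || s23 + 23L > L) next
      mer <- substring(seq, s23 + 1L, s23 + 23L)
      sp_start <- s23
    } else {
      s23 <- c_ref_pos + (p - 1L) - 22L
      if (s23 < 0L || s23 + 23L > L) next
      mer <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substring(seq, s23 + 1L, s23 + 23L))))
      sp_start <- s23 + 3L
    }
    if (grepl("N", mer, fixed = TRUE)) next
    pam3 <- substring(mer, 21L, 23L)
    hit <- Biostrings::countPattern(pam_pattern,
                                    Biostrings::DNAString(pam3),
                                    fixed = FALSE) > 0L
    if (!hit) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene_id, spacer = substring(mer, 1L, 20L), pam = pam3,
      strand = c_strand, start = sp_start, end = sp_start + 20L,
      target_c_pos = p, codon_index = codon_index, codon_seq = codon_seq,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Generate a synthetic genome with a truth manifest
#'
#' Background bases are drawn i.i.d. with `P(G or C) = gc_fraction`. Genes
#' (ATG + filler codons + TAA) are planted at evenly spaced, non-overlapping
#' offsets; filler codons exclude editable and stop codons, so the only
#' editable codons inside genes are the planted ones. Each planted target's
#' PAM trinucleotide is written at the genomic slot that puts the target C
#' at the declared window position. After assembly the generator validates
#' by direct string inspection that each gene contains exactly its planted
#' editable codons in codons 2..(n-1); if the planted PAM bases or the
#' background accidentally create an extra editable codon, generation is
#' retried with a perturbed seed.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param manifest_for List of `(pam_pattern, window)` combinations for
#'   which the manifest should enumerate expected scanner hits, e.g.
#'   `list(list(pam = "NGG", window = c(4, 8)))`.
#' @param max_retries Maximum seed perturbations before giving up.
#' @return List with `genome` (a [genome_record()]), `cds` (CDS table),
#'   `targets` (planted editable targets: gene, codon, C coordinate and
#'   strand) and `manifest` (named list, one expected-protospacer
#'   data.frame per requested combination, names `"PAM:first-last"`).
#' @export
generate_genome <- function(spec,
                            manifest_for = list(
                              list(pam = "NGG", window = c(4L, 8L))),
                            max_retries = 50L) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  for (attempt in 0:max_retries) {
    res <- .try_generate_genome(spec, spec$seed + attempt * 7919L)
    if (!is.null(res)) break
  }
  if (is.null(res))
    stop("could not generate a clean genome after ", max_retries,
         " retries; spec too constrained")
  seq <- res$seq
  manifest <- list()
  for (combo in manifest_for) {
    nm <- sprintf("%s:%d-%d", combo$pam, combo$window[1], combo$window[2])
    rows <- list()
    tg <- res$targets
    for (i in seq_len(nrow(tg))) {
      r <- .manifest_for_target(seq, tg$c_ref_pos[i], tg$c_strand[i],
                                combo$pam, combo$window, tg$gene_id[i],
                                tg$codon_index[i], tg$codon_seq[i])
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene_id = character(), spacer = character(),
                 pam = character(), strand = character(), start = integer(),
                 end = integer(), target_c_pos = integer(),
                 codon_index = integer(), codon_seq = character(),
                 stringsAsFactors = FALSE)
    # collapse coincident placements (two Cs of one TGG sharing a 23-mer)
    df <- df[!duplicated(paste(df$gene_id, df$spacer, df$pam, df$strand,
                               df$start)), , drop = FALSE]
    rownames(df) <- NULL
    manifest[[nm]] <- df
  }
  list(genome = genome_record("synthetic_contig_1", seq),
       cds = res$cds, targets = res$targets, manifest = manifest)
}

# single attempt; returns NULL when validation finds accidental editable
# codons inside a gene
.try_generate_genome <- function(spec, seed) {
  set.seed(seed %% .Machine$integer.max)
  L <- spec$length
  bg <- .sample_bases(L, spec$gc_fraction)
  gap <- (L - spec$n_genes * spec$gene_length) %/% (spec$n_genes + 1L)
  cds_rows <- list()
  target_rows <- list()
  for (g in seq_len(spec$n_genes)) {
    gstart <- gap * g + spec$gene_length * (g - 1L)   # 0-based
    glen <- spec$gene_length
    n_codon <- glen %/% 3L
    codons <- c("ATG", .fill_codons(n_codon - 2L, spec$gc_fraction), "TAA")
    plant <- spec$planted_targets[[g]]
    strand <- spec$strands[g]
    gid <- sprintf("SYN_%04d", g)
    if (!is.null(plant)) {
      ci <- plant$codon_index
      if (ci < 2L || ci > n_codon - 1L)
        stop("planted codon_index ", ci, " outside codons 2..", n_codon - 1L)
      codons[ci] <- plant$codon_seq
    }
    gene_seq <- paste(codons, collapse = "")
    gene_genomic <- if (strand == "+") gene_seq else revcomp(gene_seq)
    bg[(gstart + 1L):(gstart + glen)] <-
      strsplit(gene_genomic, "")[[1]]
    cds_rows[[g]] <- cds_table(gid, "synthetic_contig_1", gstart,
                               gstart + glen, strand)
    if (is.null(plant)) next

    # reference coordinate of the target C
    j <- 3L * (plant$codon_index - 1L)   # codon base 1 offset in CDS
    to_ref <- function(off) if (strand == "+") gstart + off else
      gstart + glen - 1L - off
    if (plant$codon_seq %in% c("CAA", "CAG", "CGA")) {
      c_ref <- to_ref(j)
      c_strand <- strand
      extra_c_ref <- integer(0)
    } else {             # TGG: PAM is planted for the first C of the
      c_ref <- to_ref(j + 2L)             # template-strand CCA; the second
      extra_c_ref <- to_ref(j + 1L)       # C is a target too and must be in
      c_strand <- if (strand == "+") "-" else "+"   # the manifest
    }
    # write the PAM so the C lands at the declared window position
    p <- plant$window_pos
    pam_start <- if (c_strand == "+") c_ref - (p - 1L) + 20L else
      c_ref + (p - 1L) - 22L
    pam_seq <- if (c_strand == "+") plant$pam else revcomp(plant$pam)
    if (pam_start < 0L || pam_start + 3L > L)
      stop("planted PAM runs off the genome for gene ", gid)
    bg[(pam_start + 1L):(pam_start + 3L)] <- strsplit(pam_seq, "")[[1]]
    target_rows[[length(target_rows) + 1L]] <- data.frame(
      gene_id = gid, codon_index = plant$codon_index,
      codon_seq = plant$codon_seq,
      c_ref_pos = c(c_ref, extra_c_ref), c_strand = c_strand,
      window_pos = plant$window_pos, pam = plant$pam,
      stringsAsFactors = FALSE)
  }
  seq <- paste(bg, collapse = "")
  cds <- do.call(rbind, cds_rows)
  targets <- if (length(target_rows)) do.call(rbind, target_rows) else
    data.frame(gene_id = character(), codon_index = integer(),
               codon_seq = character(), c_ref_pos = integer(),
               c_strand = character(), window_pos = integer(),
               pam = character(), stringsAsFactors = FALSE)

  # validation by direct string inspection: every gene must contain exactly
  # its planted editable codons among codons 2..(n-1); the PAM write may
  # have landed inside a gene body and created a new one
  for (g in seq_len(nrow(cds))) {
    row <- cds[g, , drop = FALSE]
    gseq <- substring(seq, row$start + 1L, row$end)
    if (row$strand == "-") gseq <- revcomp(gseq)
    codons <- .inspect_codons(gseq)
    inner <- codons[2:(length(codons) - 1L)]
    found <- which(inner %in% c("CAA", "CAG", "CGA", "TGG")) + 1L
    planted <- targets$codon_index[targets$gene_id == row$gene_id]
    if (!setequal(found, planted)) return(NULL)
    if (codons[1] != "ATG" || any(inner %in% c("TAA", "TAG", "TGA")))
      return(NULL)
  }
  list(seq = seq, cds = cds, targets = targets)
}

#' Generate an amplicon read pool with planted editing frequencies
#'
#' Each read is the design's barcode followed by the full reference, with
#' C->T applied independently per planted position. In `"exact"` mode each
#' position edits exactly `round(freq * n_reads)` reads (a deterministic
#' subset chosen with the seeded generator), so recovered frequencies are
#' exact rationals; in `"binomial"` mode each read-position pair edits with
#' probability `freq`. Sequencing errors (uniform substitution to one of
#' the three other bases) are applied at `error_rate` per base over the
#' whole read, including the barcode. Qualities are a constant Phred score.
#'
#' @param design An [amplicon_design()].
#' @param planted Named numeric vector: names are protospacer positions
#'   (1..20, spacer-strand orientation), values are C->T frequencies; every
#'   named position must be a reference C.
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @param error_rate Per-base substitution error rate (default 0).
#' @param mode `"exact"` or `"binomial"`.
#' @param phred Constant base quality (default 35).
#' @param path Optional FASTQ output path (plain or `.gz`); when `NULL` the
#'   read table is returned invisibly instead of written.
#' @return Data.frame of reads (`id`, `seq`, `qual`); written as FASTQ when
#'   `path` is given.
#' @export
generate_reads <- function(design, planted, n_reads, seed, error_rate = 0,
                           mode = c("exact", "binomial"), phred = 35L,
                           path = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "amplicon_design"))
  if (length(planted) && (any(planted < 0) || any(planted > 1)))
    stop("planted frequencies must lie in [0, 1]")
  set.seed(as.integer(seed))
  refb <- strsplit(design$ref_spacer, "")[[1]]
  pos <- as.integer(names(planted))
  if (length(pos) && any(refb[pos] != "C"))
    stop("planted position(s) are not reference Cs: ",
         paste(pos[refb[pos] != "C"], collapse = ", "))

  # spacer-position -> coordinate within the (barcode + reference) read
  read_coord <- function(p) {
    within_ref <- if (design$strand == "+") design$spacer_start0 + p else
      design$spacer_start0 + 21L - p
    8L + within_ref
  }
  base_read <- paste0(design$barcode, design$reference)
  mat <- matrix(rep(strsplit(base_read, "")[[1]], n_reads),
                ncol = n_reads)
  # edited base on the read (forward) strand: C->T on +, G->A on -
  edit_to <- if (design$strand == "+") "T" else "A"
  for (k in seq_along(pos)) {
    f <- planted[k]
    which_reads <- if (mode == "exact") {
      n_edit <- as.integer(round(f * n_reads))
      if (n_edit > 0L) sample.int(n_reads, n_edit) else integer(0)
    } else {
      which(stats::runif(n_reads) < f)
    }
    if (length(which_reads))
      mat[read_coord(pos[k]), which_reads] <- edit_to
  }
  if (error_rate > 0) {
    hit <- which(stats::runif(length(mat)) < error_rate)
    if (length(hit)) {
      cur <- mat[hit]
      repl <- vapply(cur, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      mat[hit] <- repl
    }
  }
  seqs <- apply(mat, 2L, paste, collapse = "")
  qual <- strrep(rawToChar(as.raw(phred + 33L)), nchar(base_read))
  reads <- data.frame(id = sprintf("%s_read_%06d", design$amplicon_id,
                                   seq_len(n_reads)),
                      seq = seqs, qual = qual, stringsAsFactors = FALSE)
  if (!is.null(path)) write_fastq(reads, path)
  invisible(reads)
}

#' Write a read table as FASTQ
#'
#' @param reads Data.frame with `id`, `seq`, `qual`.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
               con)
  invisible(path)
}

#' Generate treated/control SNV tables with planted truth
#'
#' Plants `n_shared` SNVs present in both tables (background variants) and
#' `n_private` SNVs present only in the treated table, at distinct random
#' positions. Private SNVs are C->T or G->A (deamination-consistent);
#' shared SNVs are drawn from all substitution types. Optionally plants
#' additional private SNVs with sub-threshold depth to exercise the depth
#' filter.
#'
#' @param genome_length Genome length (positions are drawn in 1..length).
#' @param n_shared,n_private Counts of shared and treated-private SNVs.
#' @param depth_range Integer range for depths of shared/private SNVs.
#' @param seed Integer seed.
#' @param n_private_lowdepth Extra private SNVs with depth drawn from
#'   `lowdepth_range` (default 0).
#' @param lowdepth_range Depth range for the low-depth plants (default
#'   `c(1, 10)`, i.e. at or below the default audit threshold).
#' @param contig Contig name used in the tables.
#' @param treated_path,control_path Optional VCF output paths.
#' @return List with `treated`, `control` (SNV tables) and the truth lists
#'   `truth_shared`, `truth_private`, `truth_private_lowdepth`.
#' @export
generate_snv_tables <- function(genome_length, n_shared, n_private,
                                depth_range = c(20L, 100L), seed = 1L,
                                n_private_lowdepth = 0L,
                                lowdepth_range = c(1L, 10L),
                                contig = "synthetic_contig_1",
                                treated_path = NULL, control_path = NULL) {
  stopifnot(n_shared >= 0L, n_private >= 0L, n_private_lowdepth >= 0L)
  set.seed(as.integer(seed))
  n_all <- n_shared + n_private + n_private_lowdepth
  if (n_all > genome_length) stop("more SNVs than positions")
  pos <- sort(sample.int(genome_length, n_all))
  grp <- sample(rep(c("shared", "private", "low"),
                    c(n_shared, n_private, n_private_lowdepth)))
  mk <- function(n, deam) {
    if (deam) {
      ref <- sample(c("C", "G"), n, replace = TRUE)
      alt <- ifelse(ref == "C", "T", "A")
    } else {
      ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      alt <- vapply(ref, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    }
    list(ref = ref, alt = unname(alt))
  }
  rdepth <- function(n, rng)
    if (n) sample(rng[1]:rng[2], n, replace = TRUE) else integer(0)
  build <- function(which_grp, deam, rng) {
    ix <- which(grp == which_grp)
    ra <- mk(length(ix), deam)
    snv_table(contig, pos[ix], ra$ref, ra$alt,
              freq = round(stats::runif(length(ix), 0.05, 0.95), 3),
              depth = rdepth(length(ix), rng))
  }
  shared <- build("shared", deam = FALSE, depth_range)
  private <- build("private", deam = TRUE, depth_range)
  low <- build("low", deam = TRUE, lowdepth_range)
  treated <- rbind(shared, private, low)
  treated <- treated[order(treated$pos), , drop = FALSE]
  rownames(treated) <- NULL
  control <- shared
  if (!is.null(treated_path)) write_snv_vcf(treated, treated_path,
                                            genome_length)
  if (!is.null(control_path)) write_snv_vcf(control, control_path,
                                            genome_length)
  list(treated = treated, control = control, truth_shared = shared,
       truth_private = private, truth_private_lowdepth = low)
}

#' Write an SNV table as a minimal VCF
#'
#' Single-sample VCFv4.2 with INFO `DP`/`AF` and FORMAT `GT:DP:AD:AF`
#' (AD is derived from depth and frequency), readable by any VCF parser.
#'
#' @param snvs SNV table.
#' @param path Output path.
#' @param genome_length Optional contig length for the header.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, path, genome_length = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(genome_length) && nrow(snvs))
             sprintf("##contig=<ID=%s,length=%d>", snvs$contig[1],
                     as.integer(genome_length)),
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele freq">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
           '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Allele freq">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "sample1", sep = "\t"))
  body <- character(0)
  if (nrow(snvs)) {
    ad_alt <- as.integer(round(snvs$depth * snvs$freq))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%s\tGT:DP:AD:AF\t0/1:%d:%d,%d:%s",
                    snvs$contig, snvs$pos, snvs$ref, snvs$alt, snvs$depth,
                    format(snvs$freq, trim = TRUE), snvs$depth,
                    snvs$depth - ad_alt, ad_alt,
                    format(snvs$freq, trim = TRUE))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
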