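# Off-target SNV audit: control subtraction, depth filtering, classification
# of the deamination signature (C->T on either strand, i.e. C->T or G->A on
# the forward reference), genomic binning and cross-replicate summaries.

#' Construct an SNV table
#'
#' @param contig,pos,ref,alt,freq,depth Vectors defining one SNV per row;
#'   `pos` is 1-based, `freq` the alternate-allele fraction, `depth` the
#'   read count.
#' @return Data.frame of SNV records.
#' @export
snv_table <- function(contig, pos, ref, alt, freq = NA_real_,
                      depth = NA_integer_) {
  n <- length(pos)
  df <- data.frame(contig = rep_len(as.character(contig), n),
                   pos = as.integer(pos),
                   ref = rep_len(toupper(as.character(ref)), n),
                   alt = rep_len(toupper(as.character(alt)), n),
                   freq = rep_len(as.numeric(freq), n),
                   depth = rep_len(as.integer(depth), n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    stopifnot(all(nchar(df$ref) == 1L), all(nchar(df$alt) == 1L),
              all(df$ref != df$alt), all(df$pos >= 1L),
              all(is.na(df$freq) | (df$freq >= 0 & df$freq <= 1)),
              all(is.na(df$depth) | df$depth >= 0L))
  }
  df
}

.snv_key <- function(x) paste(x$contig, x$pos, x$ref, x$alt, sep = "\r")

#' Read SNVs from a VCF
#'
#' Multi-allelic rows are split into biallelic records; multi-nucleotide
#' alleles are dropped with a warning (the audit concerns single-nucleotide
#' variants). Depth is taken from the first sample's FORMAT `DP`, falling
#' back to INFO `DP`; the alternate-allele fraction from FORMAT `AF`, then
#' the FORMAT `AD` ratio, then INFO `AF`; NA when absent.
#'
#' @param path VCF path.
#' @return An SNV table (see [snv_table()]).
#' @export
read_snv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(snv_table(character(), integer(), character(), character()))
  nsamp <- ncol(v@gt) - 1L
  getfmt <- function(el) {
    if (is.na(nsamp) || nsamp < 1L) return(rep(NA_character_, nrow(fix)))
    m <- tryCatch(vcfR::extract.gt(v, element = el, as.numeric = FALSE),
                  error = function(e) NULL)
    if (is.null(m)) rep(NA_character_, nrow(fix)) else as.character(m[, 1L])
  }
  info_field <- function(key) {
    m <- regmatches(fix$INFO,
                    regexpr(sprintf("(^|;)%s=[^;]+", key), fix$INFO))
    out <- rep(NA_character_, nrow(fix))
    hit <- fix$INFO != "" & grepl(sprintf("(^|;)%s=", key), fix$INFO)
    out[hit] <- sub(sprintf("^;?%s=", key), "", m)
    out
  }
  fdp <- suppressWarnings(as.numeric(getfmt("DP")))
  idp <- suppressWarnings(as.numeric(info_field("DP")))
  depth <- ifelse(is.na(fdp), idp, fdp)
  fad <- getfmt("AD")
  faf <- getfmt("AF")
  iaf <- info_field("AF")

  rows <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    afs_f <- if (!is.na(faf[i]))
      suppressWarnings(as.numeric(strsplit(faf[i], ",")[[1]])) else NULL
    afs_i <- if (!is.na(iaf[i]))
      suppressWarnings(as.numeric(strsplit(iaf[i], ",")[[1]])) else NULL
    ad <- if (!is.na(fad[i]))
      suppressWarnings(as.numeric(strsplit(fad[i], ",")[[1]])) else NULL
    for (j in seq_along(alts)) {
      if (nchar(fix$REF[i]) != 1L || nchar(alts[j]) != 1L ||
          alts[j] %in% c("*", ".")) {
        n_dropped <- n_dropped + 1L
        next
      }
      af <- NA_real_
      if (!is.null(afs_f) && length(afs_f) >= j) af <- afs_f[j]
      if (is.na(af) && !is.null(ad) && length(ad) >= j + 1L &&
          sum(ad, na.rm = TRUE) > 0)
        af <- ad[j + 1L] / sum(ad, na.rm = TRUE)
      if (is.na(af) && !is.null(afs_i) && length(afs_i) >= j) af <- afs_i[j]
      rows[[length(rows) + 1L]] <- data.frame(
        contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j], freq = af,
        depth = as.integer(depth[i]), stringsAsFactors = FALSE)
    }
  }
  if (n_dropped > 0L)
    warning(n_dropped, " non-SNV allele(s) dropped from ", path)
  if (length(rows) == 0L)
    return(snv_table(character(), integer(), character(), character()))
  do.call(rbind, rows)
}

#' Subtract control SNVs and apply the depth filter
#'
#' Retains treated records whose depth is strictly greater than `min_depth`
#' and whose (contig, pos, ref, alt) identity is absent from the control
#' set. A different alt allele at a control position does not shield a
#' treated SNV. Input order is preserved.
#'
#' @param treated,control SNV tables.
#' @param min_depth Depth threshold; records with `depth > min_depth` are
#'   kept (default 10, i.e. depth must exceed 10).
#' @return Filtered SNV table.
#' @export
subtract_control <- function(treated, control, min_depth = 10L) {
  if (nrow(treated) == 0L) return(treated)
  keep <- treated$depth > min_depth &
    !(.snv_key(treated) %in% .snv_key(control))
  out <- treated[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify SNVs by the deamination signature
#'
#' Cytosine deamination reads as C->T on the edited strand and as G->A on
#' the opposite strand, so both are counted as deamination-consistent.
#'
#' @param snvs SNV table.
#' @return List with `ct_ga` and `other` (a disjoint, exhaustive
#'   partition).
#' @export
classify_ct_ga <- function(snvs) {
  is_ctga <- (snvs$ref == "C" & snvs$alt == "T") |
    (snvs$ref == "G" & snvs$alt == "A")
  list(ct_ga = snvs[is_ctga, , drop = FALSE],
       other = snvs[!is_ctga, , drop = FALSE])
}

#' Bin SNVs along the genome
#'
#' Bins are half-open position intervals `[i * bin_size, (i+1) * bin_size)`
#' applied to the 1-based positions, so a position equal to an exact
#' multiple of the bin size falls into the following bin; a position equal
#' to the genome length is kept in the last bin. Counts sum to the number
#' of input SNVs.
#'
#' @param snvs SNV table.
#' @param genome_length Genome length in bases.
#' @param bin_size Bin width in bases (default 1e5, i.e. 0.1 Mb).
#' @return Data.frame with `bin` (1-based index), `start`, `end` (half-open)
#'   and `count`, one row per bin covering the genome.
#' @export
bin_density <- function(snvs, genome_length, bin_size = 100000L) {
  if (nrow(snvs) && any(snvs$pos > genome_length))
    stop("SNV position beyond genome_length")
  nbins <- max(1L, as.integer(ceiling(genome_length / bin_size)))
  idx <- if (nrow(snvs))
    pmin(snvs$pos %/% bin_size, nbins - 1L) else integer(0)
  counts <- tabulate(idx + 1L, nbins)
  data.frame(bin = seq_len(nbins),
             start = (seq_len(nbins) - 1L) * as.numeric(bin_size),
             end = pmin(seq_len(nbins) * as.numeric(bin_size),
                        as.numeric(genome_length) + 1),
             count = counts)
}

#' Summarize audits across replicates
#'
#' @param audits List of SNV tables, one per replicate (already control-
#'   subtracted and depth-filtered).
#' @param genome_length,bin_size Optional; when `genome_length` is given,
#'   pooled per-bin counts are included.
#' @return An object of class `audit_summary`: per-replicate counts
#'   (`n_ct_ga`, `n_total`), their mean, standard deviation and standard
#'   error (`sem = sd / sqrt(n)`, NA for a single replicate), a union site
#'   frequency matrix (rows = sites, columns = replicates, 0 where a site
#'   is absent), and optionally pooled bin counts.
#' @export
summarize_audits <- function(audits, genome_length = NULL,
                             bin_size = 100000L) {
  if (length(audits) == 0L) stop("need at least one replicate")
  n_ct_ga <- vapply(audits, function(a) nrow(classify_ct_ga(a)$ct_ga),
                    integer(1))
  n_total <- vapply(audits, nrow, integer(1))
  n <- length(audits)
  m <- mean(n_ct_ga)
  s <- if (n > 1L) stats::sd(n_ct_ga) else NA_real_
  sem <- if (n > 1L) s / sqrt(n) else NA_real_
  keys <- unique(unlist(lapply(audits, .snv_key)))
  fm <- matrix(0, length(keys), n,
               dimnames = list(gsub("\r", ":", keys),
                               paste0("rep", seq_len(n))))
  for (j in seq_len(n)) {
    a <- audits[[j]]
    if (nrow(a)) {
      at <- match(.snv_key(a), keys)
      fm[at, j] <- ifelse(is.na(a$freq), 0, a$freq)
    }
  }
  bins <- NULL
  if (!is.null(genome_length)) {
    pooled <- do.call(rbind, audits)
    bins <- bin_density(pooled, genome_length, bin_size)
  }
  structure(list(n_replicates = n, n_ct_ga = n_ct_ga, n_total = n_total,
                 mean_ct_ga = m, sd_ct_ga = s, sem_ct_ga = sem,
                 site_freq = fm, bins = bins, bin_size = bin_size),
            class = "audit_summary")
}

#' @export
print.audit_summary <- function(x, ...) {
  cat(sprintf("<audit_summary> %d replicate(s)\n", x$n_replicates))
  cat(sprintf("  C-to-T/G-to-A per replicate: %s\n",
              paste(x$n_ct_ga, collapse = ", ")))
  if (!is.na(x$sem_ct_ga))
    cat(sprintf("  mean %.2f +/- %.2f (s.e.m.)\n", x$mean_ct_ga,
                x$sem_ct_ga))
  cat(sprintf("  union sites: %d\n", nrow(x$site_freq)))
  invisible(x)
}
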