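# Genome-wide targeting-scope statistics: which fraction of genes can
# receive a premature stop codon, how many unique protospacers each gene
# offers, and how the candidate pool splits into the three efficiency
# categories (no GC motif & GC <= 75%, GC motif, GC > 75%). The latter two
# overlap, so the three printed fractions sum to more than 100; the exact
# identity is fraction(no motif AND gc <= 75) + fraction(motif OR gc > 75)
# = 100.

#' Per-gene protospacer summaries
#'
#' @param protospacers Protospacer table from [scan_genome()] (post-dedupe
#'   within gene).
#' @param genes Character vector: the full gene universe, including genes
#'   with zero protospacers (typically all non-partial CDS gene_ids).
#' @return Data.frame with `gene_id`, `n_unique_protospacers`, `editable`.
#' @export
summarize_genes <- function(protospacers, genes) {
  genes <- as.character(genes)
  extra <- setdiff(unique(protospacers$gene_id), genes)
  if (length(extra))
    stop("protospacers reference gene(s) outside the universe: ",
         paste(utils::head(extra, 3), collapse = ", "))
  counts <- table(factor(protospacers$gene_id, levels = genes))
  data.frame(gene_id = genes,
             n_unique_protospacers = as.integer(counts),
             editable = as.integer(counts) >= 1L,
             stringsAsFactors = FALSE)
}

#' Build a genome-wide scope report
#'
#' Aggregates per-gene summaries and annotated protospacers into the
#' targeting-scope report: editable-gene fraction, deduplicated genome-level
#' protospacer total, category fractions and the exact/cumulative
#' distributions of unique protospacers per gene. Fractions are percentages
#' kept at full precision; round only at presentation time.
#'
#' Genome-level `n_protospacers_total` deduplicates physical placements
#' across genes (a 23-mer shared by two overlapping genes counts once);
#' per-gene counts may double-attribute. Category fractions are computed
#' over the deduplicated set of the scanned PAM.
#'
#' @param summaries Output of [summarize_genes()].
#' @param protospacers The annotated protospacer table the summaries came
#'   from.
#' @param pam,window,genome_id Optional metadata echoed into the report
#'   (used by [compare_pams()] to refuse cross-genome comparisons).
#' @return An object of class `scope_report` (a list; see fields in the
#'   source or the JSON written by [write_summary_json()]).
#' @export
build_scope_report <- function(summaries, protospacers, pam = NULL,
                               window = NULL, genome_id = NULL) {
  n_genes <- nrow(summaries)
  n_editable <- sum(summaries$editable)
  uniq <- dedupe_protospacers(protospacers)
  n_total <- nrow(uniq)
  if (n_total) {
    no_motif_le75 <- !uniq$gc_motif_in_window & uniq$gc_percent <= 75
    f_no <- 100 * mean(no_motif_le75)
    f_motif <- 100 * mean(uniq$gc_motif_in_window)
    f_gt75 <- 100 * mean(uniq$gc_percent > 75)
  } else f_no <- f_motif <- f_gt75 <- NA_real_
  ks <- summaries$n_unique_protospacers
  kmax <- max(ks, 1L)
  per_k_exact <- vapply(1:kmax, function(k) sum(ks == k), integer(1))
  per_k_cum <- vapply(1:kmax, function(k) sum(ks >= k), integer(1))
  structure(list(
    genome_id = genome_id,
    pam = if (inherits(pam, "pam_spec")) pam$pattern else pam,
    window = if (inherits(window, "editing_window"))
      c(window$first, window$last) else window,
    n_genes = n_genes,
    n_editable = n_editable,
    fraction_editable = if (n_genes) 100 * n_editable / n_genes else NA_real_,
    n_protospacers_total = n_total,
    fraction_no_motif_le75 = f_no,
    fraction_motif = f_motif,
    fraction_gc_gt75 = f_gt75,
    per_k_exact = stats::setNames(as.list(per_k_exact), 1:kmax),
    per_k_cumulative = stats::setNames(as.list(per_k_cum), 1:kmax)
  ), class = "scope_report")
}

#' @export
print.scope_report <- function(x, ...) {
  cat(sprintf("<scope_report> %s PAM %s window %s\n",
              if (is.null(x$genome_id)) "?" else x$genome_id,
              if (is.null(x$pam)) "?" else x$pam,
              if (is.null(x$window)) "?" else paste(x$window, collapse = "-")))
  cat(sprintf("  genes: %d; editable: %d (%.2f%%)\n",
              x$n_genes, x$n_editable, x$fraction_editable))
  cat(sprintf("  protospacers (dedup): %d\n", x$n_protospacers_total))
  if (!is.na(x$fraction_no_motif_le75))
    cat(sprintf("  no motif & GC<=75%%: %.2f%%; GC motif: %.2f%%; GC>75%%: %.2f%%\n",
                x$fraction_no_motif_le75, x$fraction_motif,
                x$fraction_gc_gt75))
  invisible(x)
}

#' Compare two PAM specifications on the same genome
#'
#' Pairs the headline metrics of two scope reports (typically NGG vs NGN)
#' and their differences. Because every NGG PAM is an NGN PAM, the broader
#' specification can never reach fewer genes; a violation indicates
#' inconsistent inputs and is reported.
#'
#' @param report_a,report_b [build_scope_report()] outputs computed on the
#'   same genome with the same window; `report_b` is the broader PAM.
#' @return Data.frame with columns `metric`, values for both reports, and
#'   `difference` (b - a), plus attribute `monotonic` (TRUE when the broader
#'   PAM dominates).
#' @export
compare_pams <- function(report_a, report_b) {
  if (!identical(report_a$genome_id, report_b$genome_id))
    stop("scope reports come from different genomes: ",
         report_a$genome_id, " vs ", report_b$genome_id)
  if (!identical(report_a$window, report_b$window))
    stop("scope reports use different editing windows")
  metrics <- c("n_genes", "n_editable", "fraction_editable",
               "n_protospacers_total")
  a <- vapply(metrics, function(m) as.numeric(report_a[[m]]), numeric(1))
  b <- vapply(metrics, function(m) as.numeric(report_b[[m]]), numeric(1))
  out <- data.frame(metric = metrics,
                    a = a, b = b, difference = b - a,
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- c(if (is.null(report_a$pam)) "a" else report_a$pam,
                       if (is.null(report_b$pam)) "b" else report_b$pam)
  mono <- report_b$fraction_editable >= report_a$fraction_editable
  if (!is.na(mono) && !mono)
    warning("broader PAM reaches fewer editable genes than the narrower ",
            "one; inputs are inconsistent")
  attr(out, "monotonic") <- mono
  out
}
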