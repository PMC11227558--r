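# Whole-genome reproduction of the published targeting-scope analysis:
# scan every non-partial CDS of an annotated reference genome with the
# NGG and NGN PAM specifications and the 4-8 editing window, and pair the
# resulting scope reports.

#' Run the full targeting-scope analysis on a reference genome
#'
#' Reads a GenBank flatfile (for example the *S. coelicolor* M145
#' chromosome, accession NC_003888.3), scans all non-partial CDS features
#' with the requested window under both PAM specifications, and returns the
#' two scope reports plus their comparison. With the defaults this is the
#' genome-wide analysis whose headline numbers are the editable-gene
#' percentages, accumulated deduplicated protospacer totals, counts of
#' genes with at least ten unique protospacers, and the three GC/motif
#' category fractions per PAM.
#'
#' @param genbank_path Path to the GenBank flatfile with CDS features.
#' @param pams Character vector of two PAM patterns, narrow first.
#' @param window An [editing_window()] (default 4-8).
#' @return List with `reports` (one [build_scope_report()] per PAM, named
#'   by pattern), `comparison` (from [compare_pams()]) and `n_genes`.
#' @export
reproduce_reference_scan <- function(genbank_path, pams = c("NGG", "NGN"),
                                     window = editing_window(4, 8)) {
  gin <- read_genbank(genbank_path)
  genes <- unique(gin$cds$gene_id[!gin$cds$partial])
  gid <- paste(vapply(gin$genomes, `[[`, "", "contig_id"), collapse = ",")
  reports <- lapply(pams, function(p) {
    guides <- scan_genome(gin$genomes, gin$cds, pam_spec(p), window)
    build_scope_report(summarize_genes(guides, genes), guides,
                       pam = pam_spec(p), window = window, genome_id = gid)
  })
  names(reports) <- pams
  list(reports = reports,
       comparison = compare_pams(reports[[1]], reports[[2]]),
       n_genes = length(genes))
}
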