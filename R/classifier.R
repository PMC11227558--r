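# Sequence-context annotation of protospacers: the features that explain
# editing efficiency differences between rAPOBEC1- and hAPOBEC3A-based
# editors on GC-rich templates.

#' GC content of 20-mer spacers
#'
#' @param spacer Character vector of 20-mers over \{A,C,G,T\}.
#' @return Numeric vector, `100 * (#G + #C) / 20`.
#' @export
gc_content <- function(spacer) {
  if (any(nchar(spacer) != 20L))
    stop("spacer must be a 20-mer")
  gc <- nchar(gsub("[^GCgc]", "", spacer))
  100 * gc / 20
}

#' GC-motif presence in the editing window
#'
#' A spacer has the motif iff some position `p` in the window carries a C
#' whose 5' neighbour (position `p - 1`) is G. Only the C must lie inside
#' the window; the G may sit at `window$first - 1`. Position 1 never
#' qualifies (it has no 5' neighbour within the spacer). The deaminase
#' reads the 5' context of the edited C, hence this asymmetric definition;
#' it is isolated here so the stricter both-in-window variant is a one-line
#' change.
#'
#' @param spacer Character vector of 20-mers.
#' @param window An [editing_window()].
#' @return Logical vector.
#' @export
has_gc_motif <- function(spacer, window) {
  stopifnot(inherits(window, "editing_window"))
  ps <- window$first:window$last
  ps <- ps[ps >= 2L]
  if (!length(ps)) return(rep(FALSE, length(spacer)))
  out <- rep(FALSE, length(spacer))
  for (p in ps) {
    out <- out | (substring(spacer, p, p) == "C" &
                    substring(spacer, p - 1L, p - 1L) == "G")
  }
  out
}

#' Count bystander Cs in the editing window
#'
#' Number of window positions other than the target C that carry a C; these
#' are candidates for unwanted co-editing.
#'
#' @param spacer Character vector of 20-mers.
#' @param window An [editing_window()].
#' @param target_c_pos Integer vector (recycled), the target C's spacer
#'   position; must lie in the window and carry a C.
#' @return Integer vector of counts.
#' @export
bystander_c_count <- function(spacer, window, target_c_pos) {
  stopifnot(inherits(window, "editing_window"))
  n <- max(length(spacer), length(target_c_pos))
  spacer <- rep_len(spacer, n); tpos <- rep_len(target_c_pos, n)
  if (any(tpos < window$first | tpos > window$last))
    stop("target_c_pos outside the editing window")
  if (any(substring(spacer, tpos, tpos) != "C"))
    stop("spacer does not carry a C at target_c_pos")
  ps <- window$first:window$last
  counts <- integer(n)
  for (p in ps) {
    counts <- counts + as.integer(substring(spacer, p, p) == "C" & p != tpos)
  }
  counts
}

#' PAM class of a 3-mer
#'
#' `NGA`/`NGT`/`NGC`/`NGG` when the middle base is G, otherwise `"other"`.
#'
#' @param pam Character vector of 3-mers.
#' @return Character vector of classes.
#' @export
pam_class <- function(pam) {
  if (any(nchar(pam) != 3L)) stop("PAM must be a 3-mer")
  ifelse(substring(pam, 2L, 2L) == "G" &
           substring(pam, 3L, 3L) %in% c("A", "C", "G", "T"),
         paste0("NG", substring(pam, 3L, 3L)), "other")
}

#' Annotate protospacers with sequence-context features
#'
#' Adds `gc_percent`, `gc_motif_in_window`, `bystander_c_count` and
#' `pam_class` columns to a protospacer table.
#'
#' @param protospacers Protospacer table from the scanner.
#' @param window The [editing_window()] the scan used.
#' @return The table with annotation columns appended.
#' @export
annotate_protospacers <- function(protospacers, window) {
  if (nrow(protospacers) == 0L) {
    protospacers$gc_percent <- numeric(0)
    protospacers$gc_motif_in_window <- logical(0)
    protospacers$bystander_c_count <- integer(0)
    protospacers$pam_class <- character(0)
    return(protospacers)
  }
  protospacers$gc_percent <- gc_content(protospacers$spacer)
  protospacers$gc_motif_in_window <- has_gc_motif(protospacers$spacer, window)
  protospacers$bystander_c_count <-
    bystander_c_count(protospacers$spacer, window, protospacers$target_c_pos)
  protospacers$pam_class <- pam_class(protospacers$pam)
  protospacers
}
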