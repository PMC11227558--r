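# Sequence utilities shared across modules. Internal alphabet is strict
# uppercase {A,C,G,T,N}; everything else is coerced to N on ingestion.

#' IUPAC degenerate nucleotide sets
#'
#' Named list mapping each IUPAC nucleotide code to the set of concrete bases
#' it stands for (N = ACGT, D = AGT, R = AG, Y = CT, ...).
#'
#' @format Named list of character vectors.
#' @keywords internal
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# logical lookup matrix: rows = pattern code, cols = concrete base
.iupac_matrix <- local({
  codes <- names(IUPAC_SETS)
  m <- matrix(FALSE, length(codes), 4,
              dimnames = list(codes, c("A", "C", "G", "T")))
  for (cd in codes) m[cd, IUPAC_SETS[[cd]]] <- TRUE
  m
})

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences over \{A,C,G,T,N\}.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("TCACTGCAT")
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Positionwise IUPAC pattern match
#'
#' Tests whether each concrete sequence matches a degenerate IUPAC pattern of
#' the same length, position by position. A sequence containing N never
#' matches (an undefined base cannot be guaranteed to match).
#'
#' @param seqs Character vector of concrete sequences (A/C/G/T, possibly N).
#' @param pattern Single IUPAC string; must have the same nchar as every
#'   element of `seqs`.
#' @return Logical vector.
#' @export
iupac_match <- function(seqs, pattern) {
  stopifnot(length(pattern) == 1L)
  pat <- strsplit(toupper(pattern), "")[[1]]
  if (!all(pat %in% rownames(.iupac_matrix)))
    stop("invalid IUPAC code in pattern: ", pattern)
  n <- length(pat)
  if (length(seqs) == 0L) return(logical(0))
  if (any(nchar(seqs) != n))
    stop("sequence length does not match pattern length ", n)
  sm <- matrix(unlist(strsplit(toupper(seqs), ""), use.names = FALSE),
               nrow = n)
  ok <- rep(TRUE, length(seqs))
  for (i in seq_len(n)) {
    base <- sm[i, ]
    hit <- base %in% c("A", "C", "G", "T")
    hit[hit] <- .iupac_matrix[pat[i], base[hit]]
    ok <- ok & hit
  }
  ok
}

#' Match a protospacer+PAM 23-mer against an experimental-design pattern
#'
#' Positionwise IUPAC membership test used to restrict scanner output to a
#' fixed sequence architecture (for example the 16-site design pattern
#' `NNDDTCDDDNNNNNNNNNNNCGN`, where D = A/G/T).
#'
#' @param x Character vector of 23-mers (20-nt spacer + 3-nt PAM).
#' @param pattern IUPAC string of length 23.
#' @return Logical vector, one element per input 23-mer.
#' @examples
#' match_pattern("AAGATCAGAAAAAAAAAAAACGG", "NNDDTCDDDNNNNNNNNNNNCGN")
#' @export
match_pattern <- function(x, pattern) {
  if (nchar(pattern) != 23L)
    stop("pattern must have length 23, got ", nchar(pattern))
  if (any(nchar(x) != 23L))
    stop("protospacer+PAM strings must have length 23")
  iupac_match(x, pattern)
}

# sanitize a raw sequence string: uppercase, non-ACGTN -> N with one warning
.clean_seq <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0L) {
    warning(sprintf("%s: %d non-ACGTN character(s) converted to N",
                    what, nchar(bad)))
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  seq
}

# vectorized substring on one big string; returns NA where out of range
# handled upstream (callers must pass valid coordinates)
.slices <- function(seq, start0, width) {
  if (length(start0) == 0L) return(character(0))
  substring(seq, start0 + 1L, start0 + width)
}
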