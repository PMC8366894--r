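# IUPAC nucleotide code helpers shared across modules.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand an IUPAC code to the set of concrete bases it covers
#'
#' @param code Single IUPAC nucleotide letter.
#' @return Character vector of bases from `{A,C,G,T}`.
#' @export
iupac_bases <- function(code) {
  out <- .IUPAC_SETS[[toupper(code)]]
  if (is.null(out)) stop("not an IUPAC nucleotide code: ", code)
  out
}

#' Smallest IUPAC code covering a set of bases
#'
#' @param bases Character vector over `{A,C,G,T}` (duplicates allowed).
#' @return Single IUPAC letter.
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (length(bases) == 0 || !all(bases %in% c("A", "C", "G", "T")))
    stop("bases must be drawn from {A,C,G,T}")
  for (code in names(.IUPAC_SETS)) {
    s <- .IUPAC_SETS[[code]]
    if (length(s) == length(bases) && all(s == bases)) return(code)
  }
  stop("unreachable")
}

#' Do two IUPAC codes share at least one concrete base?
#' @param a,b Single IUPAC letters.
#' @return Logical.
#' @export
iupac_compatible <- function(a, b) {
  length(intersect(iupac_bases(a), iupac_bases(b))) > 0
}

#' Reverse complement of a DNA string (IUPAC-aware)
#' @param x Character scalar over the IUPAC alphabet.
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# split a sequence string into a character vector of single bases
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.collapse <- function(x) paste(x, collapse = "")

# uniform random DNA of length n under the current RNG stream
.random_dna <- function(n) .collapse(sample(c("A", "C", "G", "T"), n, replace = TRUE))
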