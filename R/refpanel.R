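# Locus reference panels, pairwise alignment, identity and diagnostic sites.
#
# All coordinates are 0-based, intervals half-open. The two species are
# referred to throughout by the labels used on herbarium determinations:
# "advena" (Pennisetum advena) and "setaceum" (P. setaceum).

.LOCI <- c("rbcL", "trnH-psbA", "ITS")
.SPECIES <- c("advena", "setaceum")

#' Default alignment scoring scheme
#'
#' Global end-to-end alignment with match +1, mismatch -1, gap open -3 and
#' gap extend -1 (a gap of length L costs 3 + L). The penalties are steep
#' enough that near-identical barcode amplicons align gaplessly unless an
#' indel is real.
#'
#' @return Named list with elements `match`, `mismatch`, `gap_open`,
#'   `gap_extend`.
#' @export
alignment_scoring <- function() {
  list(match = 1L, mismatch = -1L, gap_open = -3L, gap_extend = -1L)
}

#' Construct a locus reference sequence
#'
#' A named haplotype for one locus, species and (optionally) intra-specific
#' variant, e.g. ITS variant I of *P. advena* ("aI" in report shorthand).
#'
#' @param locus One of `"rbcL"`, `"trnH-psbA"`, `"ITS"`.
#' @param species `"advena"` or `"setaceum"`.
#' @param variant `NULL`, `"I"` or `"II"`.
#' @param sequence DNA string over `{A,C,G,T}`; no ambiguity codes.
#' @return Object of class `locus_reference`.
#' @export
locus_reference <- function(locus, species, variant = NULL, sequence) {
  locus <- match.arg(locus, .LOCI)
  species <- match.arg(species, .SPECIES)
  if (!is.null(variant)) variant <- match.arg(variant, c("I", "II"))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("reference sequence must be non-empty")
  if (grepl("[^ACGT]", sequence))
    stop("reference sequence may only contain A, C, G, T")
  structure(
    list(locus = locus, species = species, variant = variant,
         sequence = sequence),
    class = "locus_reference")
}

#' @export
print.locus_reference <- function(x, ...) {
  cat(sprintf("<locus_reference> %s  (%d nt)\n", ref_id(x), nchar(x$sequence)))
  invisible(x)
}

#' Identifier of a locus reference ("locus|species|variant")
#' @param ref A `locus_reference`.
#' @return Character scalar; the variant part is omitted when absent.
#' @export
ref_id <- function(ref) {
  stopifnot(inherits(ref, "locus_reference"))
  if (is.null(ref$variant)) paste(ref$locus, ref$species, sep = "|")
  else paste(ref$locus, ref$species, ref$variant, sep = "|")
}

#' Bundle locus references into a panel
#'
#' @param ... `locus_reference` objects (or a single list of them).
#' @return Object of class `locus_panel`: a list keyed by [ref_id()].
#' @export
locus_panel <- function(...) {
  refs <- list(...)
  if (length(refs) == 1 && !inherits(refs[[1]], "locus_reference"))
    refs <- refs[[1]]
  ids <- vapply(refs, ref_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate (locus, species, variant) in panel: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  names(refs) <- ids
  structure(refs, class = "locus_panel")
}

#' @export
print.locus_panel <- function(x, ...) {
  cat("<locus_panel> with", length(x), "references:\n")
  for (id in names(x)) cat(" ", id, sprintf("(%d nt)\n", nchar(x[[id]]$sequence)))
  invisible(x)
}

#' Look up one reference in a panel
#'
#' @param panel A `locus_panel`.
#' @param locus,species,variant Identify the reference; when `variant` is
#'   `NULL` and only variant-labelled references exist for the combination,
#'   variant `"I"` is returned (the panel's canonical haplotype).
#' @return A `locus_reference`.
#' @export
panel_ref <- function(panel, locus, species, variant = NULL) {
  stopifnot(inherits(panel, "locus_panel"))
  key <- if (is.null(variant)) paste(locus, species, sep = "|")
         else paste(locus, species, variant, sep = "|")
  if (!is.null(panel[[key]])) return(panel[[key]])
  if (is.null(variant)) {
    key <- paste(locus, species, "I", sep = "|")
    if (!is.null(panel[[key]])) return(panel[[key]])
  }
  stop("no such reference in panel: ", key)
}

#' Read / write a reference panel as FASTA
#'
#' Record IDs use the `"locus|species|variant"` convention (variant omitted
#' when absent).
#'
#' @param path FASTA file path.
#' @return `read_panel_fasta()` a `locus_panel`; `write_panel_fasta()` the
#'   path, invisibly.
#' @export
read_panel_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  refs <- lapply(seq_along(seqs), function(i) {
    parts <- strsplit(names(seqs)[i], "|", fixed = TRUE)[[1]]
    if (!length(parts) %in% 2:3)
      stop("malformed panel record ID: ", names(seqs)[i])
    locus_reference(parts[1], parts[2],
                    variant = if (length(parts) == 3) parts[3] else NULL,
                    sequence = as.character(seqs[[i]]))
  })
  locus_panel(refs)
}

#' @rdname read_panel_fasta
#' @param panel A `locus_panel`.
#' @export
write_panel_fasta <- function(panel, path) {
  stopifnot(inherits(panel, "locus_panel"))
  seqs <- Biostrings::DNAStringSet(
    vapply(panel, function(r) r$sequence, character(1)))
  names(seqs) <- names(panel)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

.check_dna_input <- function(x, what) {
  if (!is.character(x) || length(x) != 1 || !nzchar(x))
    stop(what, " must be a non-empty DNA string")
  if (grepl("[^ACGT]", x))
    stop(what, " may only contain A, C, G, T")
  x
}

#' Optimal global pairwise alignment
#'
#' End-to-end affine-gap alignment under [alignment_scoring()]. Ties between
#' co-optimal alignments are resolved deterministically, preferring a
#' substitution over a gap.
#'
#' @param a,b DNA strings over `{A,C,G,T}`.
#' @param scoring Scoring scheme, see [alignment_scoring()].
#' @return Object of class `pairwise_alignment`: list with gapped strings
#'   `a` and `b` (equal length) and the alignment `score`.
#' @examples
#' align_pair("ACGT", "AGT")
#' @export
align_pair <- function(a, b, scoring = alignment_scoring()) {
  a <- .check_dna_input(toupper(a), "a")
  b <- .check_dna_input(toupper(b), "b")
  res <- cpp_align(a, b, scoring$match, scoring$mismatch,
                   -scoring$gap_open, -scoring$gap_extend,
                   mode = 0L, iupac = FALSE)
  structure(list(a = res$a, b = res$b, score = res$score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score", x$score, "\n")
  cat(" ", x$a, "\n ", x$b, "\n")
  invisible(x)
}

# strip alignment columns belonging to leading/trailing single-sequence
# overhangs; returns the retained column range (or NULL if none)
.core_columns <- function(ca, cb) {
  gap <- ca == "-" | cb == "-"
  first <- which(!gap)[1]
  if (is.na(first)) return(NULL)
  last <- max(which(!gap))
  # leading run of gapped columns before `first`, trailing after `last`
  c(first, last)
}

#' Percent identity of two sequences
#'
#' Computed from the global alignment of [align_pair()]. The denominator is
#' every alignment column after stripping leading/trailing gap-only
#' overhangs; internal gap columns count as compared and non-matching.
#'
#' @inheritParams align_pair
#' @return Object of class `pairwise_identity`: list with
#'   `percent_identity` (0-100), `matches` and `compared_columns`.
#' @export
pairwise_identity <- function(a, b, scoring = alignment_scoring()) {
  aln <- align_pair(a, b, scoring)
  ca <- .chars(aln$a); cb <- .chars(aln$b)
  rng <- .core_columns(ca, cb)
  if (is.null(rng)) stop("alignment has no aligned columns")
  keep <- seq(rng[1], rng[2])
  matches <- sum(ca[keep] == cb[keep] & ca[keep] != "-")
  compared <- length(keep)
  structure(list(percent_identity = 100 * matches / compared,
                 matches = matches, compared_columns = compared),
            class = "pairwise_identity")
}

#' @export
print.pairwise_identity <- function(x, ...) {
  cat(sprintf("<pairwise_identity> %.2f%% (%d/%d columns)\n",
              x$percent_identity, x$matches, x$compared_columns))
  invisible(x)
}

#' Diagnostic sites separating the two species at one locus
#'
#' Aligns the two references globally and returns every column at which they
#' differ (substitution or gap). These are the fixed inter-specific
#' differences used for haplotype assignment: 2 on rbcL and 4 on trnH-psbA
#' for the *P. advena* / *P. setaceum* pair.
#'
#' @param ref_a,ref_s `locus_reference`s for the same locus and different
#'   species; `ref_a` gives the `allele_a` column, `ref_s` the `allele_s`.
#' @param scoring See [alignment_scoring()].
#' @return Object of class `diagnostic_sites`: data.frame with columns
#'   `column` (0-based alignment column), `allele_a`, `allele_s` (base or
#'   `"-"`), `pos_a`, `pos_s` (0-based position in the respective ungapped
#'   reference; `NA` for a gap allele). Attributes: `locus`,
#'   `alignment_length`.
#' @export
diagnostic_sites <- function(ref_a, ref_s, scoring = alignment_scoring()) {
  stopifnot(inherits(ref_a, "locus_reference"), inherits(ref_s, "locus_reference"))
  if (ref_a$locus != ref_s$locus)
    stop("references are from different loci: ", ref_a$locus, " vs ", ref_s$locus)
  if (ref_a$species == ref_s$species)
    stop("references must be from different species")
  aln <- align_pair(ref_a$sequence, ref_s$sequence, scoring)
  ca <- .chars(aln$a); cb <- .chars(aln$b)
  pos_a <- cumsum(ca != "-") - 1L; pos_a[ca == "-"] <- NA_integer_
  pos_s <- cumsum(cb != "-") - 1L; pos_s[cb == "-"] <- NA_integer_
  diff <- which(ca != cb)
  out <- data.frame(column = diff - 1L,
                    allele_a = ca[diff], allele_s = cb[diff],
                    pos_a = pos_a[diff], pos_s = pos_s[diff],
                    stringsAsFactors = FALSE)
  # orient alleles by species, not argument order
  if (ref_a$species == "setaceum")
    out <- data.frame(column = out$column, allele_a = out$allele_s,
                      allele_s = out$allele_a, pos_a = out$pos_s,
                      pos_s = out$pos_a, stringsAsFactors = FALSE)
  structure(out, locus = ref_a$locus, alignment_length = length(ca),
            class = c("diagnostic_sites", "data.frame"))
}

#' Divergence summary of a reference panel
#'
#' Recomputes, from the panel alone, the inter- and intra-specific
#' differences that discriminate the two species: diagnostic site counts on
#' the chloroplast loci, ITS percent identity between species, and SNP
#' counts between intra-specific ITS variants.
#'
#' @param panel A `locus_panel` containing both species at all three loci
#'   (ITS with variants I/II per species where available).
#' @return Named list: `rbcl_diagnostic_sites`, `trnh_diagnostic_sites`,
#'   `its_percent_identity`, `advena_its_variant_snps`,
#'   `setaceum_its_variant_snps` (the variant SNP entries are `NA` when the
#'   panel lacks variant-II references).
#' @export
compare_reference_panel <- function(panel) {
  stopifnot(inherits(panel, "locus_panel"))
  rb <- diagnostic_sites(panel_ref(panel, "rbcL", "advena"),
                         panel_ref(panel, "rbcL", "setaceum"))
  tr <- diagnostic_sites(panel_ref(panel, "trnH-psbA", "advena"),
                         panel_ref(panel, "trnH-psbA", "setaceum"))
  ai <- panel_ref(panel, "ITS", "advena", "I")
  si <- panel_ref(panel, "ITS", "setaceum", "I")
  its_id <- pairwise_identity(ai$sequence, si$sequence)
  snps <- function(sp) {
    v2 <- tryCatch(panel_ref(panel, "ITS", sp, "II"), error = function(e) NULL)
    if (is.null(v2)) return(NA_integer_)
    v1 <- panel_ref(panel, "ITS", sp, "I")
    aln <- align_pair(v1$sequence, v2$sequence)
    sum(.chars(aln$a) != .chars(aln$b))
  }
  list(rbcl_diagnostic_sites = nrow(rb),
       trnh_diagnostic_sites = nrow(tr),
       its_percent_identity = its_id$percent_identity,
       advena_its_variant_snps = snps("advena"),
       setaceum_its_variant_snps = snps("setaceum"))
}
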