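# Sanger read processing: quality trimming, primer trimming and
# bidirectional consensus assembly with IUPAC ambiguity handling.

#' A quality-annotated Sanger read
#'
#' @param bases String over the IUPAC nucleotide alphabet (may be empty).
#' @param qualities Integer PHRED scores, one per base, each in `[0, 93]`.
#' @param direction `"forward"` or `"reverse"` (sequencing direction).
#' @return Object of class `quality_read`.
#' @export
quality_read <- function(bases, qualities, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  bases <- toupper(bases)
  qualities <- as.integer(qualities)
  if (nchar(bases) != length(qualities))
    stop("bases and qualities must have equal length")
  if (nzchar(bases) && grepl(sprintf("[^%s]", paste(names(.IUPAC_SETS), collapse = "")), bases))
    stop("bases must be IUPAC nucleotide letters")
  if (length(qualities) && (min(qualities) < 0 || max(qualities) > 93))
    stop("qualities must be PHRED scores in [0, 93]")
  structure(list(bases = bases, qualities = qualities, direction = direction),
            class = "quality_read")
}

#' @export
print.quality_read <- function(x, ...) {
  cat(sprintf("<quality_read> %s, %d nt, median Q%s\n", x$direction,
              nchar(x$bases),
              if (length(x$qualities)) stats::median(x$qualities) else "-"))
  invisible(x)
}

#' @export
length.quality_read <- function(x) nchar(x$bases)

.subset_read <- function(read, idx) {
  quality_read(.collapse(.chars(read$bases)[idx]), read$qualities[idx],
               read$direction)
}

#' Quality-trim a Sanger read
#'
#' Retains the longest contiguous run in which every sliding window of
#' `window` bases has mean quality above `floor`, then refines the run's
#' edges by dropping boundary bases whose own quality is at or below the
#' floor. Runs shorter than the window are judged by their overall mean.
#' An empty result is valid (a read with no high-quality stretch).
#'
#' @param read A [quality_read()].
#' @param floor PHRED floor (default 30, i.e. the high-quality target).
#' @param window Sliding window width in bases.
#' @return A trimmed [quality_read()]; attribute `span` holds the retained
#'   0-based half-open interval on the input read.
#' @export
trim_quality <- function(read, floor = 30, window = 10) {
  stopifnot(inherits(read, "quality_read"), window >= 1)
  q <- read$qualities
  n <- length(q)
  empty <- function() structure(.subset_read(read, integer(0)), span = c(0L, 0L))
  if (n == 0) return(empty())
  if (n < window) {
    if (mean(q) > floor) return(structure(read, span = c(0L, n)))
    return(empty())
  }
  wm <- stats::filter(q, rep(1 / window, window), sides = 1)[window:n]
  good <- wm > floor  # window starting at position i has mean > floor
  if (!any(good)) return(empty())
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  lo <- starts[best]; hi <- ends[best] + window - 1
  while (lo <= hi && q[lo] <= floor) lo <- lo + 1
  while (hi >= lo && q[hi] <= floor) hi <- hi - 1
  if (lo > hi) return(empty())
  structure(.subset_read(read, lo:hi), span = c(lo - 1L, hi))
}

# IUPAC-aware Hamming distance of two equal-length base vectors
.iupac_mismatches <- function(x, y) {
  sum(!mapply(iupac_compatible, x, y))
}

#' Trim amplification primers from a read
#'
#' Removes a read prefix matching any of the two primers or their reverse
#' complements with at most `max_mismatch` mismatches (IUPAC-aware), and
#' likewise a suffix. No internal edits; an unmatched read is returned
#' unchanged.
#'
#' @param read A [quality_read()].
#' @param fwd_primer,rev_primer Primer sequences (IUPAC allowed).
#' @param max_mismatch Mismatch tolerance per primer match.
#' @return A [quality_read()].
#' @export
trim_primers <- function(read, fwd_primer, rev_primer, max_mismatch = 2) {
  stopifnot(inherits(read, "quality_read"))
  if (!nzchar(fwd_primer) || !nzchar(rev_primer))
    stop("primers must be non-empty")
  cands <- unique(toupper(c(fwd_primer, rev_primer,
                            revcomp(fwd_primer), revcomp(rev_primer))))
  ch <- .chars(read$bases)
  n <- length(ch)
  # prefix
  cut_lo <- 0L
  for (p in cands[order(-nchar(cands))]) {
    k <- nchar(p)
    if (n >= k && .iupac_mismatches(ch[1:k], .chars(p)) <= max_mismatch) {
      cut_lo <- k; break
    }
  }
  # suffix
  cut_hi <- 0L
  for (p in cands[order(-nchar(cands))]) {
    k <- nchar(p)
    if (n - cut_lo >= k &&
        .iupac_mismatches(ch[(n - k + 1):n], .chars(p)) <= max_mismatch) {
      cut_hi <- k; break
    }
  }
  idx <- if (cut_lo + cut_hi >= n) integer(0) else (cut_lo + 1L):(n - cut_hi)
  .subset_read(read, idx)
}

#' IUPAC-coded consensus from a bidirectional Sanger read pair
#'
#' Reverse-complements the reverse read, aligns it to the forward read
#' (ends-free, IUPAC-compatible scoring) and merges per overlap column:
#' identical calls are kept with summed quality (capped at 93); calls whose
#' base sets overlap are merged into the covering IUPAC code; disagreeing
#' concrete calls take the higher-quality base when the quality gap reaches
#' `quality_gap`, otherwise the IUPAC code covering both. Non-overlapping
#' flanks are retained at single-strand quality. Assembly fails — the
#' empty consensus with status `"failed_assembly"` — when either input is
#' empty, the overlap is shorter than `min_overlap` columns, or overlap
#' identity falls below `min_identity` (the behaviour of a trace pair from
#' a template population segregating for an indel).
#'
#' @param fwd,rev [quality_read()]s, already quality- and primer-trimmed.
#' @param min_overlap Minimum overlap columns for a valid assembly.
#' @param min_identity Minimum fraction of compatible overlap columns.
#' @param quality_gap PHRED difference letting one strand override the
#'   other at a disagreeing column.
#' @param floor Consensus edge positions below this quality are trimmed.
#' @param scoring See [alignment_scoring()].
#' @return Object of class `consensus_sequence`: list with `bases`,
#'   `qualities`, `trimmed_span` (0-based half-open, on the merged
#'   coordinate system) and `status` (`"ok"` or `"failed_assembly"`).
#' @export
assemble_bidirectional <- function(fwd, rev, min_overlap = 50,
                                   min_identity = 0.8, quality_gap = 10,
                                   floor = 30,
                                   scoring = alignment_scoring()) {
  stopifnot(inherits(fwd, "quality_read"), inherits(rev, "quality_read"))
  failed <- function() structure(
    list(bases = "", qualities = integer(0), trimmed_span = c(0L, 0L),
         status = "failed_assembly"), class = "consensus_sequence")
  if (!nzchar(fwd$bases) || !nzchar(rev$bases)) return(failed())
  rc_b <- revcomp(rev$bases)
  rc_q <- rev(rev$qualities)
  aln <- cpp_align(fwd$bases, rc_b, scoring$match, scoring$mismatch,
                   -scoring$gap_open, -scoring$gap_extend,
                   mode = 1L, iupac = TRUE)
  ca <- .chars(aln$a); cb <- .chars(aln$b)
  qa <- qb <- rep(NA_integer_, length(ca))
  qa[ca != "-"] <- fwd$qualities
  qb[cb != "-"] <- rc_q
  both <- ca != "-" & cb != "-"
  if (sum(both) < min_overlap) return(failed())
  comp <- mapply(iupac_compatible, ca[both], cb[both])
  if (mean(comp) < min_identity) return(failed())
  n <- length(ca)
  bases <- character(n); quals <- integer(n)
  for (i in seq_len(n)) {
    if (ca[i] == "-") { bases[i] <- cb[i]; quals[i] <- qb[i]; next }
    if (cb[i] == "-") { bases[i] <- ca[i]; quals[i] <- qa[i]; next }
    if (ca[i] == cb[i]) {
      bases[i] <- ca[i]; quals[i] <- min(93L, qa[i] + qb[i])
    } else if (iupac_compatible(ca[i], cb[i])) {
      bases[i] <- iupac_code(union(iupac_bases(ca[i]), iupac_bases(cb[i])))
      quals[i] <- as.integer(round((qa[i] + qb[i]) / 2))
    } else if (abs(qa[i] - qb[i]) >= quality_gap) {
      bases[i] <- if (qa[i] >= qb[i]) ca[i] else cb[i]
      quals[i] <- max(qa[i], qb[i])
    } else {
      bases[i] <- iupac_code(union(iupac_bases(ca[i]), iupac_bases(cb[i])))
      quals[i] <- as.integer(round((qa[i] + qb[i]) / 2))
    }
  }
  lo <- 1L; hi <- n
  while (lo <= hi && quals[lo] < floor) lo <- lo + 1L
  while (hi >= lo && quals[hi] < floor) hi <- hi - 1L
  if (lo > hi) return(failed())
  structure(list(bases = .collapse(bases[lo:hi]),
                 qualities = quals[lo:hi],
                 trimmed_span = c(lo - 1L, hi), status = "ok"),
            class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  if (x$status == "failed_assembly") {
    cat("<consensus_sequence> failed_assembly\n")
  } else {
    amb <- sum(!.chars(x$bases) %in% c("A", "C", "G", "T"))
    cat(sprintf("<consensus_sequence> %d nt, %d ambiguous, span [%d, %d)\n",
                nchar(x$bases), amb, x$trimmed_span[1], x$trimmed_span[2]))
  }
  invisible(x)
}

# ---- FASTQ I/O (PHRED+33) ---------------------------------------------------

.phred_string <- function(q) intToUtf8(as.integer(q) + 33L)

#' Write / read a single quality read as FASTQ (PHRED+33)
#'
#' @param read A [quality_read()].
#' @param path FASTQ path.
#' @param id Record identifier.
#' @return The path (write) or a [quality_read()] (read), invisibly/visibly.
#' @export
write_quality_read_fastq <- function(read, path, id = "read") {
  stopifnot(inherits(read, "quality_read"))
  x <- Biostrings::DNAStringSet(read$bases)
  names(x) <- id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(.phred_string(read$qualities)))
  invisible(path)
}

#' @rdname write_quality_read_fastq
#' @param direction Direction to stamp on the read.
#' @export
read_quality_read_fastq <- function(path, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  # Biostrings warns about dropping its own metadata columns here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  q <- as(Biostrings::quality(x), "IntegerList")[[1]]
  quality_read(as.character(x[[1]]), q, direction)
}

#' Write / read a short-read set as FASTQ (PHRED+33)
#'
#' The true template label travels in the record description after a space
#' and is recovered on read-back (simulation bookkeeping only; a mapper
#' never looks at it).
#'
#' @param rs A `read_set` (see [simulate_short_reads()]).
#' @param path FASTQ path.
#' @return The path (write) or a `read_set` (read).
#' @export
write_read_set_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  x <- Biostrings::DNAStringSet(rs$sequence)
  names(x) <- paste(rs$id, rs$label)
  q <- attr(rs, "quality")
  quals <- Biostrings::BStringSet(
    vapply(nchar(rs$sequence),
           function(n) .phred_string(rep(q, n)), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname write_read_set_fastq
#' @export
read_read_set_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  hdr <- names(x)
  id <- sub(" .*$", "", hdr)
  label <- ifelse(grepl(" ", hdr), sub("^[^ ]+ ", "", hdr), NA_character_)
  q <- as(Biostrings::quality(x), "IntegerList")[[1]][1]
  structure(data.frame(id = id, label = label, start = NA_integer_,
                       sequence = as.character(x), stringsAsFactors = FALSE,
                       row.names = NULL),
            quality = as.integer(q), class = c("read_set", "data.frame"))
}

#' Write a consensus sequence as FASTA (ambiguity codes preserved)
#' @param cons A `consensus_sequence`.
#' @param path FASTA path.
#' @param id Record identifier.
#' @export
write_consensus_fasta <- function(cons, path, id = "consensus") {
  stopifnot(inherits(cons, "consensus_sequence"))
  x <- Biostrings::DNAStringSet(cons$bases)
  names(x) <- id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
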