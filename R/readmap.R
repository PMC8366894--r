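# Amplicon read mapping and pileup construction. References are
# amplicon-scale (<= ~1 kb), so every read gets a full semi-global
# placement; no seeding or indexing layer.

#' Map short reads to a locus reference
#'
#' Best semi-global placement (read end-to-end, reference end gaps free)
#' under [alignment_scoring()], with deterministic leftmost tie-breaking.
#' A read is flagged mapped when its aligned identity (matches over
#' alignment columns, gap columns counting against) reaches
#' `min_identity`. Reads shorter than `min_length` are left unmapped with
#' a reason.
#'
#' @param reads A `read_set` (see [simulate_short_reads()]) or character
#'   vector of read sequences.
#' @param reference A `locus_reference` or DNA string.
#' @param min_identity Mapping identity threshold.
#' @param min_length Minimum read length considered mappable.
#' @param scoring See [alignment_scoring()].
#' @return Object of class `read_alignments`: data.frame with columns
#'   `read_id`, `start` (0-based reference offset), `score`, `mismatches`,
#'   `gaps`, `aln_cols`, `identity`, `mapped`, `reason`, `aligned_read`,
#'   `aligned_ref`. Attributes `reference` (sequence) and `ref_len`.
#' @export
map_reads <- function(reads, reference, min_identity = 0.8, min_length = 30,
                      scoring = alignment_scoring()) {
  if (inherits(reference, "locus_reference")) reference <- reference$sequence
  if (inherits(reads, "read_set")) {
    ids <- reads$id; seqs <- reads$sequence
  } else {
    seqs <- as.character(reads)
    ids <- if (!is.null(names(seqs))) names(seqs)
           else sprintf("read%06d", seq_along(seqs))
  }
  short <- nchar(seqs) < min_length
  res <- cpp_map_reads(seqs[!short], reference, scoring$match,
                       scoring$mismatch, -scoring$gap_open,
                       -scoring$gap_extend)
  out <- data.frame(read_id = ids, start = NA_integer_, score = NA_integer_,
                    mismatches = NA_integer_, gaps = NA_integer_,
                    aln_cols = NA_integer_, identity = NA_real_,
                    mapped = FALSE, reason = "", aligned_read = "",
                    aligned_ref = "", stringsAsFactors = FALSE)
  if (any(!short)) {
    idx <- which(!short)
    out$start[idx] <- res$start
    out$score[idx] <- res$score
    out$mismatches[idx] <- res$mismatches
    out$gaps[idx] <- res$gaps
    out$aln_cols[idx] <- res$aln_cols
    ident <- (res$aln_cols - res$mismatches - res$gaps) / res$aln_cols
    out$identity[idx] <- ident
    out$mapped[idx] <- ident >= min_identity
    out$reason[idx] <- ifelse(ident >= min_identity, "",
                              "identity below threshold")
    out$aligned_read[idx] <- res$aligned_read
    out$aligned_ref[idx] <- res$aligned_ref
  }
  out$reason[short] <- sprintf("read shorter than %d nt", min_length)
  structure(out, reference = reference, ref_len = nchar(reference),
            class = c("read_alignments", "data.frame"))
}

#' @rdname map_reads
#' @param read A single read sequence.
#' @export
map_read <- function(read, reference, min_identity = 0.8, min_length = 30,
                     scoring = alignment_scoring()) {
  map_reads(read, reference, min_identity, min_length, scoring)
}

#' Build a per-position pileup from read alignments
#'
#' Each mapped read contributes exactly once per covered reference
#' position. Insertions are recorded against the reference position to
#' their left (half-open, 0-based coordinates); insertions before position
#' 0 are discarded.
#'
#' @param alignments A `read_alignments` object (unmapped rows are
#'   ignored).
#' @param reference Optional override of the alignments' reference.
#' @return Object of class `pileup`: list with `ref` (sequence), `counts`
#'   (5 x L integer matrix, rows `A`, `C`, `G`, `T`, `del`), `insertions`
#'   (data.frame `position`, `sequence`, `count`) and `depth` (base +
#'   deletion counts per position).
#' @export
build_pileup <- function(alignments, reference = NULL) {
  stopifnot(inherits(alignments, "read_alignments"))
  if (is.null(reference)) reference <- attr(alignments, "reference")
  if (inherits(reference, "locus_reference")) reference <- reference$sequence
  ok <- alignments[alignments$mapped, , drop = FALSE]
  L <- nchar(reference)
  res <- cpp_pileup(ok$start, ok$aligned_read, ok$aligned_ref, L)
  counts <- res$counts
  rownames(counts) <- c("A", "C", "G", "T", "del")
  structure(list(ref = reference, counts = counts,
                 insertions = data.frame(position = res$ins_pos,
                                         sequence = as.character(res$ins_seq),
                                         count = res$ins_count,
                                         stringsAsFactors = FALSE),
                 depth = colSums(counts)),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d positions, mean depth %.1f, %d insertion allele(s)\n",
              length(x$depth), mean(x$depth), nrow(x$insertions)))
  invisible(x)
}

#' Export a pileup as delimited text
#' @param p A `pileup`.
#' @param path Output TSV path.
#' @export
write_pileup_tsv <- function(p, path) {
  stopifnot(inherits(p, "pileup"))
  df <- data.frame(position = seq_along(p$depth) - 1L,
                   ref = .chars(p$ref), t(p$counts), depth = p$depth)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export read alignments as delimited text
#'
#' SAM-like dump: `read_id`, `flag` (0 mapped / 4 unmapped), `start`
#' (1-based), `score`, `mismatches`, `gaps`, `identity`, `aligned_read`,
#' `aligned_ref`.
#'
#' @param alignments A `read_alignments`.
#' @param path Output TSV path.
#' @export
write_alignments_tsv <- function(alignments, path) {
  stopifnot(inherits(alignments, "read_alignments"))
  df <- data.frame(read_id = alignments$read_id,
                   flag = ifelse(alignments$mapped, 0L, 4L),
                   start = alignments$start + 1L,
                   score = alignments$score,
                   mismatches = alignments$mismatches,
                   gaps = alignments$gaps,
                   identity = round(alignments$identity, 4),
                   aligned_read = alignments$aligned_read,
                   aligned_ref = alignments$aligned_ref,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
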