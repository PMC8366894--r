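# Variant detection from pileups and intra-individual ITS variant mixture
# deconvolution — the computational core of the identification method.

#' Detect variants from a pileup
#'
#' A call is emitted for every non-reference allele (substitution,
#' deletion, or insertion) that simultaneously meets the depth, count and
#' frequency thresholds. The frequency floor of 0.05 keeps minority ITS
#' variants down to ~15% comfortably detectable while suppressing
#' sequencing error at rates up to ~1%.
#'
#' @param p A `pileup`.
#' @param min_depth Minimum depth at the position.
#' @param min_count Minimum supporting read count.
#' @param min_freq Minimum allele frequency (count / depth).
#' @return Object of class `variant_calls`: data.frame with columns
#'   `position` (0-based), `ref`, `alt` (base, `"-"` for a deletion, or
#'   the inserted sequence), `kind` (`SNV`/`deletion`/`insertion`),
#'   `count`, `depth`, `frequency`; sorted by position then allele.
#' @export
detect_variants <- function(p, min_depth = 10, min_count = 2,
                            min_freq = 0.05) {
  stopifnot(inherits(p, "pileup"))
  if (!length(p$depth)) stop("pileup is empty")
  ref <- .chars(p$ref)
  rows <- list()
  for (base in c("A", "C", "G", "T", "del")) {
    cnt <- p$counts[base, ]
    allele <- if (base == "del") "-" else base
    hit <- which(p$depth >= min_depth & cnt >= min_count &
                   cnt / p$depth >= min_freq &
                   ref != allele & cnt > 0)
    if (length(hit))
      rows[[length(rows) + 1]] <- data.frame(
        position = hit - 1L, ref = ref[hit], alt = allele,
        kind = if (base == "del") "deletion" else "SNV",
        count = cnt[hit], depth = p$depth[hit],
        frequency = cnt[hit] / p$depth[hit], stringsAsFactors = FALSE)
  }
  ins <- p$insertions
  if (nrow(ins)) {
    d <- p$depth[ins$position + 1L]
    keep <- d >= min_depth & ins$count >= min_count & ins$count / d >= min_freq
    if (any(keep))
      rows[[length(rows) + 1]] <- data.frame(
        position = ins$position[keep], ref = ref[ins$position[keep] + 1L],
        alt = ins$sequence[keep], kind = "insertion",
        count = ins$count[keep], depth = d[keep],
        frequency = ins$count[keep] / d[keep], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(position = integer(0), ref = character(0),
                         alt = character(0), kind = character(0),
                         count = integer(0), depth = integer(0),
                         frequency = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("variant_calls", "data.frame"))
}

#' Table of sites distinguishing ITS variant haplotypes
#'
#' Aligns every ITS variant reference to the first (the anchor) and
#' returns each anchor position at which at least two labels carry
#' different alleles, with every label's allele. Positions where a label
#' has a gap are flagged. Labels follow report shorthand: `aI`, `aII`,
#' `sI`, `sII`.
#'
#' @param refs List of >= 2 ITS `locus_reference`s (e.g. the ITS entries
#'   of a panel).
#' @return Object of class `informative_sites`: data.frame with column
#'   `pos` (0-based position on the anchor reference), one allele column
#'   per label, and `has_gap`. Attributes: `labels`, `anchor` (the
#'   anchor's label), `anchor_sequence`.
#' @export
informative_sites <- function(refs) {
  refs <- refs[vapply(refs, function(r) inherits(r, "locus_reference"),
                      logical(1))]
  if (length(refs) < 2) stop("need at least two ITS variant references")
  if (any(vapply(refs, function(r) r$locus, character(1)) != "ITS"))
    stop("informative_sites expects ITS references")
  labels <- vapply(refs, function(r)
    paste0(substr(r$species, 1, 1), if (is.null(r$variant)) "I" else r$variant),
    character(1))
  if (anyDuplicated(labels)) stop("duplicate variant labels among references")
  anchor <- refs[[1]]$sequence
  L <- nchar(anchor)
  mat <- matrix("", nrow = L, ncol = length(refs),
                dimnames = list(NULL, labels))
  mat[, 1] <- .chars(anchor)
  for (k in seq_along(refs)[-1]) {
    aln <- align_pair(anchor, refs[[k]]$sequence)
    ca <- .chars(aln$a); cb <- .chars(aln$b)
    proj <- cb[ca != "-"]
    mat[, k] <- proj
  }
  differ <- apply(mat, 1, function(r) length(unique(r)) > 1)
  pos <- which(differ)
  out <- data.frame(pos = pos - 1L, mat[pos, , drop = FALSE],
                    has_gap = apply(mat[pos, , drop = FALSE], 1,
                                    function(r) any(r == "-")),
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  structure(out, labels = labels, anchor = labels[1],
            anchor_sequence = anchor,
            class = c("informative_sites", "data.frame"))
}

#' Deconvolve an intra-individual ITS variant mixture
#'
#' Every mapped read covering at least `min_sites_per_read` informative
#' sites is scored by Hamming distance to each candidate variant
#' restricted to the sites it covers, and votes for the minimum-distance
#' label. A read whose covered sites cannot separate a subset of labels
#' ties among them; tied votes are reallocated proportionally to the vote
#' shares of the unambiguously assigned reads within the tied subset
#' (equal split only when no unambiguous evidence exists), which keeps the
#' estimator consistent as coverage grows. Labels ending below
#' `noise_floor` are dropped and the remaining mass renormalized.
#'
#' @param alignments `read_alignments` of ITS reads mapped to the
#'   informative-site anchor reference.
#' @param info An [informative_sites()] table.
#' @param min_sites_per_read Minimum covered informative sites for a read
#'   to vote.
#' @param noise_floor Minimum retained label proportion.
#' @param specimen_id Identifier carried into the profile.
#' @return Object of class `variant_profile`: list with `specimen_id`,
#'   `proportions` (named, summing to 1), `counts` (fractional assigned
#'   votes per label) and `unassigned` (reads covering no informative
#'   site, plus unmapped reads).
#' @export
deconvolve_its <- function(alignments, info, min_sites_per_read = 1,
                           noise_floor = 0.03, specimen_id = NA_character_) {
  stopifnot(inherits(alignments, "read_alignments"),
            inherits(info, "informative_sites"))
  if (!nrow(info)) stop("informative-site table is empty")
  labels <- attr(info, "labels")
  ok <- alignments[alignments$mapped, , drop = FALSE]
  n_unmapped <- sum(!alignments$mapped)
  empty_profile <- function(unassigned) structure(
    list(specimen_id = specimen_id, proportions = stats::setNames(numeric(0), character(0)),
         counts = stats::setNames(numeric(0), character(0)),
         unassigned = unassigned, flagged = "unassigned"),
    class = "variant_profile")
  if (!nrow(ok)) return(empty_profile(n_unmapped))
  proj <- cpp_project_reads(ok$start, ok$aligned_read, ok$aligned_ref,
                            info$pos)
  covered <- proj != ""
  ncov <- rowSums(covered)
  voting <- ncov >= min_sites_per_read
  if (!any(voting)) return(empty_profile(n_unmapped + nrow(ok)))
  dist <- matrix(0L, nrow = nrow(ok), ncol = length(labels),
                 dimnames = list(NULL, labels))
  for (l in labels) {
    allele <- matrix(rep(info[[l]], each = nrow(ok)), nrow = nrow(ok))
    dist[, l] <- rowSums(covered & proj != allele)
  }
  dist <- dist[voting, , drop = FALSE]
  mind <- apply(dist, 1, min)
  tie_mat <- dist == mind
  n_ties <- rowSums(tie_mat)
  u <- colSums(tie_mat[n_ties == 1, , drop = FALSE])  # unambiguous votes
  names(u) <- labels
  alloc <- as.numeric(u)
  names(alloc) <- labels
  amb <- which(n_ties > 1)
  if (length(amb)) {
    keys <- apply(tie_mat[amb, , drop = FALSE], 1,
                  function(r) paste(which(r), collapse = ","))
    for (key in unique(keys)) {
      members <- labels[as.integer(strsplit(key, ",", fixed = TRUE)[[1]])]
      mass <- sum(keys == key)
      w <- u[members]
      if (sum(w) > 0) w <- w / sum(w) else w <- rep(1 / length(members),
                                                    length(members))
      alloc[members] <- alloc[members] + mass * w
    }
  }
  total <- sum(alloc)
  prop <- alloc / total
  keep <- prop >= noise_floor
  prop <- prop[keep] / sum(prop[keep])
  structure(list(specimen_id = specimen_id, proportions = prop,
                 counts = alloc[keep],
                 unassigned = n_unmapped + sum(!voting), flagged = NULL),
            class = "variant_profile")
}

#' @export
print.variant_profile <- function(x, ...) {
  if (!length(x$proportions)) {
    cat("<variant_profile>", x$specimen_id, " (no assignable reads)\n")
  } else {
    cat(sprintf("<variant_profile> %s: %s  (%d unassigned)\n", x$specimen_id,
                paste(sprintf("%s %.1f%%", names(x$proportions),
                              100 * x$proportions), collapse = ", "),
                x$unassigned))
  }
  invisible(x)
}

#' Detect a segregating indel in a chloroplast pileup
#'
#' Reports an indel mixture whenever an insertion or deletion allele sits
#' at intermediate frequency (within `band`) at adequate depth — the
#' signature of two co-amplified haplotypes differing by a single indel,
#' which defeats bidirectional Sanger sequencing of the locus.
#'
#' @param p A `pileup`.
#' @param min_depth Minimum depth at the indel position.
#' @param band Frequency interval defining "mixed".
#' @return Object of class `indel_mixture_report`: data.frame with
#'   columns `position`, `kind`, `allele`, `freq_with` (haplotype carrying
#'   the indel), `freq_without`, `depth`. Zero rows when no mixture is
#'   present.
#' @export
detect_mixed_indel <- function(p, min_depth = 10, band = c(0.2, 0.8)) {
  stopifnot(inherits(p, "pileup"))
  rows <- list()
  del <- p$counts["del", ]
  f <- ifelse(p$depth > 0, del / pmax(p$depth, 1), 0)
  hit <- which(p$depth >= min_depth & f >= band[1] & f <= band[2] & del > 0)
  for (i in hit)
    rows[[length(rows) + 1]] <- data.frame(
      position = i - 1L, kind = "deletion", allele = "-",
      freq_with = f[i], freq_without = 1 - f[i], depth = p$depth[i],
      stringsAsFactors = FALSE)
  ins <- p$insertions
  if (nrow(ins)) {
    d <- p$depth[ins$position + 1L]
    fi <- ins$count / pmax(d, 1)
    keep <- d >= min_depth & fi >= band[1] & fi <= band[2]
    for (i in which(keep))
      rows[[length(rows) + 1]] <- data.frame(
        position = ins$position[i], kind = "insertion",
        allele = ins$sequence[i], freq_with = fi[i],
        freq_without = 1 - fi[i], depth = d[i], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(position = integer(0), kind = character(0),
                         allele = character(0), freq_with = numeric(0),
                         freq_without = numeric(0), depth = integer(0),
                         stringsAsFactors = FALSE)
  structure(out, class = c("indel_mixture_report", "data.frame"))
}

#' Export variant calls as a minimal VCF
#'
#' CHROM is the locus identifier; positions convert from the package's
#' 0-based convention to VCF's 1-based on write. Deletions and insertions
#' use the conventional anchored representation.
#'
#' @param calls A `variant_calls` table.
#' @param reference The reference sequence the calls refer to.
#' @param locus CHROM value.
#' @param path Output path.
#' @export
write_variant_vcf <- function(calls, reference, locus, path) {
  stopifnot(inherits(calls, "variant_calls"))
  if (inherits(reference, "locus_reference")) reference <- reference$sequence
  ref <- .chars(reference)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", locus, length(ref)),
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Allele count\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(calls))) {
    p <- calls$position[i]
    if (calls$kind[i] == "SNV") {
      pos1 <- p + 1L; REF <- calls$ref[i]; ALT <- calls$alt[i]
    } else if (calls$kind[i] == "deletion") {
      pos1 <- p      # anchor base left of the deleted base, 1-based = p
      if (p == 0) next  # cannot anchor a deletion at position 0 minimally
      REF <- paste0(ref[p], ref[p + 1]); ALT <- ref[p]
    } else { # insertion anchored at `position`
      pos1 <- p + 1L
      REF <- ref[p + 1]; ALT <- paste0(ref[p + 1], calls$alt[i])
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AC=%d;AF=%.4f",
                       locus, pos1, REF, ALT, calls$depth[i],
                       calls$count[i], calls$frequency[i]), con)
  }
  invisible(path)
}

#' Export a variant profile as delimited text
#' @param profile A `variant_profile`.
#' @param path Output TSV path.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "variant_profile"))
  df <- data.frame(specimen_id = profile$specimen_id,
                   label = names(profile$proportions),
                   proportion = as.numeric(profile$proportions),
                   votes = as.numeric(profile$counts),
                   unassigned = profile$unassigned,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
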