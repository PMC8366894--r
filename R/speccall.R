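# Specimen-level integration: chloroplast haplotype assignment at diagnostic
# sites, the species / hybrid / maternal-lineage verdict, an advisory
# morphological range check, and the per-specimen report.

.HAP_LEVELS <- c("a", "s", "mixed", "unresolved")

#' Assign a chloroplast haplotype at diagnostic sites
#'
#' Reads the allele carried at each diagnostic site and returns `"a"` when
#' every resolvable site carries the *P. advena* allele, `"s"`
#' symmetrically, `"mixed"` when any site shows both alleles (an IUPAC
#' code covering both in a consensus, or both alleles at >= `mixed_band`
#' frequency in a pileup), and `"unresolved"` when fewer than half of the
#' sites are resolvable (or the resolved sites conflict).
#'
#' @param x A `consensus_sequence` (or IUPAC DNA string), or a `pileup`
#'   built against the *advena* reference of the locus.
#' @param sites A [diagnostic_sites()] set for the locus.
#' @param ref The *advena* `locus_reference` (or sequence) used to locate
#'   the sites; required for the consensus form.
#' @param min_depth Pileup form: minimum depth for a site to be resolvable.
#' @param mixed_band Pileup form: frequency at which a second allele makes
#'   a site mixed.
#' @return One of `"a"`, `"s"`, `"mixed"`, `"unresolved"`, with attribute
#'   `site_calls` (per-site detail).
#' @export
assign_haplotype <- function(x, sites, ref = NULL, min_depth = 10,
                             mixed_band = 0.2) {
  stopifnot(inherits(sites, "diagnostic_sites"))
  if (nrow(sites) == 0) stop("diagnostic site set is empty")
  if (inherits(x, "pileup")) {
    calls <- .site_calls_pileup(x, sites, min_depth, mixed_band)
  } else {
    seqx <- if (inherits(x, "consensus_sequence")) x$bases else as.character(x)
    if (!nzchar(seqx)) {
      calls <- rep("uncovered", nrow(sites))
    } else {
      if (is.null(ref)) stop("`ref` is required to place a consensus")
      if (inherits(ref, "locus_reference")) ref <- ref$sequence
      calls <- .site_calls_consensus(seqx, sites, ref)
    }
  }
  resolvable <- calls %in% c("a", "s", "both")
  verdict <- if (sum(resolvable) < nrow(sites) / 2) "unresolved"
    else if (any(calls == "both")) "mixed"
    else if (all(calls[resolvable] == "a")) "a"
    else if (all(calls[resolvable] == "s")) "s"
    else "unresolved"  # conflicting fixed differences
  structure(verdict, site_calls = data.frame(pos_a = sites$pos_a,
                                             call = calls,
                                             stringsAsFactors = FALSE))
}

.site_calls_consensus <- function(consensus, sites, ref) {
  sc <- alignment_scoring()
  aln <- cpp_align(toupper(consensus), ref, sc$match, sc$mismatch,
                   -sc$gap_open, -sc$gap_extend, mode = 1L, iupac = TRUE)
  ca <- .chars(aln$a); cb <- .chars(aln$b)
  at_ref <- rep(NA_character_, nchar(ref))
  pos <- 0L
  for (i in seq_along(cb)) {
    if (cb[i] == "-") next
    pos <- pos + 1L
    at_ref[pos] <- ca[i]
  }
  vapply(seq_len(nrow(sites)), function(k) {
    pa <- sites$pos_a[k]
    if (is.na(pa)) return("uncovered")  # gap-allele site not locatable on ref
    b <- at_ref[pa + 1L]
    if (is.na(b)) return("uncovered")
    aa <- sites$allele_a[k]; as_ <- sites$allele_s[k]
    set <- if (b == "-") "-" else iupac_bases(b)
    has_a <- aa %in% set; has_s <- as_ %in% set
    if (has_a && has_s) "both"
    else if (has_a) "a"
    else if (has_s) "s"
    else "other"
  }, character(1))
}

.site_calls_pileup <- function(p, sites, min_depth, mixed_band) {
  vapply(seq_len(nrow(sites)), function(k) {
    pa <- sites$pos_a[k]
    if (is.na(pa)) return("uncovered")
    d <- p$depth[pa + 1L]
    if (is.na(d) || d < min_depth) return("uncovered")
    freq_of <- function(allele) {
      row <- if (allele == "-") "del" else allele
      if (!row %in% rownames(p$counts)) return(0)
      p$counts[row, pa + 1L] / d
    }
    fa <- freq_of(sites$allele_a[k]); fs <- freq_of(sites$allele_s[k])
    if (fa >= mixed_band && fs >= mixed_band) "both"
    else if (max(fa, fs) >= 0.5) { if (fa > fs) "a" else "s" }
    else "other"
  }, character(1))
}

#' Integrate loci into a specimen-level verdict
#'
#' The specimen is called a hybrid when its ITS profile carries at least
#' `hybrid_floor` mass on a variant of each species (nuclear additivity);
#' otherwise it is called the profile's species when that agrees with the
#' resolved chloroplast haplotypes, and indeterminate (with a note) on
#' conflict. The maternal lineage is the species of the chloroplast
#' haplotype — chloroplasts being maternally inherited in these grasses —
#' and is reported only when both chloroplast loci agree.
#'
#' @param hap_rbcl,hap_trnh Haplotype calls from [assign_haplotype()].
#' @param profile A `variant_profile` for ITS.
#' @param hybrid_floor Minimum per-species ITS mass for a hybrid call.
#' @param specimen_id Identifier (defaults to the profile's).
#' @param locus_detail Optional named character vector of display labels
#'   per chloroplast locus (e.g. `"sI, sII"` for an indel mixture).
#' @param notes Character vector of evidence notes to carry along.
#' @return Object of class `specimen_call`.
#' @export
call_specimen <- function(hap_rbcl, hap_trnh, profile, hybrid_floor = 0.10,
                          specimen_id = NULL, locus_detail = NULL,
                          notes = character(0)) {
  stopifnot(inherits(profile, "variant_profile"))
  hap_rbcl <- match.arg(as.character(hap_rbcl), .HAP_LEVELS)
  hap_trnh <- match.arg(as.character(hap_trnh), .HAP_LEVELS)
  if (is.null(specimen_id)) specimen_id <- profile$specimen_id
  pr <- profile$proportions
  a_mass <- pr[startsWith(names(pr), "a")]
  s_mass <- pr[startsWith(names(pr), "s")]
  has_a <- any(a_mass >= hybrid_floor)
  has_s <- any(s_mass >= hybrid_floor)
  hap_species <- c(a = "advena", s = "setaceum")
  resolved <- c(rbcL = hap_rbcl, `trnH-psbA` = hap_trnh)
  resolved <- resolved[resolved %in% c("a", "s")]
  maternal <- NA_character_
  if (hap_rbcl %in% c("a", "s") && hap_rbcl == hap_trnh)
    maternal <- hap_species[[hap_rbcl]]
  hybrid <- FALSE
  if (hap_rbcl == "unresolved" && hap_trnh == "unresolved") {
    verdict <- "indeterminate"
    notes <- c(notes, "both chloroplast loci unresolved")
  } else if (has_a && has_s) {
    verdict <- "hybrid"; hybrid <- TRUE
  } else if (has_a || has_s) {
    ps <- if (has_a) "advena" else "setaceum"
    conflict <- length(resolved) &&
      any(hap_species[resolved] != ps)
    if (conflict) {
      verdict <- "indeterminate"
      notes <- c(notes, sprintf(
        "ITS assigns %s but chloroplast haplotype(s) disagree (%s)",
        ps, paste(names(resolved), resolved, sep = "=", collapse = ", ")))
    } else verdict <- ps
  } else {
    verdict <- "indeterminate"
    notes <- c(notes, "no ITS variant above the reporting floor")
  }
  structure(list(specimen_id = specimen_id,
                 haplotype = c(rbcL = hap_rbcl, `trnH-psbA` = hap_trnh),
                 locus_detail = locus_detail, its_profile = profile,
                 species_verdict = verdict, hybrid = hybrid,
                 maternal_lineage = maternal, notes = notes),
            class = "specimen_call")
}

#' @export
print.specimen_call <- function(x, ...) {
  cat(sprintf("<specimen_call> %s: %s%s\n", x$specimen_id, x$species_verdict,
              if (!is.na(x$maternal_lineage))
                paste0(" (maternal ", x$maternal_lineage, ")") else ""))
  cat(sprintf("  rbcL=%s trnH-psbA=%s  ITS: %s\n", x$haplotype["rbcL"],
              x$haplotype["trnH-psbA"],
              paste(sprintf("%s %.0f%%", names(x$its_profile$proportions),
                            100 * x$its_profile$proportions),
                    collapse = ", ")))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

# reference ranges for the two species (measurement, unit, advena range,
# setaceum range); stipe length is the single most reliable quantitative
# character (0.3-1.1 mm vs 1.1-3.1 mm)
.MORPHO_RANGES <- list(
  stipe_mm = list(advena = c(0.3, 1.1), setaceum = c(1.1, 3.1)),
  leaf_width_mm = list(advena = c(6, 11), setaceum = c(1, 3.7)),
  leaf_length_cm = list(advena = c(22, 52), setaceum = c(30, 100)))

#' A morphological measurement record
#'
#' Measurements are ranges (min, max) over the specimen's organs; a single
#' value stands for a degenerate range.
#'
#' @param stipe_mm Stipe length range (mm).
#' @param leaf_width_mm Leaf blade width range (mm).
#' @param leaf_length_cm Leaf length range (cm).
#' @param posture Inflorescence posture, `"drooping"` or `"rigid"`.
#' @param blade Leaf blade, `"flat"` or `"involute"`.
#' @return Object of class `morpho_record`.
#' @export
morpho_record <- function(stipe_mm = NULL, leaf_width_mm = NULL,
                          leaf_length_cm = NULL, posture = NULL,
                          blade = NULL) {
  rng <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1) x <- c(x, x)
    if (length(x) != 2 || x[1] > x[2] || any(x <= 0))
      stop(what, " must be a positive (min, max) range")
    x
  }
  if (!is.null(posture)) posture <- match.arg(posture, c("drooping", "rigid"))
  if (!is.null(blade)) blade <- match.arg(blade, c("flat", "involute"))
  structure(list(stipe_mm = rng(stipe_mm, "stipe_mm"),
                 leaf_width_mm = rng(leaf_width_mm, "leaf_width_mm"),
                 leaf_length_cm = rng(leaf_length_cm, "leaf_length_cm"),
                 posture = posture, blade = blade),
            class = "morpho_record")
}

#' Advisory morphological classification
#'
#' Scores each available character against the two species' reference
#' ranges: a measured range falling inside exactly one species' range
#' votes for that species; inside both or neither, no vote. Categorical
#' characters vote directly (drooping inflorescence / flat blade =
#' *advena*; rigid / involute = *setaceum*). The verdict is the unanimous
#' vote, else indeterminate. Morphology is corroborating evidence only and
#' never overrides a molecular verdict.
#'
#' @param m A [morpho_record()] with at least stipe length or leaf width.
#' @return Object of class `morpho_classification`: list with `verdict`
#'   (`advena` / `setaceum` / `indeterminate`) and `scores` (per-character
#'   vote, `"none"` when uninformative).
#' @export
classify_morphology <- function(m) {
  stopifnot(inherits(m, "morpho_record"))
  if (is.null(m$stipe_mm) && is.null(m$leaf_width_mm))
    stop("no usable characters: need stipe length or leaf width")
  scores <- character(0)
  inside <- function(x, r) x[1] >= r[1] && x[2] <= r[2]
  for (ch in names(.MORPHO_RANGES)) {
    x <- m[[ch]]
    if (is.null(x)) next
    in_a <- inside(x, .MORPHO_RANGES[[ch]]$advena)
    in_s <- inside(x, .MORPHO_RANGES[[ch]]$setaceum)
    scores[ch] <- if (in_a && !in_s) "advena"
                  else if (in_s && !in_a) "setaceum" else "none"
  }
  if (!is.null(m$posture))
    scores["posture"] <- if (m$posture == "drooping") "advena" else "setaceum"
  if (!is.null(m$blade))
    scores["blade"] <- if (m$blade == "flat") "advena" else "setaceum"
  votes <- unique(scores[scores != "none"])
  verdict <- if (length(votes) == 1) votes else "indeterminate"
  structure(list(verdict = verdict, scores = scores),
            class = "morpho_classification")
}

#' @export
print.morpho_classification <- function(x, ...) {
  cat("<morpho_classification>", x$verdict, "\n")
  for (ch in names(x$scores)) cat(sprintf("  %s: %s\n", ch, x$scores[ch]))
  invisible(x)
}

.LABEL_ORDER <- c("aI", "aII", "sI", "sII")

#' Tabulate specimen calls
#'
#' One row per specimen: the chloroplast haplotype labels, the ITS variant
#' labels and their estimated percentages, the verdict, the hybrid flag
#' and the maternal lineage. The printed rendering and the data.frame
#' carry identical content.
#'
#' @param calls List of `specimen_call` objects.
#' @return Object of class `specimen_report` (a data.frame).
#' @export
report <- function(calls) {
  cols <- c("specimen_id", "rbcL", "trnH_psbA", "ITS", "ITS_percent",
            "species_verdict", "hybrid", "maternal_lineage", "notes")
  if (!length(calls)) {
    out <- as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols),
      stringsAsFactors = FALSE)
    out$hybrid <- logical(0)
    return(structure(out, class = c("specimen_report", "data.frame")))
  }
  rows <- lapply(calls, function(x) {
    stopifnot(inherits(x, "specimen_call"))
    pr <- x$its_profile$proportions
    ord <- order(match(names(pr), .LABEL_ORDER))
    pr <- pr[ord]
    detail <- function(locus) {
      if (!is.null(x$locus_detail) && !is.na(x$locus_detail[locus]) &&
          locus %in% names(x$locus_detail)) x$locus_detail[[locus]]
      else x$haplotype[[locus]]
    }
    data.frame(specimen_id = x$specimen_id,
               rbcL = detail("rbcL"), trnH_psbA = detail("trnH-psbA"),
               ITS = paste(names(pr), collapse = ", "),
               ITS_percent = paste(sprintf("%.0f%% %s", 100 * pr, names(pr)),
                                   collapse = ", "),
               species_verdict = x$species_verdict, hybrid = x$hybrid,
               maternal_lineage = ifelse(is.na(x$maternal_lineage), "",
                                         x$maternal_lineage),
               notes = paste(x$notes, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("specimen_report", "data.frame"))
}

#' @export
print.specimen_report <- function(x, ...) {
  cat("Specimen identification report",
      sprintf("(%d specimen%s)\n", nrow(x), if (nrow(x) == 1) "" else "s"))
  if (nrow(x)) print.data.frame(x, right = FALSE, row.names = FALSE)
  invisible(x)
}

#' Write a specimen report as delimited text
#' @param rep A `specimen_report`.
#' @param path Output TSV path.
#' @export
write_report_tsv <- function(rep, path) {
  stopifnot(inherits(rep, "specimen_report"))
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
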