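# End-to-end identification: Sanger consensus for the chloroplast loci with
# a short-read fallback when bidirectional assembly fails, short-read ITS
# deconvolution, and specimen-level integration.

#' Derive the analysis context from a panel
#'
#' Precomputes what every specimen shares: the diagnostic site sets of the
#' chloroplast loci, the ITS informative-site table, and the common
#' mapping references (the *advena* haplotype of each locus; ITS maps to
#' variant aI, the informative-site anchor).
#'
#' @param panel A `locus_panel`.
#' @return List with `sites` (per chloroplast locus), `info`, `map_ref`
#'   (per locus `locus_reference`) and the `panel` itself.
#' @export
panel_context <- function(panel) {
  stopifnot(inherits(panel, "locus_panel"))
  sites <- list(
    "rbcL" = diagnostic_sites(panel_ref(panel, "rbcL", "advena"),
                              panel_ref(panel, "rbcL", "setaceum")),
    "trnH-psbA" = diagnostic_sites(panel_ref(panel, "trnH-psbA", "advena"),
                                   panel_ref(panel, "trnH-psbA", "setaceum")))
  its_refs <- list(panel_ref(panel, "ITS", "advena", "I"),
                   panel_ref(panel, "ITS", "advena", "II"),
                   panel_ref(panel, "ITS", "setaceum", "I"),
                   panel_ref(panel, "ITS", "setaceum", "II"))
  its_refs <- its_refs[!vapply(its_refs, is.null, logical(1))]
  info <- informative_sites(its_refs)
  map_ref <- list(
    "rbcL" = panel_ref(panel, "rbcL", "advena"),
    "trnH-psbA" = panel_ref(panel, "trnH-psbA", "advena"),
    "ITS" = its_refs[[1]])
  list(panel = panel, sites = sites, info = info, map_ref = map_ref)
}

#' Identify one specimen from its sequencing data
#'
#' For each chloroplast locus the Sanger pair is quality-trimmed and
#' assembled; when assembly succeeds the haplotype is read off the
#' consensus at the diagnostic sites, and when it fails (the single-indel
#' mixture signature) the locus falls back to the short reads: mapping,
#' pileup, indel-mixture detection and pileup-based haplotyping. ITS is
#' always resolved from short reads by mixture deconvolution.
#'
#' @param specimen_id Identifier for the report row.
#' @param sanger Named list (per chloroplast locus) of `list(fwd, rev)`
#'   [quality_read()] pairs; a missing locus goes straight to short reads.
#' @param short_reads Named list (per locus) of `read_set`s (or anything
#'   [map_reads()] accepts).
#' @param ctx A [panel_context()].
#' @param hybrid_floor Passed to [call_specimen()].
#' @param trim_floor,trim_window Passed to [trim_quality()].
#' @param min_depth Depth floor for pileup-based calls.
#' @return A `specimen_call`.
#' @export
process_specimen <- function(specimen_id, sanger, short_reads, ctx,
                             hybrid_floor = 0.10, trim_floor = 30,
                             trim_window = 10, min_depth = 10) {
  haps <- c(rbcL = "unresolved", `trnH-psbA` = "unresolved")
  detail <- c(rbcL = NA_character_, `trnH-psbA` = NA_character_)
  notes <- character(0)
  for (locus in c("rbcL", "trnH-psbA")) {
    hap <- NULL
    pair <- sanger[[locus]]
    if (!is.null(pair)) {
      cons <- assemble_bidirectional(
        trim_quality(pair$fwd, trim_floor, trim_window),
        trim_quality(pair$rev, trim_floor, trim_window))
      if (cons$status == "ok") {
        hap <- assign_haplotype(cons, ctx$sites[[locus]],
                                ref = ctx$map_ref[[locus]])
      } else {
        notes <- c(notes, sprintf(
          "%s could not be bidirectionally Sanger-sequenced; resolved from short reads",
          locus))
      }
    }
    if (is.null(hap)) {
      rs <- short_reads[[locus]]
      if (is.null(rs)) { haps[locus] <- "unresolved"; next }
      aln <- map_reads(rs, ctx$map_ref[[locus]])
      pile <- build_pileup(aln)
      hap <- assign_haplotype(pile, ctx$sites[[locus]], min_depth = min_depth)
      mix <- detect_mixed_indel(pile, min_depth = min_depth)
      if (nrow(mix)) {
        letter <- if (hap %in% c("a", "s")) hap else "?"
        detail[locus] <- sprintf("%sI, %sII", letter, letter)
        notes <- c(notes, sprintf(
          "%s carries two haplotypes differing by a single %s (%.0f%%/%.0f%%)",
          locus, mix$kind[1], 100 * mix$freq_with[1],
          100 * mix$freq_without[1]))
      }
    }
    haps[locus] <- as.character(hap)
  }
  its_aln <- map_reads(short_reads[["ITS"]], ctx$map_ref[["ITS"]])
  profile <- deconvolve_its(its_aln, ctx$info, specimen_id = specimen_id)
  call_specimen(haps["rbcL"], haps["trnH-psbA"], profile,
                hybrid_floor = hybrid_floor, specimen_id = specimen_id,
                locus_detail = detail, notes = notes)
}

#' Simulate and identify a set of specimens
#'
#' Runs the full pipeline over genotype scenarios: per specimen, Sanger
#' pairs for the chloroplast loci and short reads for every locus are
#' simulated from the panel (all streams seeded from the config seed),
#' then identified with [process_specimen()].
#'
#' @param panel A `locus_panel` (default: the synthetic panel under its
#'   default configuration).
#' @param scenarios List of [genotype_spec()]s (default:
#'   [cultivar_scenarios()]).
#' @param cfg A [read_sim_config()].
#' @param sanger_error_model Passed to [simulate_sanger_pair()].
#' @param hybrid_floor Passed to [call_specimen()].
#' @return List with `calls` (per-specimen `specimen_call`s) and `report`
#'   (the [report()] table).
#' @export
run_identification <- function(panel = make_reference_panel(),
                               scenarios = cultivar_scenarios(),
                               cfg = read_sim_config(),
                               sanger_error_model = "quality",
                               hybrid_floor = 0.10) {
  ctx <- panel_context(panel)
  calls <- lapply(scenarios, function(spec) {
    sanger <- lapply(c(rbcL = "rbcL", `trnH-psbA` = "trnH-psbA"),
                     function(locus) simulate_sanger_pair(
                       spec, panel, locus, error_model = sanger_error_model,
                       seed = .derive_seed(cfg$seed, spec$specimen_id, locus,
                                           "sanger")))
    reads <- simulate_short_reads(spec, panel, cfg)
    process_specimen(spec$specimen_id, sanger, reads, ctx,
                     hybrid_floor = hybrid_floor)
  })
  list(calls = calls, report = report(calls))
}

#' Identify specimens from a fixture directory
#'
#' Reads the panel FASTA, manifest and per-specimen FASTQ files written by
#' [write_fixture_set()] and identifies every specimen.
#'
#' @param dir Fixture directory containing `panel.fasta` and
#'   `manifest.tsv`.
#' @param hybrid_floor Passed to [call_specimen()].
#' @return As [run_identification()].
#' @export
run_identification_files <- function(dir, hybrid_floor = 0.10) {
  panel <- read_panel_fasta(file.path(dir, "panel.fasta"))
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE, check.names = FALSE)
  ctx <- panel_context(panel)
  calls <- lapply(unique(manifest$specimen_id), function(sid) {
    rows <- manifest[manifest$specimen_id == sid, , drop = FALSE]
    sanger <- list(); reads <- list()
    for (i in seq_len(nrow(rows))) {
      locus <- rows$locus[i]
      reads[[locus]] <- read_read_set_fastq(file.path(dir, rows$short_reads[i]))
      if (locus != "ITS")
        sanger[[locus]] <- list(
          fwd = read_quality_read_fastq(file.path(dir, rows$sanger_fwd[i]),
                                        "forward"),
          rev = read_quality_read_fastq(file.path(dir, rows$sanger_rev[i]),
                                        "reverse"))
    }
    process_specimen(sid, sanger, reads, ctx, hybrid_floor = hybrid_floor)
  })
  list(calls = calls, report = report(calls))
}
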