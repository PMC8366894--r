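# Synthetic-data generator: reference panels, specimen genotypes, Sanger-style
# read pairs and amplicon short reads with the divergence structure observed
# between Pennisetum advena and P. setaceum.

# run expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-stream seed from a master seed and a string key;
# result always in [0, 2^31 - 2]
.derive_seed <- function(master, ...) {
  key <- paste(..., collapse = "/")
  v <- utf8ToInt(key)
  h <- sum(v * (seq_along(v) %% 97 + 1) * 131) %% 2147483647
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

#' Configuration of the synthetic reference panel
#'
#' Defaults emulate the divergence structure of the *P. advena* /
#' *P. setaceum* pair: 2 diagnostic substitutions on rbcL, 4 on trnH-psbA,
#' ~90% ITS identity between species, 3 SNPs between the two *P. advena*
#' ITS variants (aI/aII) and 2 between the *P. setaceum* variants (sI/sII),
#' plus an optional pair of trnH-psbA haplotypes differing by a single 1-nt
#' indel within *P. setaceum*.
#'
#' @param rbcl_length,trnh_length,its_length Locus lengths (nt).
#' @param rbcl_diff,trnh_diff Inter-species substitution counts on the
#'   chloroplast loci.
#' @param its_identity Target ITS percent identity between species (0-100].
#' @param advena_its_snps,setaceum_its_snps SNPs between intra-specific ITS
#'   variants I and II.
#' @param trnh_indel_variant Emit a second *P. setaceum* trnH-psbA haplotype
#'   carrying a 1-nt insertion.
#' @param margin Bases at each reference end kept free of planted
#'   differences (primer-proximal regions stay clean).
#' @param seed Master random seed; all per-locus streams derive from it.
#' @return Object of class `panel_config`.
#' @export
panel_config <- function(rbcl_length = 550L, trnh_length = 400L,
                         its_length = 600L, rbcl_diff = 2L, trnh_diff = 4L,
                         its_identity = 90, advena_its_snps = 3L,
                         setaceum_its_snps = 2L, trnh_indel_variant = TRUE,
                         margin = 30L, seed = 1L) {
  cfg <- list(rbcl_length = as.integer(rbcl_length),
              trnh_length = as.integer(trnh_length),
              its_length = as.integer(its_length),
              rbcl_diff = as.integer(rbcl_diff),
              trnh_diff = as.integer(trnh_diff),
              its_identity = its_identity,
              advena_its_snps = as.integer(advena_its_snps),
              setaceum_its_snps = as.integer(setaceum_its_snps),
              trnh_indel_variant = isTRUE(trnh_indel_variant),
              margin = as.integer(margin), seed = as.integer(seed))
  if (cfg$its_identity <= 0 || cfg$its_identity > 100)
    stop("its_identity must be in (0, 100]")
  its_div <- round((1 - cfg$its_identity / 100) * cfg$its_length)
  interior <- function(len) len - 2L * cfg$margin
  if (cfg$rbcl_diff < 0 || cfg$rbcl_diff > interior(cfg$rbcl_length))
    stop("rbcl_diff infeasible for rbcl_length")
  if (cfg$trnh_diff < 0 || cfg$trnh_diff + 1L > interior(cfg$trnh_length))
    stop("trnh_diff infeasible for trnh_length")
  if (its_div + cfg$advena_its_snps + cfg$setaceum_its_snps >
      interior(cfg$its_length))
    stop("ITS divergence + variant SNPs exceed available positions")
  cfg$its_divergent <- as.integer(its_div)
  structure(cfg, class = "panel_config")
}

# substitute the bases of `seq` at `pos` (1-based) with different bases
.substitute_at <- function(seq, pos) {
  ch <- .chars(seq)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  .collapse(ch)
}

#' Generate a synthetic reference panel
#'
#' Deterministic given the config seed. The emitted panel satisfies, by
#' construction: `diagnostic_sites()` on the chloroplast references yields
#' exactly the configured counts; ITS aI vs sI percent identity is within
#' one point of the target; intra-specific ITS variant pairs differ at
#' exactly the configured SNP counts and nowhere else.
#'
#' @param cfg A [panel_config()].
#' @return A `locus_panel`.
#' @export
make_reference_panel <- function(cfg = panel_config()) {
  stopifnot(inherits(cfg, "panel_config"))
  interior <- function(len) seq(cfg$margin + 1L, len - cfg$margin)
  refs <- .with_seed(.derive_seed(cfg$seed, "panel"), {
    out <- list()
    # chloroplast loci: advena backbone + planted substitutions in setaceum
    rb_a <- .random_dna(cfg$rbcl_length)
    rb_pos <- sort(sample(interior(cfg$rbcl_length), cfg$rbcl_diff))
    out$rb_a <- locus_reference("rbcL", "advena", sequence = rb_a)
    out$rb_s <- locus_reference("rbcL", "setaceum",
                                sequence = .substitute_at(rb_a, rb_pos))
    tr_a <- .random_dna(cfg$trnh_length)
    tr_all <- sample(interior(cfg$trnh_length), cfg$trnh_diff + 1L)
    tr_pos <- sort(tr_all[seq_len(cfg$trnh_diff)])
    tr_s1 <- .substitute_at(tr_a, tr_pos)
    out$tr_a <- locus_reference("trnH-psbA", "advena", sequence = tr_a)
    if (cfg$trnh_indel_variant) {
      # variant II: 1-nt insertion at a position away from diagnostic sites,
      # inserted base chosen to differ from both neighbours so the indel
      # placement is alignment-unambiguous
      ip <- tr_all[cfg$trnh_diff + 1L]
      ch <- .chars(tr_s1)
      ins <- sample(setdiff(c("A", "C", "G", "T"), c(ch[ip], ch[ip + 1L])), 1)
      tr_s2 <- .collapse(c(ch[1:ip], ins, ch[(ip + 1L):length(ch)]))
      out$tr_s1 <- locus_reference("trnH-psbA", "setaceum", "I", tr_s1)
      out$tr_s2 <- locus_reference("trnH-psbA", "setaceum", "II", tr_s2)
    } else {
      out$tr_s1 <- locus_reference("trnH-psbA", "setaceum", sequence = tr_s1)
    }
    # ITS: species divergence as substitutions only, variant SNPs disjoint
    its_a1 <- .random_dna(cfg$its_length)
    npos <- cfg$its_divergent + cfg$advena_its_snps + cfg$setaceum_its_snps
    pos <- sample(interior(cfg$its_length), npos)
    div_pos <- sort(pos[seq_len(cfg$its_divergent)])
    a2_pos <- sort(pos[cfg$its_divergent + seq_len(cfg$advena_its_snps)])
    s2_pos <- sort(pos[cfg$its_divergent + cfg$advena_its_snps +
                         seq_len(cfg$setaceum_its_snps)])
    its_s1 <- .substitute_at(its_a1, div_pos)
    out$its_a1 <- locus_reference("ITS", "advena", "I", its_a1)
    out$its_a2 <- locus_reference("ITS", "advena", "II",
                                  .substitute_at(its_a1, a2_pos))
    out$its_s1 <- locus_reference("ITS", "setaceum", "I", its_s1)
    out$its_s2 <- locus_reference("ITS", "setaceum", "II",
                                  .substitute_at(its_s1, s2_pos))
    out
  })
  locus_panel(unname(refs))
}

.ITS_LABELS <- c("aI", "aII", "sI", "sII")

#' Specify a specimen genotype
#'
#' The ground truth for one synthetic specimen: its chloroplast (maternal)
#' species and the true mixture of ITS variants among its rDNA copies.
#'
#' @param specimen_id Character scalar.
#' @param chloroplast_species `"advena"` or `"setaceum"`.
#' @param its_mixture Named numeric vector of true proportions over labels
#'   from `{aI, aII, sI, sII}`; non-negative, summing to 1.
#' @param trnh_indel_mix If `TRUE`, the specimen carries both trnH-psbA
#'   haplotypes (the single-indel pair) in equal amounts.
#' @return Object of class `genotype_spec`.
#' @export
genotype_spec <- function(specimen_id, chloroplast_species, its_mixture,
                          trnh_indel_mix = FALSE) {
  chloroplast_species <- match.arg(chloroplast_species, .SPECIES)
  if (is.null(names(its_mixture)) ||
      !all(names(its_mixture) %in% .ITS_LABELS))
    stop("its_mixture must be named with labels from {aI, aII, sI, sII}")
  if (any(its_mixture < 0) || abs(sum(its_mixture) - 1) > 1e-9)
    stop("its_mixture proportions must be >= 0 and sum to 1")
  if (!any(its_mixture > 0)) stop("at least one ITS variant must be present")
  structure(list(specimen_id = specimen_id,
                 chloroplast_species = chloroplast_species,
                 its_mixture = its_mixture[its_mixture > 0],
                 trnh_indel_mix = isTRUE(trnh_indel_mix)),
            class = "genotype_spec")
}

#' @export
print.genotype_spec <- function(x, ...) {
  mix <- paste(sprintf("%s:%.2f", names(x$its_mixture), x$its_mixture),
               collapse = " ")
  cat(sprintf("<genotype_spec> %s  chloroplast=%s  ITS{%s}%s\n",
              x$specimen_id, x$chloroplast_species, mix,
              if (x$trnh_indel_mix) "  trnH indel mixture" else ""))
  invisible(x)
}

#' Short-read simulation settings
#'
#' @param read_length Read length (nt).
#' @param error_rate Per-base substitution error rate, in `[0, 0.1]`.
#' @param coverage Mean per-position coverage.
#' @param paired Unused placeholder for paired-end layout; reads are
#'   simulated unpaired.
#' @param seed Master seed for the read streams.
#' @return Object of class `read_sim_config`.
#' @export
read_sim_config <- function(read_length = 150L, error_rate = 0.001,
                            coverage = 1000, paired = FALSE, seed = 1L) {
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must be in [0, 0.1]")
  if (coverage <= 0) stop("coverage must be > 0")
  structure(list(read_length = as.integer(read_length),
                 error_rate = error_rate, coverage = coverage,
                 paired = isTRUE(paired), seed = as.integer(seed)),
            class = "read_sim_config")
}

# resolve a specimen's template mixture at one locus to panel references
.locus_mixture <- function(spec, panel, locus) {
  if (locus == "ITS") {
    labs <- names(spec$its_mixture)
    tmpl <- lapply(labs, function(l) {
      sp <- if (startsWith(l, "a")) "advena" else "setaceum"
      va <- if (endsWith(l, "II")) "II" else "I"
      panel_ref(panel, "ITS", sp, va)
    })
    list(labels = labs, templates = tmpl, props = unname(spec$its_mixture))
  } else if (locus == "trnH-psbA" && spec$trnh_indel_mix) {
    sp <- spec$chloroplast_species
    list(labels = paste0(substr(sp, 1, 1), c("I", "II")),
         templates = list(panel_ref(panel, locus, sp, "I"),
                          panel_ref(panel, locus, sp, "II")),
         props = c(0.5, 0.5))
  } else {
    sp <- spec$chloroplast_species
    list(labels = substr(sp, 1, 1),
         templates = list(panel_ref(panel, locus, sp)), props = 1)
  }
}

#' Simulate amplicon short reads for one specimen
#'
#' Each read is drawn from one template haplotype chosen with probability
#' equal to its true proportion, placed uniformly along the template, and
#' mutated at the configured per-base substitution error rate. Reads are
#' emitted on the reference strand. Deterministic given the config seed.
#'
#' @param spec A [genotype_spec()].
#' @param panel A `locus_panel` containing every haplotype with non-zero
#'   proportion.
#' @param cfg A [read_sim_config()].
#' @param loci Loci to simulate.
#' @return Named list (per locus) of `read_set` objects: data.frames with
#'   columns `id`, `label` (true template), `start` (0-based position on
#'   the template) and `sequence`; attribute `quality` holds the constant
#'   PHRED score implied by the error rate.
#' @export
simulate_short_reads <- function(spec, panel, cfg = read_sim_config(),
                                 loci = .LOCI) {
  stopifnot(inherits(spec, "genotype_spec"), inherits(panel, "locus_panel"))
  qual <- if (cfg$error_rate > 0)
    min(40L, as.integer(round(-10 * log10(cfg$error_rate)))) else 40L
  out <- list()
  for (locus in loci) {
    mix <- .locus_mixture(spec, panel, locus)
    out[[locus]] <- .with_seed(
      .derive_seed(cfg$seed, spec$specimen_id, locus, "short"), {
      tmpl_seq <- vapply(mix$templates, function(r) r$sequence, character(1))
      mean_len <- mean(nchar(tmpl_seq))
      n <- max(1L, as.integer(round(cfg$coverage * mean_len / cfg$read_length)))
      pick <- sample.int(length(mix$labels), n, replace = TRUE,
                         prob = mix$props)
      len <- nchar(tmpl_seq)[pick]
      start <- floor(runif(n) * (len - cfg$read_length + 1))
      seqs <- substring(tmpl_seq[pick], start + 1, start + cfg$read_length)
      if (cfg$error_rate > 0) {
        nerr <- stats::rbinom(n, cfg$read_length, cfg$error_rate)
        for (i in which(nerr > 0)) {
          pos <- sample.int(cfg$read_length, nerr[i])
          ch <- .chars(seqs[i])
          for (p in pos)
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
          seqs[i] <- .collapse(ch)
        }
      }
      structure(
        data.frame(id = sprintf("%s|%s|r%06d", spec$specimen_id, locus,
                                seq_len(n)),
                   label = mix$labels[pick], start = as.integer(start),
                   sequence = seqs, stringsAsFactors = FALSE),
        quality = qual, locus = locus, specimen = spec$specimen_id,
        class = c("read_set", "data.frame"))
    })
  }
  out
}

# per-position IUPAC mixture template: bases whose summed proportion reaches
# the secondary-peak threshold are covered by the emitted code
.mixture_iupac <- function(seqs, props, threshold) {
  L <- nchar(seqs[1])
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  vapply(seq_len(L), function(j) {
    mass <- tapply(props, mat[, j], sum)
    keep <- names(mass)[mass >= threshold]
    if (length(keep) == 0) keep <- names(mass)[which.max(mass)]
    iupac_code(keep)
  }, character(1))
}

# plateau Q50 over the read core, linear decay to Q10 over the last `tail`
# bases (in reading direction)
.sanger_quality_profile <- function(n, plateau = 50L, floor_q = 10L,
                                    tail = 50L) {
  q <- rep(plateau, n)
  k <- min(tail, n)
  q[(n - k + 1):n] <- round(seq(plateau, floor_q, length.out = k))
  as.integer(q)
}

#' Simulate a bidirectional Sanger read pair for one specimen and locus
#'
#' Emulates trace basecalling on a (possibly mixed) template population:
#' at positions where a minority template base reaches the secondary-peak
#' threshold the emitted base is the IUPAC code covering the observed
#' bases; quality follows a plateau-plus-decay profile, and bases are
#' miscalled at the rate implied by their quality. When the mixture
#' contains two templates that differ by an indel, every position
#' downstream of the indel (in each read's own direction) is emitted as a
#' low-quality random base on both strands — the trace collapse that makes
#' such amplicons impossible to sequence bidirectionally.
#'
#' @param spec A [genotype_spec()].
#' @param panel A `locus_panel`.
#' @param locus Locus to sequence.
#' @param read_length Maximum trace read length (nt).
#' @param peak_threshold Minority proportion at which a secondary peak is
#'   called into the IUPAC code.
#' @param error_model `"quality"` (miscalls at the per-base quality-implied
#'   rate) or `"none"` (error-free).
#' @param seed Seed; defaults to a stream derived from the specimen/locus.
#' @return List with `fwd` and `rev` [quality_read()]s.
#' @export
simulate_sanger_pair <- function(spec, panel, locus, read_length = 500L,
                                 peak_threshold = 0.2,
                                 error_model = c("quality", "none"),
                                 seed = NULL) {
  stopifnot(inherits(spec, "genotype_spec"), inherits(panel, "locus_panel"))
  error_model <- match.arg(error_model)
  locus <- match.arg(locus, .LOCI)
  mix <- .locus_mixture(spec, panel, locus)
  if (is.null(seed)) seed <- .derive_seed(1L, spec$specimen_id, locus, "sanger")
  .with_seed(seed, {
    seqs <- vapply(mix$templates, function(r) r$sequence, character(1))
    lens <- nchar(seqs)
    if (length(unique(lens)) == 1) {
      tmpl <- .mixture_iupac(seqs, mix$props, peak_threshold)
      L <- lens[1]
      n <- min(read_length, L)
      fwd_b <- tmpl[1:n]
      rev_b <- .chars(revcomp(.collapse(tmpl[(L - n + 1):L])))
      fwd_q <- .sanger_quality_profile(n)
      rev_q <- .sanger_quality_profile(n)
    } else {
      # single-indel mixture: trace collapses downstream of the indel
      stopifnot(length(seqs) == 2)
      lo <- seqs[which.min(lens)]; hi <- seqs[which.max(lens)]
      cl <- .chars(lo); ch <- .chars(hi)
      pre <- 0L
      while (pre < nchar(lo) && cl[pre + 1] == ch[pre + 1]) pre <- pre + 1L
      rl <- rev(cl); rh <- rev(ch)
      suf <- 0L
      while (suf < nchar(lo) - pre && rl[suf + 1] == rh[suf + 1]) suf <- suf + 1L
      L <- max(lens)
      n <- min(read_length, L)
      fwd_b <- c(ch[seq_len(min(pre, n))],
                 if (n > pre) sample(c("A", "C", "G", "T"), n - pre,
                                     replace = TRUE))
      fwd_q <- c(.sanger_quality_profile(n)[seq_len(min(pre, n))],
                 if (n > pre) rep(8L, n - pre))
      rev_clean <- .chars(revcomp(.collapse(ch[(L - min(suf, n) + 1):L])))
      k <- length(rev_clean)
      rev_b <- c(rev_clean,
                 if (n > k) sample(c("A", "C", "G", "T"), n - k, replace = TRUE))
      rev_q <- c(.sanger_quality_profile(n)[seq_len(k)],
                 if (n > k) rep(8L, n - k))
    }
    if (error_model == "quality") {
      miscall <- function(b, q) {
        p <- 10^(-q / 10)
        hit <- stats::runif(length(b)) < p & b %in% c("A", "C", "G", "T")
        for (i in which(hit))
          b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
        b
      }
      fwd_b <- miscall(fwd_b, fwd_q)
      rev_b <- miscall(rev_b, rev_q)
    }
    list(fwd = quality_read(.collapse(fwd_b), fwd_q, "forward"),
         rev = quality_read(.collapse(rev_b), rev_q, "reverse"))
  })
}

#' The thirteen reference specimen scenarios
#'
#' A bundled set of synthetic specimen genotypes mirroring the specimens a
#' diagnostic laboratory would meet for this species pair: the *P. advena*
#' type material and a trade import, the five major cultivars — three pure
#' *P. advena* ("Fireworks", "Rubrum", "Summer Samba") and the two of
#' hybrid origin ("Cherry Sparkler": 45% aI / 15% aII / 40% sI;
#' "Sky Rocket": 20% aI / 50% aII / 30% sI) — and six *P. setaceum*
#' collections, among them "Simons 2006" (70/30 sI/sII and the trnH-psbA
#' single-indel haplotype mixture) and "Mooney 9419" (30/70). Pure
#' *P. advena* specimens carry 55% aI / 45% aII. The remaining *P.
#' setaceum* collections default to an even 50/50 sI/sII mixture — an
#' assumption, since only the presence of both variants is established for
#' them.
#'
#' @return Named list of 13 [genotype_spec()] objects.
#' @export
cultivar_scenarios <- function() {
  adv <- c(aI = 0.55, aII = 0.45)
  set5050 <- c(sI = 0.5, sII = 0.5)
  specs <- list(
    genotype_spec("Valkenburg 4026", "advena", adv),
    genotype_spec("Wipff 1723", "advena", adv),
    genotype_spec("Cherry Sparkler", "advena",
                  c(aI = 0.45, aII = 0.15, sI = 0.40)),
    genotype_spec("Fireworks", "advena", adv),
    genotype_spec("Rubrum", "advena", adv),
    genotype_spec("Sky Rocket", "advena",
                  c(aI = 0.20, aII = 0.50, sI = 0.30)),
    genotype_spec("Summer Samba", "advena", adv),
    genotype_spec("Mooney 9419", "setaceum", c(sI = 0.30, sII = 0.70)),
    genotype_spec("Simons 2006", "setaceum", c(sI = 0.70, sII = 0.30),
                  trnh_indel_mix = TRUE),
    genotype_spec("Valkenburg 3934", "setaceum", set5050),
    genotype_spec("Verloove 13345", "setaceum", set5050),
    genotype_spec("Verloove 13647", "setaceum", set5050),
    genotype_spec("Verloove 13650", "setaceum", set5050))
  names(specs) <- vapply(specs, function(s) s$specimen_id, character(1))
  specs
}

#' Write a complete fixture set to disk
#'
#' Emits the panel FASTA, per-specimen per-locus Sanger pairs and short
#' reads as PHRED+33 FASTQ, and a tab-delimited manifest with the truth
#' columns. Byte-identical across runs with the same seeds.
#'
#' @param panel A `locus_panel`.
#' @param scenarios List of [genotype_spec()]s.
#' @param cfg A [read_sim_config()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_fixture_set <- function(panel, scenarios, cfg = read_sim_config(),
                              dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_panel_fasta(panel, file.path(dir, "panel.fasta"))
  rows <- list()
  slug <- function(x) gsub("[^A-Za-z0-9]+", "_", x)
  for (spec in scenarios) {
    reads <- simulate_short_reads(spec, panel, cfg)
    for (locus in names(reads)) {
      sp <- slug(spec$specimen_id); lc <- slug(locus)
      f_short <- file.path(dir, sprintf("%s_%s_reads.fastq", sp, lc))
      write_read_set_fastq(reads[[locus]], f_short)
      pair <- simulate_sanger_pair(
        spec, panel, locus,
        seed = .derive_seed(cfg$seed, spec$specimen_id, locus, "sanger"))
      f_fwd <- file.path(dir, sprintf("%s_%s_sanger_F.fastq", sp, lc))
      f_rev <- file.path(dir, sprintf("%s_%s_sanger_R.fastq", sp, lc))
      write_quality_read_fastq(pair$fwd, f_fwd,
                               id = sprintf("%s|%s|F", spec$specimen_id, locus))
      write_quality_read_fastq(pair$rev, f_rev,
                               id = sprintf("%s|%s|R", spec$specimen_id, locus))
      rows[[length(rows) + 1]] <- data.frame(
        specimen_id = spec$specimen_id, locus = locus,
        short_reads = basename(f_short), sanger_fwd = basename(f_fwd),
        sanger_rev = basename(f_rev),
        truth_chloroplast = spec$chloroplast_species,
        truth_its_mixture = paste(sprintf("%s=%g", names(spec$its_mixture),
                                          spec$its_mixture), collapse = ";"),
        truth_trnh_indel_mix = spec$trnh_indel_mix,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mf)
}
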