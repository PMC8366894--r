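# Variant detection and ITS mixture deconvolution.

test_that("variant detection applies the depth/count/frequency thresholds", {
  # homogeneous error-free pileup: no calls
  ref <- rand_dna(50)
  counts <- matrix(0L, 5, 50)
  refch <- strsplit(ref, "")[[1]]
  for (i in 1:50) counts[match(refch[i], c("A", "C", "G", "T")), i] <- 100L
  p <- fab_pileup(ref, counts)
  expect_equal(nrow(detect_variants(p)), 0)

  # 400 G / 600 A at a reference-A position: SNV at frequency 0.40
  ref2 <- paste0("A", substr(ref, 2, 50))
  counts2 <- counts
  counts2[, 1] <- 0L; counts2[1, 1] <- 600L; counts2[3, 1] <- 400L
  v <- detect_variants(fab_pileup(ref2, counts2))
  expect_equal(nrow(v), 1)
  expect_equal(v$position, 0)
  expect_equal(v$alt, "G")
  expect_equal(v$kind, "SNV")
  expect_equal(v$frequency, 0.40)

  # a 2% alternative at depth 1000 stays below the frequency floor
  counts3 <- counts
  counts3[, 2] <- 0L
  main <- match(refch[2], c("A", "C", "G", "T"))
  alt <- setdiff(1:4, main)[1]
  counts3[main, 2] <- 980L; counts3[alt, 2] <- 20L
  expect_equal(nrow(detect_variants(fab_pileup(ref, counts3))), 0)
  expect_equal(nrow(detect_variants(fab_pileup(ref, counts3),
                                    min_freq = 0.01)), 1)
})

test_that("variant detection equals direct counting on random pileups", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    ref <- rand_dna(n)
    counts <- matrix(rpois(5 * n, 4), 5, n)
    p <- fab_pileup(ref, counts)
    got <- detect_variants(p)
    want <- naive_variants(p)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      ord <- order(want$position, want$alt)
      expect_equal(got$position, want$position[ord])
      expect_equal(got$alt, want$alt[ord])
      expect_equal(got$count, want$count[ord])
    }
  }
})

test_that("raising any threshold never adds a call", {
  set.seed(32)
  ref <- rand_dna(40)
  counts <- matrix(rpois(5 * 40, 6), 5, 40)
  p <- fab_pileup(ref, counts)
  base <- detect_variants(p, min_depth = 5, min_count = 1, min_freq = 0.02)
  key <- function(v) paste(v$position, v$alt)
  for (args in list(list(min_depth = 20), list(min_count = 4),
                    list(min_freq = 0.2),
                    list(min_depth = 25, min_count = 5, min_freq = 0.15))) {
    stricter <- do.call(detect_variants, c(list(p), args))
    expect_true(all(key(stricter) %in% key(base)))
  }
})

test_that("informative sites are the union of planted variant differences", {
  # four tiny ITS variants with disjoint planted differences
  base <- rand_dna(120)
  a1 <- locus_reference("ITS", "advena", "I", base)
  a2 <- locus_reference("ITS", "advena", "II", plant_subs(base, c(10, 40)))
  s1 <- locus_reference("ITS", "setaceum", "I", plant_subs(base, c(60, 80, 100)))
  s2 <- locus_reference("ITS", "setaceum", "II", plant_subs(base, 110))
  info <- informative_sites(list(a1, a2, s1, s2))
  expect_equal(info$pos, sort(c(10, 40, 60, 80, 100, 110)) - 1L)
  expect_equal(attr(info, "labels"), c("aI", "aII", "sI", "sII"))
  expect_equal(info$aII[info$pos == 9], substr(a2$sequence, 10, 10))
  expect_false(any(info$has_gap))

  # identical sequences: no informative sites; fewer than two: rejected
  expect_equal(nrow(informative_sites(list(a1, locus_reference(
    "ITS", "setaceum", "I", base)))), 0)
  expect_error(informative_sites(list(a1)), "at least two")
})

test_that("the panel's informative-site table has species plus variant columns", {
  panel <- shared_panel()
  ctx <- panel_context(panel)
  cfg <- panel_config(seed = 42)
  expect_equal(nrow(ctx$info),
               cfg$its_divergent + cfg$advena_its_snps + cfg$setaceum_its_snps)
})

test_that("single-variant reads deconvolve to a pure profile", {
  panel <- shared_panel()
  ctx <- panel_context(panel)
  spec <- genotype_spec("pure", "advena", c(aI = 1))
  rs <- simulate_short_reads(spec, panel,
                             read_sim_config(coverage = 60, error_rate = 0,
                                             seed = 33), loci = "ITS")
  aln <- map_reads(rs$ITS, ctx$map_ref$ITS)
  prof <- deconvolve_its(aln, ctx$info, specimen_id = "pure")
  expect_equal(prof$proportions, c(aI = 1))
  expect_equal(sum(prof$proportions), 1)
})

test_that("deconvolution equals exact per-read identification for full-length reads", {
  panel <- shared_panel()
  ctx <- panel_context(panel)
  spec <- genotype_spec("mix", "advena", c(aI = 0.6, sI = 0.4))
  # reads spanning the whole locus cover every informative site
  cfg <- read_sim_config(read_length = 600, coverage = 60, error_rate = 0,
                         seed = 34)
  rs <- simulate_short_reads(spec, panel, cfg, loci = "ITS")$ITS
  aln <- map_reads(rs$sequence, ctx$map_ref$ITS)
  prof <- deconvolve_its(aln, ctx$info, specimen_id = "mix")
  # oracle: classify each read by whole-sequence Hamming distance to the
  # candidate templates
  tmpl <- c(aI = panel_ref(panel, "ITS", "advena", "I")$sequence,
            aII = panel_ref(panel, "ITS", "advena", "II")$sequence,
            sI = panel_ref(panel, "ITS", "setaceum", "I")$sequence,
            sII = panel_ref(panel, "ITS", "setaceum", "II")$sequence)
  hamming <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  calls <- vapply(rs$sequence, function(r) {
    d <- vapply(tmpl, hamming, numeric(1), x = r)
    names(which.min(d))
  }, character(1))
  want <- table(calls) / length(calls)
  expect_equal(sort(names(prof$proportions)), sort(names(want)))
  expect_equal(as.numeric(prof$proportions[names(want)]),
               as.numeric(want), tolerance = 1e-12)
  # and the oracle equals the generator truth here
  expect_equal(unname(calls), rs$label)
})

test_that("profiles sum to one and tied votes are reallocated proportionally", {
  panel <- shared_panel()
  ctx <- panel_context(panel)
  set.seed(35)
  for (mix in list(c(aI = 0.55, aII = 0.45), c(sI = 0.7, sII = 0.3),
                   c(aI = 0.45, aII = 0.15, sI = 0.40))) {
    spec <- genotype_spec("m", "advena", mix)
    rs <- simulate_short_reads(spec, panel,
                               read_sim_config(coverage = 300, seed = 36),
                               loci = "ITS")
    aln <- map_reads(rs$ITS, ctx$map_ref$ITS)
    prof <- deconvolve_its(aln, ctx$info, specimen_id = "m")
    expect_equal(sum(prof$proportions), 1, tolerance = 1e-9)
    expect_equal(sort(names(prof$proportions)), sort(names(mix)))
    expect_true(all(abs(prof$proportions[names(mix)] - mix) < 0.08))
  }
})

test_that("a profile with no assignable reads is flagged unassigned", {
  panel <- shared_panel()
  ctx <- panel_context(panel)
  aln <- map_reads(rand_dna(150), ctx$map_ref$ITS)  # unmappable read
  prof <- deconvolve_its(aln, ctx$info, specimen_id = "none")
  expect_equal(prof$flagged, "unassigned")
  expect_equal(length(prof$proportions), 0)
  expect_equal(prof$unassigned, 1)
})

test_that("a balanced single-indel mixture is reported and skewed ones are not", {
  panel <- shared_panel()
  ctx <- panel_context(panel)
  spec <- genotype_spec("indel", "setaceum", c(sI = 0.5, sII = 0.5),
                        trnh_indel_mix = TRUE)
  rs <- simulate_short_reads(spec, panel,
                             read_sim_config(coverage = 300, error_rate = 0,
                                             seed = 37), loci = "trnH-psbA")
  aln <- map_reads(rs$`trnH-psbA`, ctx$map_ref$`trnH-psbA`)
  mix <- detect_mixed_indel(build_pileup(aln))
  expect_equal(nrow(mix), 1)
  expect_equal(mix$kind, "insertion")
  expect_lt(abs(mix$freq_with - 0.5), 0.05)
  expect_lt(abs(mix$freq_without - 0.5), 0.05)

  # single template: nothing to report
  spec2 <- genotype_spec("pure", "setaceum", c(sI = 1))
  rs2 <- simulate_short_reads(spec2, panel,
                              read_sim_config(coverage = 100, error_rate = 0,
                                              seed = 38), loci = "trnH-psbA")
  aln2 <- map_reads(rs2$`trnH-psbA`, ctx$map_ref$`trnH-psbA`)
  expect_equal(nrow(detect_mixed_indel(build_pileup(aln2))), 0)

  # 90/10: outside the reporting band
  ref <- rand_dna(60)
  counts <- matrix(0L, 5, 60)
  refch <- strsplit(ref, "")[[1]]
  for (i in 1:60) counts[match(refch[i], c("A", "C", "G", "T")), i] <- 90L
  counts[5, 30] <- 10L  # 10% deletion allele
  expect_equal(nrow(detect_mixed_indel(fab_pileup(ref, counts))), 0)
  counts[5, 30] <- 60L  # 40% deletion allele: inside the band
  expect_equal(nrow(detect_mixed_indel(fab_pileup(ref, counts))), 1)
})

test_that("variant calls export as minimal, 1-based VCF", {
  ref <- "ACGTACGTAC"
  counts <- matrix(0L, 5, 10)
  refch <- strsplit(ref, "")[[1]]
  for (i in 1:10) counts[match(refch[i], c("A", "C", "G", "T")), i] <- 50L
  counts[3, 4] <- 30L  # G allele at reference position 3 (0-based; ref T)
  p <- fab_pileup(ref, counts)
  v <- detect_variants(p, min_depth = 10, min_count = 2, min_freq = 0.05)
  path <- tempfile(fileext = ".vcf")
  write_variant_vcf(v, ref, "rbcL", path)
  lines <- readLines(path)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  body <- lines[!startsWith(lines, "#")]
  rows <- grep("\tG\t", body, value = TRUE)
  expect_true(any(startsWith(body, "rbcL\t4\t")))  # 0-based 3 -> 1-based 4
  unlink(path)
})
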