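# Synthetic-data generator: panel structure, genotype scenarios, short
# reads and Sanger pairs.

test_that("panel generation is deterministic and respects feasibility limits", {
  p1 <- make_reference_panel(panel_config(seed = 7))
  p2 <- make_reference_panel(panel_config(seed = 7))
  expect_identical(lapply(p1, `[[`, "sequence"), lapply(p2, `[[`, "sequence"))
  p3 <- make_reference_panel(panel_config(seed = 8))
  expect_false(identical(p1[["rbcL|advena"]]$sequence,
                         p3[["rbcL|advena"]]$sequence))
  expect_error(panel_config(rbcl_length = 100, rbcl_diff = 80),
               "infeasible")
  expect_error(panel_config(its_identity = 0), "its_identity")
})

test_that("intra-specific ITS variants differ at the configured SNPs and nowhere else", {
  panel <- shared_panel()
  a1 <- panel_ref(panel, "ITS", "advena", "I")$sequence
  a2 <- panel_ref(panel, "ITS", "advena", "II")$sequence
  s1 <- panel_ref(panel, "ITS", "setaceum", "I")$sequence
  s2 <- panel_ref(panel, "ITS", "setaceum", "II")$sequence
  hamming <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  expect_equal(hamming(a1, a2), 3)
  expect_equal(hamming(s1, s2), 2)
  # species divergence and variant SNPs are disjoint
  div <- hamming(a1, s1)
  expect_equal(hamming(a2, s1), div + 3)
  expect_equal(hamming(a1, s2), div + 2)
})

test_that("the trnH-psbA setaceum haplotypes differ by exactly one insertion", {
  panel <- shared_panel()
  v1 <- panel_ref(panel, "trnH-psbA", "setaceum", "I")$sequence
  v2 <- panel_ref(panel, "trnH-psbA", "setaceum", "II")$sequence
  expect_equal(nchar(v2), nchar(v1) + 1)
  aln <- align_pair(v1, v2)
  gaps <- which(strsplit(aln$a, "")[[1]] == "-")
  expect_equal(length(gaps), 1)
  expect_equal(gsub("-", "", aln$a), v1)
})

test_that("the bundled scenarios carry the reported genotype structure", {
  sc <- cultivar_scenarios()
  expect_length(sc, 13)
  expect_equal(sc[["Cherry Sparkler"]]$its_mixture,
               c(aI = 0.45, aII = 0.15, sI = 0.40))
  expect_equal(sc[["Sky Rocket"]]$its_mixture,
               c(aI = 0.20, aII = 0.50, sI = 0.30))
  expect_equal(sc[["Mooney 9419"]]$its_mixture, c(sI = 0.30, sII = 0.70))
  expect_equal(sc[["Simons 2006"]]$its_mixture, c(sI = 0.70, sII = 0.30))
  expect_true(sc[["Simons 2006"]]$trnh_indel_mix)
  expect_equal(sum(vapply(sc, function(s) s$trnh_indel_mix, logical(1))), 1)
  chloro <- vapply(sc, function(s) s$chloroplast_species, character(1))
  expect_equal(sum(chloro == "advena"), 7)
  expect_equal(sum(chloro == "setaceum"), 6)
  for (s in sc) expect_equal(sum(s$its_mixture), 1)
  expect_error(genotype_spec("x", "advena", c(aI = 0.7, sI = 0.2)), "sum to 1")
  expect_error(genotype_spec("x", "advena", c(0.5, 0.5)), "named")
})

test_that("error-free single-variant reads are exact template substrings", {
  panel <- shared_panel()
  spec <- genotype_spec("pure", "advena", c(aI = 1))
  rs <- simulate_short_reads(spec, panel,
                             read_sim_config(coverage = 30, error_rate = 0,
                                             seed = 5), loci = "ITS")$ITS
  tmpl <- panel_ref(panel, "ITS", "advena", "I")$sequence
  expect_true(all(rs$label == "aI"))
  expect_equal(rs$sequence,
               substring(tmpl, rs$start + 1, rs$start + 150))
  # read count approximates coverage * length / read length
  expect_equal(nrow(rs), round(30 * 600 / 150))
})

test_that("setaceum chloroplast reads carry the setaceum allele at diagnostic sites", {
  panel <- shared_panel()
  sites <- diagnostic_sites(panel_ref(panel, "rbcL", "advena"),
                            panel_ref(panel, "rbcL", "setaceum"))
  spec <- genotype_spec("set", "setaceum", c(sI = 1))
  rs <- simulate_short_reads(spec, panel,
                             read_sim_config(coverage = 100, error_rate = 0,
                                             seed = 6), loci = "rbcL")$rbcL
  for (k in seq_len(nrow(sites))) {
    pos <- sites$pos_s[k]  # 0-based on the setaceum template
    covers <- rs$start <= pos & pos < rs$start + 150
    got <- substring(rs$sequence[covers], pos - rs$start[covers] + 1,
                     pos - rs$start[covers] + 1)
    expect_true(all(got == sites$allele_s[k]))
  }
})

test_that("mixture allele frequencies converge to the configured proportions", {
  panel <- shared_panel()
  spec <- genotype_spec("mix", "advena", c(aI = 0.55, aII = 0.45))
  # coverage 1000: binomial check on the template draw at each informative site
  rs <- simulate_short_reads(spec, panel,
                             read_sim_config(coverage = 1000, seed = 9),
                             loci = "ITS")$ITS
  f <- mean(rs$label == "aI")
  expect_lt(abs(f - 0.55), 3 * sqrt(0.55 * 0.45 / nrow(rs)) + 0.001)
  # coverage 10,000: within 2 percentage points
  rs <- simulate_short_reads(spec, panel,
                             read_sim_config(coverage = 10000, seed = 9),
                             loci = "ITS")$ITS
  expect_lt(abs(mean(rs$label == "aI") - 0.55), 0.02)
})

test_that("short-read simulation is reproducible bit-for-bit under a fixed seed", {
  panel <- shared_panel()
  spec <- genotype_spec("det", "setaceum", c(sI = 0.5, sII = 0.5))
  cfg <- read_sim_config(coverage = 50, seed = 123)
  r1 <- simulate_short_reads(spec, panel, cfg)
  r2 <- simulate_short_reads(spec, panel, cfg)
  expect_identical(r1, r2)
})

test_that("pure-template Sanger pairs reproduce the template without ambiguity", {
  panel <- shared_panel()
  spec <- genotype_spec("pure", "advena", c(aI = 1))
  pair <- simulate_sanger_pair(spec, panel, "ITS", error_model = "none",
                               seed = 1)
  tmpl <- panel_ref(panel, "ITS", "advena", "I")$sequence
  expect_equal(pair$fwd$bases, substr(tmpl, 1, 500))
  expect_equal(pair$rev$bases,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(tmpl, 101, 600)))))
  expect_false(grepl("[^ACGT]", pair$fwd$bases))
})

test_that("a balanced SNP mixture emits IUPAC codes exactly at the mixed sites", {
  panel <- shared_panel()
  a1 <- panel_ref(panel, "ITS", "advena", "I")$sequence
  a2 <- panel_ref(panel, "ITS", "advena", "II")$sequence
  spec <- genotype_spec("mix", "advena", c(aI = 0.55, aII = 0.45))
  pair <- simulate_sanger_pair(spec, panel, "ITS", error_model = "none",
                               seed = 2)
  diff_pos <- which(strsplit(a1, "")[[1]] != strsplit(a2, "")[[1]])
  fwd <- strsplit(pair$fwd$bases, "")[[1]]
  amb <- which(!fwd %in% c("A", "C", "G", "T"))
  expect_equal(amb, diff_pos[diff_pos <= 500])
  for (p in amb) {
    want <- sort(c(substr(a1, p, p), substr(a2, p, p)))
    expect_equal(sort(iupac_bases(fwd[p])), want)
  }
  # a minority below the secondary-peak threshold is not called
  spec2 <- genotype_spec("min", "advena", c(aI = 0.9, aII = 0.1))
  pair2 <- simulate_sanger_pair(spec2, panel, "ITS", error_model = "none",
                                seed = 3)
  expect_false(grepl("[^ACGT]", pair2$fwd$bases))
})

test_that("a single-indel mixture collapses both strands downstream of the indel", {
  panel <- shared_panel()
  spec <- genotype_spec("indel", "setaceum", c(sI = 0.5, sII = 0.5),
                        trnh_indel_mix = TRUE)
  pair <- simulate_sanger_pair(spec, panel, "trnH-psbA",
                               error_model = "none", seed = 4)
  v1 <- panel_ref(panel, "trnH-psbA", "setaceum", "I")$sequence
  v2 <- panel_ref(panel, "trnH-psbA", "setaceum", "II")$sequence
  pre <- 0
  while (substr(v1, pre + 1, pre + 1) == substr(v2, pre + 1, pre + 1))
    pre <- pre + 1
  # forward strand: clean up to the indel, low-quality beyond it
  # (the read-end quality decay may also dip below 30 near the tail,
  # so the high-quality check stops before the decay region)
  nfwd <- length(pair$fwd$qualities)
  expect_true(all(pair$fwd$qualities[seq_len(min(pre, nfwd - 50))] >= 30))
  expect_true(all(pair$fwd$qualities[(pre + 1):nfwd] < 30))
  expect_equal(substr(pair$fwd$bases, 1, pre), substr(v2, 1, pre))
  # reverse strand mirrors from its own end
  nrev <- length(pair$rev$qualities)
  suf <- nchar(v1) - pre
  expect_true(all(pair$rev$qualities[seq_len(min(suf, nrev - 50))] >= 30))
  expect_true(all(pair$rev$qualities[(suf + 1):nrev] < 30))
})

test_that("fixture sets are written byte-identically under the same seed", {
  panel <- shared_panel()
  sc <- cultivar_scenarios()[c("Rubrum", "Simons 2006")]
  cfg <- read_sim_config(coverage = 40, seed = 31)
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture_set(panel, sc, cfg, d1)
  write_fixture_set(panel, sc, cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  unlink(c(d1, d2), recursive = TRUE)
})
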