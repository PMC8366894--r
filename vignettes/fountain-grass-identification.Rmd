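---
title: "Identifying fountain grass species and hybrid cultivars from barcode data"
author: "pennid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying fountain grass species and hybrid cultivars from barcode data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The identification model

Two closely related fountain grasses must be separated: *Pennisetum
setaceum*, an invasive species, and *P. advena*, the non-invasive parent
of the common ornamental cultivars. The model behind `pennid` rests on
three marker properties:

1. **Fixed chloroplast differences.** rbcL and the trnH-psbA spacer carry
   2 and 4 fixed inter-specific substitutions. A specimen's haplotype at
   these *diagnostic sites* is `a` (advena), `s` (setaceum), `mixed`
   (both alleles present), or `unresolved`. Because plastids are
   maternally inherited in these grasses, the chloroplast haplotype also
   names the seed parent; this inheritance assumption is encoded
   explicitly and surfaces as the `maternal_lineage` field.
2. **ITS divergence and intragenomic variation.** The nuclear ribosomal
   ITS region differs ~10% between the species, and each species carries
   two intragenomic variants (aI/aII three SNPs apart; sI/sII two SNPs
   apart) — expected in polyploids with many rDNA copies. Within one
   specimen the variants occur in measurable proportions.
3. **Hybrid additivity.** A hybrid inherits ITS variants from both
   parents. The verdict rule is: *hybrid* iff the estimated ITS profile
   puts at least `hybrid_floor` (default 0.10) of its mass on a variant
   of each species; otherwise the ITS species, provided it agrees with
   the chloroplast haplotypes, else *indeterminate* with a conflict note.
   Conflicting chloroplast loci (one `a`, one `s`) never produce a
   maternal-lineage claim.

Morphology (stipe length 0.3–1.1 mm vs 1.1–3.1 mm, leaf width, posture,
blade form) is scored against reference ranges as corroborating evidence
only; it never overrides the molecular verdict, because the cultivars'
leaf measurements stray well outside the wild-type ranges while the
molecular markers stay fixed.

## Estimating ITS variant proportions

Short reads are mapped to a single ITS reference (variant aI, the
informative-site anchor) by affine-gap semi-global alignment; a read
covering at least one *informative site* (a position at which at least
two of the four variant haplotypes differ) is scored by Hamming distance
to every candidate variant restricted to the sites it covers, and votes
for the nearest.

A read whose covered sites cannot separate a subset of labels — e.g. a
read from aI that happens to cover none of the three aI/aII SNPs — ties.
Splitting ties equally would drag nested label pairs toward 50/50: with
the default geometry roughly a third of within-species reads tie, an
asymmetry that biases the species split by several percentage points and
does not vanish with coverage. `pennid` therefore reallocates each tied
vote proportionally to the unambiguous vote shares *within the tied
subset* (an equal split is used only when no unambiguous evidence
exists). This one-pass reallocation is deterministic and consistent: the
unambiguous reads estimate the within-subset ratio without bias, so the
estimator converges to the true proportions as coverage grows. A full EM
over partially covering reads would add little here and is deliberately
not used. Labels below a noise floor of 0.03 — the error-driven
false-vote level at the default error rate — are dropped and the mass
renormalized, which prevents spurious hybrid calls.

## Sanger consensus building

Bidirectional trace reads are modelled as IUPAC base strings with PHRED
qualities. Processing follows common trace-assembly practice, with every
rule explicit and testable:

* **Quality trimming** retains the longest run in which every sliding
  10-base window has mean quality above 30, then drops boundary bases at
  or below the floor. Windowed trimming is used instead of a per-base
  floor because per-base trimming fragments otherwise good reads.
* **Primer trimming** removes a prefix/suffix matching either primer or
  its reverse complement with up to 2 mismatches; never internal edits.
* **Assembly** reverse-complements the reverse read, aligns the strands
  ends-free with IUPAC-compatible scoring, and merges per column: equal
  calls keep their base with summed quality (capped at 93); overlapping
  base sets merge into the covering IUPAC code; disagreeing concrete
  calls take the higher-quality base when the PHRED gap reaches 10,
  otherwise the covering code. Assembly *fails* when the overlap is under
  50 columns or under 80% identity — thresholds chosen so that clean
  amplicons never fail while the diagnostic failure mode always does:
  when a specimen co-amplifies two haplotypes differing by a single
  indel, every position downstream of the indel becomes a superposition
  of two frames, both strands collapse from their respective ends, and
  the surviving high-quality segments no longer overlap. The pipeline
  then falls back to short reads for that locus, detects the indel
  mixture from the pileup (an insertion or deletion allele at 0.2–0.8
  frequency, depth ≥ 10), and reports both haplotypes.

## Variant calling

Pileup variant calls require depth ≥ 10, count ≥ 2 and frequency ≥ 0.05.
The frequency floor is set well below the smallest real component the
method must detect (the 15% aII fraction in one hybrid cultivar) and
well above the per-base error rate (≤ 1%); calls are monotone in all
three thresholds. Insertions anchor to the reference position on their
left; all coordinates are 0-based half-open internally, converting to
1-based only on VCF export.

## Alignment engine

All comparisons are pairwise (no MSA, no phylogenetics): global
end-to-end alignment for reference comparisons, ends-free for strand
merging, semi-global (read global, reference ends free) for mapping.
Scoring is match +1, mismatch −1, gap open −3, gap extend −1 — steep gap
penalties so that near-identical barcode amplicons align gaplessly unless
an indel is real. Percent identity counts all alignment columns after
stripping single-sequence overhangs, internal gaps scoring as
differences; whether indel columns belong in the ITS identity denominator
is genuinely open, and this is one defensible, reproducible choice. Ties
among co-optimal alignments prefer a substitution over a gap and then a
fixed traceback order, so results are deterministic. The engine is
implemented in C++ (Gotoh three-state DP) for per-read throughput; its
scores are cross-checked in the test suite against exhaustive search on
short pairs and against `Biostrings::pairwiseAlignment` on longer ones.
Reads are mapped when aligned identity reaches 0.8 — permissive enough
that setaceum reads (~11% divergent) map onto the advena ITS anchor,
strict enough that unrelated sequence (~25% expected identity) never
does.

## What the synthetic generator emulates

The generator is the package's study population, with defaults fixed to
the observed divergence structure:

| quantity | default |
|---|---|
| locus lengths (rbcL / trnH-psbA / ITS) | 550 / 400 / 600 nt |
| inter-species substitutions (rbcL / trnH-psbA) | 2 / 4 |
| ITS inter-species identity | 90% |
| ITS variant SNPs (advena / setaceum) | 3 / 2 |
| trnH-psbA setaceum indel haplotypes | 1-nt insertion, present |
| pure advena ITS mixture | 55% aI / 45% aII |
| hybrid mixtures | 45/15/40 and 20/50/30 (aI/aII/sI) |
| setaceum mixtures | 70/30, 30/70 sI/sII |
| short reads | 150 nt, error 0.001, coverage 1000 |
| Sanger traces | ≤500 nt, plateau Q50, decay to Q10 over last 50 nt |

Base composition is i.i.d. uniform; planted differences avoid the
terminal 30 nt (primer-proximal regions stay clean) and are mutually
disjoint, so ITS identity is analytically controlled. The six *P.
setaceum* collections for which only variant *presence* is established
default to a 50/50 sI/sII mixture — an assumption, labelled as such. The
secondary-peak threshold for emitting an ambiguity code is a minority
proportion of 0.20, mimicking typical basecaller behaviour. All streams
derive deterministically from one master seed (per-specimen, per-locus
sub-seeds), so fixture sets and reports are byte-identical across runs.

What it does **not** emulate — and hence what passing tests cannot show
about real data: chromatogram traces and dye effects, PCR chimeras and
polymerase slippage, quality-dependent error spectra, paired-end insert
geometry, reads from the reverse strand, contamination, and cross-genus
amplification. The mapping reference is the same-species panel rather
than an outgroup (real workflows sometimes map to a related species'
reference), a deliberate simplification.

## Numerical and degenerate-input choices

* Empty quality-trimmed reads are valid flagged outcomes, not errors;
  assembling with one yields `failed_assembly`.
* A specimen whose reads cover no informative site gets an `unassigned`
  profile and an indeterminate verdict rather than a guess.
* Both chloroplast loci unresolved forces *indeterminate* regardless of
  the ITS profile.
* Diagnostic sites at which a consensus shows an ambiguity covering both
  alleles make the locus `mixed`; fewer than half the sites resolvable
  makes it `unresolved`; resolved-but-conflicting fixed differences also
  resolve to `unresolved` (no such case exists in the study material).
* The hybrid floor of 0.10 accepts the smallest real hybrid component
  (15%) with margin while rejecting noise-level foreign mass (≤5%).

## Problem sizes used in the checks

The test suite exercises the 13-specimen scenario set end to end at
coverage 1000 (error 0.001) and verifies mixture recovery within ±5
percentage points there and ±2 points at coverage 10,000; unit tests run
at coverages of 30–500. The acceptance script uses coverage 1000. These
sizes were chosen as the smallest at which binomial noise is comfortably
inside the stated tolerances.

## Known limitations

* Proportion estimates treat ITS read ratios as mixture proportions;
  unequal rDNA copy numbers across chromosome sets or PCR bias would be
  absorbed into the estimate, not modelled.
* No diploid/polyploid genotype likelihoods, no base-quality-aware
  calling, no chimera detection.
* The two-species design is hard-coded into the verdict logic; other
  *Pennisetum* species would map but not classify.
* Morphological ranges cover the two species only and are advisory.
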