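# pennid

Molecular identification of the ornamental fountain grasses *Pennisetum
setaceum* and *P. advena* (syn. *Cenchrus advena*), and detection of their
hybrid cultivars, from DNA barcode data.

## The problem

*P. setaceum* is a regulated invasive species in the EU, while the popular
ornamental cultivars ("Rubrum", "Fireworks", "Cherry Sparkler", "Sky
Rocket", "Summer Samba") traded under the same name belong to — or derive
from — the non-invasive *P. advena*. Telling them apart is therefore a
practical diagnostic problem for plant-protection laboratories. Three
barcode loci resolve it:

* **rbcL** and the **trnH-psbA** intergenic spacer (chloroplast): the two
  species consistently differ at **2** and **4** fixed nucleotide
  positions respectively. Because plastids are maternally inherited, these
  loci also identify the seed parent of a hybrid.
* **ITS** (nuclear ribosomal, partial 18S–ITS1–5.8S–ITS2–partial 28S): the
  species are only ~**90%** identical, and each carries two intragenomic
  variants (aI/aII in *P. advena*, 3 SNPs apart; sI/sII in *P. setaceum*,
  2 SNPs apart) whose proportions within a specimen can be estimated from
  amplicon reads. A specimen carrying ITS variants of **both** species is
  additive — evidence of hybrid origin.

## What the package does

For a specimen with bidirectional Sanger traces and/or short reads per
locus, `pennid`:

1. builds a quality-trimmed (PHRED > 30), IUPAC-coded consensus from each
   Sanger pair (`trim_quality()`, `trim_primers()`,
   `assemble_bidirectional()`); a template population segregating for a
   single indel makes both strands collapse downstream of it, which is
   detected and reported as a failed assembly;
2. maps short reads to the locus references with an affine-gap semi-global
   aligner and tallies a pileup (`map_reads()`, `build_pileup()`);
3. calls variants above depth/count/frequency floors (`detect_variants()`),
   detects segregating indels (`detect_mixed_indel()`), and deconvolves the
   intra-individual ITS variant mixture into proportion estimates by
   minimum-distance read voting with proportional tie reallocation
   (`deconvolve_its()`);
4. assigns each chloroplast locus the `a` or `s` haplotype at the
   diagnostic sites (`assign_haplotype()`) and integrates everything into a
   specimen verdict — species, hybrid status, maternal lineage — plus an
   advisory morphological range check (`call_specimen()`,
   `classify_morphology()`, `report()`).

A seeded synthetic-data generator (`make_reference_panel()`,
`simulate_short_reads()`, `simulate_sanger_pair()`,
`cultivar_scenarios()`) reproduces the divergence structure above,
including the reported per-specimen mixtures (55/45 aI/aII; 45/15/40 and
20/50/30 for the two hybrids; 70/30 and 30/70 sI/sII) and the trnH-psbA
single-indel specimen, so the whole pipeline is testable end to end.

## Worked example

```r
library(pennid)
panel <- make_reference_panel()             # synthetic two-species panel
res <- run_identification(panel = panel,
                          cfg = read_sim_config(coverage = 200, seed = 7))
res$report[, c("specimen_id", "rbcL", "trnH_psbA", "ITS", "species_verdict",
               "maternal_lineage")]
```

```
 specimen_id     rbcL trnH_psbA ITS         species_verdict maternal_lineage
 Valkenburg 4026 a    a         aI, aII     advena          advena
 Wipff 1723      a    a         aI, aII     advena          advena
 Cherry Sparkler a    a         aI, aII, sI hybrid          advena
 Fireworks       a    a         aI, aII     advena          advena
 Rubrum          a    a         aI, aII     advena          advena
 Sky Rocket      a    a         aI, aII, sI hybrid          advena
 Summer Samba    a    a         aI, aII     advena          advena
 Mooney 9419     s    s         sI, sII     setaceum        setaceum
 Simons 2006     s    sI, sII   sI, sII     setaceum        setaceum
 Valkenburg 3934 s    s         sI, sII     setaceum        setaceum
 Verloove 13345  s    s         sI, sII     setaceum        setaceum
 Verloove 13647  s    s         sI, sII     setaceum        setaceum
 Verloove 13650  s    s         sI, sII     setaceum        setaceum
```

Reading the rows: every cultivar carries the *advena* chloroplast
(`a`/`a`), so *P. advena* is the seed parent throughout; "Cherry Sparkler"
and "Sky Rocket" additionally carry the *setaceum* ITS variant sI, hence
the hybrid verdict. "Simons 2006" shows `sI, sII` at trnH-psbA: its two
chloroplast haplotypes differ by a single indel, its Sanger pair fails
bidirectional assembly, and the locus is resolved from short reads (see
the report's `notes` column). The `ITS_percent` column carries the
estimated variant proportions.

A thin command-line wrapper ships in `exec/pennid`
(`pennid simulate | run | report`, YAML-configurable seeds and
thresholds).

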