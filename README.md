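# dazzle

Annotation, haplotyping and allele-specific CpG methylation analysis of the
D4Z4 macrosatellite array from long noisy reads.

## The problem

The D4Z4 locus at chromosome 4q35 is a tandem array of 1 to >100 copies of a
~3.3 kb KpnI–KpnI repeat unit, each carrying a partial *DUX4* copy.
Facioscapulohumeral muscular dystrophy (FSHD) arises when *DUX4* silencing is
lost: by contraction of the array to 1–10 repeat units (FSHD1) or by
pathogenic variants in chromatin modifiers such as *SMCHD1* (FSHD2), in both
cases on a permissive **4qA** haplotype whose distal **pLAM** sequence carries
the *DUX4* poly(A) signal. A ~98%-identical non-pathogenic array sits at
10q26; 4q and 10q units are classically told apart by the 4q-specific XapI
and 10q-specific BlnI restriction sites. The locus defeats short reads and is
frequently misassembled, but single ultra-long nanopore reads can span whole
arrays together with their flanks and simultaneously report CpG methylation.

`dazzle` is for researchers and method developers working with such reads. It
annotates raw reads directly — no whole-genome alignment step — and computes
the quantities an FSHD molecular work-up needs:

- **repeat-unit counts** per read by the KpnI–KpnI convention: full units
  (including internally truncated ones) counted, terminal partials excluded;
- **spanning classification**: a read containing both the proximal p13E-11
  flank and a distal feature (pLAM or the qB-distal sequence) covers the
  whole array;
- **haplotype calls**: chromosome (4q/10q) from upstream-flank > distal >
  per-unit XapI/BlnI evidence with translocation conflicts flagged; A/B from
  pLAM/qB; distal subtype from the distal partial-unit length
  (S ≈ 0.3 kb, M ≈ 0.6 kb, L ≈ 1.9 kb);
- **allele groups** of spanning reads keyed by (chromosome, A/B, subtype,
  exact RU structure — in-cis duplications render as e.g. `15 + 2 + 5`),
  with mosaic fractions and Wilson intervals;
- **allele consensus** sequences built by unit-anchored column voting
  (structure-preserving by construction, with a post-hoc abort if not), plus
  per-unit variant matrices versus the canonical unit;
- **methylation statistics** on allele-anchored CpG sites: pooled-count
  region means (DR1 at unit positions 563–814; *DUX4* TSS at 1688 ± 200;
  global and final-unit 5mC rates), coverage-filtered smoothed profiles,
  missing-aware autocorrelation (peaks at ~3.3 kbp and ~180 bp reflect the
  unit and nucleosome periodicities), and repeat-length-vs-methylation
  correlations;
- a fully **seeded simulator** of alleles, reads and methylation calls with
  ground truth, which is how the whole pipeline is tested at desk scale.

The methods vignette (`vignettes/dazzle-methods.Rmd`) describes every model,
default and numerical choice.

## Worked example

Simulate a mosaic 4q carrier (a contracted 3 RU and an 18 RU 4qAL allele on
4q, one 10qA allele), sequence it, and haplotype the reads:

```r
library(dazzle)

bundle <- syntheticBundle(seed = 7)
specs <- list(
  alleleSpec("contracted", "4q",  "A", "AL", structure = 3,  mosaic_fraction = 0.5),
  alleleSpec("long",       "4q",  "A", "AL", structure = 18, mosaic_fraction = 0.5),
  alleleSpec("tenq",       "10q", "A", "AS", structure = 9,  mosaic_fraction = 1))
alleles <- lapply(specs, buildAlleleSequence, bundle = bundle)

sim    <- simulateReads(alleles, 120, seed = 7)   # 3% error, lognormal lengths
anns   <- annotateReads(sim$reads, bundle)
groups <- groupAlleles(anns, bundle)
reportTable(groups)[, c("chrom", "haplotype", "ru", "n_spanning", "mosaic_fraction")]
```

```
  chrom haplotype ru n_spanning mosaic_fraction
1   10q      10qA  9          9          1.0000
2    4q      4qAL  3         11          0.7857
3    4q      4qAL 18          3          0.2143
```

Every allele is recovered with its exact repeat count and haplotype. Note the
length bias: the two 4q alleles were simulated at equal molecular fractions,
but the contracted allele yields almost four times as many spanning reads
(11 vs 3), because a fragment must exceed ~65 kb to span 18 units — the same
distortion seen in real targeted sequencing, which is why `mosaic_fraction`
is a read-level, not cell-level, estimate.

From here, `buildConsensus()` polishes each group into an allele sequence,
`callUnitVariants()` tabulates per-unit variants, and `anchorCalls()` +
`regionStats()` / `methylationAcf()` compute allele-specific methylation
statistics from per-read CpG calls (TSV dialect: `read_id`, `read_pos`,
`strand`, `prob_5mC`). A thin command-line dispatcher over these stages ships
at `inst/cli/d4z4e2e.R`.

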