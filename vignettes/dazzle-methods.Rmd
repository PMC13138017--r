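---
title: "Methods: annotating, haplotyping and methylation-profiling D4Z4 macrosatellite arrays from long reads"
author: "dazzle maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: D4Z4 array analysis from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dazzle)
```

# The problem

The D4Z4 macrosatellite at chromosome 4q35 is a tandem array of 1 to more
than 100 copies of a ~3.3 kb KpnI–KpnI repeat unit, each carrying a partial
*DUX4* copy. Facioscapulohumeral muscular dystrophy (FSHD) arises when *DUX4*
silencing fails: through array contraction to 1–10 units (FSHD1) or through
pathogenic variants in chromatin modifiers such as *SMCHD1* (FSHD2), in both
cases on a permissive "A" haplotype whose distal pLAM sequence supplies a
poly(A) signal (PAS). A nearly identical, non-pathogenic array sits at 10q26;
4q and 10q units are classically distinguished by a 4q-specific XapI and a
10q-specific BlnI restriction site. The locus is essentially invisible to
short reads and is misassembled by automated assemblers, but single ultra-long
nanopore reads can span entire arrays together with their flanks.

`dazzle` analyzes such reads directly, without a genome alignment step:

1. **annotate** — detect repeat units and flanking features in each raw read,
   segment arrays (in-cis duplications, inverted upstream units), classify
   spanning reads;
2. **haplotype** — assign 4q/10q, A/B and the distal subtype; group reads
   into alleles; estimate mosaic fractions;
3. **consensus** — build a polished allele sequence from spanning reads and
   tabulate per-unit variants;
4. **methylation** — anchor per-read CpG calls onto the allele and compute
   region statistics, smoothed profiles, autocorrelation and repeat-length
   correlations;
5. **simulate** — generate alleles, reads and methylation calls with ground
   truth, so every stage is verifiable at desk scale.

Internally all interval arithmetic is 0-based half-open; every reported
position is 1-based inclusive in unit coordinates, so that published landmark
coordinates (the DR1 window at unit positions 563–814; the *DUX4* TSS at unit
position 1688) can be used as-is.

# Read annotation

## Unit and feature detection

Reads are scanned with a seed-and-extend detector rather than an external
aligner, so results are deterministic and self-contained. k-mers (k = 15)
sampled every 25 bp from the canonical unit (and from each flanking feature)
are matched exactly against all k-mers of the read and of its reverse
complement. Anchors are chained into instances: a chain breaks when the
target coordinate wraps backwards (the next tandem copy) or when the read
advances ≥ 400 bp further than the target (spacer or foreign sequence); a
target-side jump with no read-side jump — an internal deletion — does *not*
break the chain. Instance boundaries are refined by greedy base-wise
extension toward the unit ends (stopping at four consecutive mismatches and
snapping back to the last agreeing base), which makes boundaries exact on
error-free sequence and keeps partial-unit length measurements within a few
bases otherwise. When the KpnI motif itself is corrupted by a sequencing
error, this alignment coordinate wins; counting is KpnI-defined, not
motif-defined.

Each instance's identity is the edit-distance identity of the implied
interval; instances longer than 1.5 kb are measured on a 1 kb slice centered
on their longest co-linear anchor run, which is an unbiased estimate under a
uniform error process and — deliberately — ignores large internal deletions,
which are structural events, not base-level error. Hits with identity below
`min_unit_identity` (default 0.70, tolerant of older pore chemistries) are
dropped. The published workflows do not state their identity or
mapping-quality cut-offs; this default is a design decision of this package.

## Completeness and the counting convention

A unit instance is classified by which unit ends its anchors (after boundary
extension) reach: both ends → `full`, or `truncated_internal` when the read
span falls ≥ 500 bp short of the unit length (an internal deletion; such
units still count); the KpnI-proximal end only → a distal-type partial; the
KpnI-distal end only → a proximal-type partial. Repeat-unit counts are the
number of `full` + `truncated_internal` units, excluding terminal partials —
the KpnI–KpnI counting convention used in current guidelines. This convention
is why a unit carrying a ~1.2 kb internal deletion is included in the count
while the ~0.3/0.6/1.9 kb distal partial that defines the S/M/L subtypes is
not.

## Array segmentation

Ordered unit hits are split into segments where the read-space gap reaches
`spacer_min_gap` (default 4000 bp) or the strand flips. Observed spacers in
in-cis duplicated alleles run ~6.5–20 kb while intra-array gaps are far below
1 kb, so the threshold separates duplication structures without splitting
noisy arrays. A minus-strand segment on the proximal side of the main array
is flagged as an inverted upstream unit/array (the D4S2463 configuration
found ~42 kb upstream of 4q arrays).

## Motifs

XapI (RAATTY), BlnI (CCTAGG), KpnI (GGTACC), the 4q/10q PAS variants
(defaults ATTAAA / ATCAAA, overridable — the PAS sequences are not printed in
the source descriptions of the workflow and come from prior literature), the
telomeric repeat, and any user-supplied motifs are scanned by exact IUPAC
matching on both strands, degenerate codes expanded at scan time. Telomeric
annotation flags runs of ≥ 8 consecutive TTAGGG; full repeat-family HMM
scanning is out of scope, but additional motifs (e.g. a beta-satellite probe)
can be supplied.

# Haplotyping

Three evidence levels feed the chromosome call, in fixed precedence:

1. **upstream unique flank** — only observable when the read extends beyond
   the ~42 kb 4q/10q homology region; locus-unique, therefore decisive;
2. **distal evidence** — the chromosome-unique downstream flank and the PAS
   variant inside the pLAM hit;
3. **per-unit XapI/BlnI majority** — each detected unit is genotyped at the
   diagnostic site coordinates (positions known per bundle), and units vote.

The precedence ordering is a design decision (the published description
lists the sources without ordering them): flank evidence is unique in the
genome, whereas motifs recur per unit and are individually error-prone.
Disagreement between levels sets a `conflict` flag while the higher level
wins — this is exactly the 4q-to-10q translocation configuration (10q flanks
over XapI-carrying units), which is reported rather than silently resolved.

A/B comes from the distal feature: pLAM → A, qB → B; a bundle without the qB
sequence disables B-haplotyping with a warning at load time. A-type alleles
are subtyped by the distal partial unit length: S ≤ 450 bp, M in (450, 1000],
L ≥ 1500 (defaults bracketing the observed ~0.3, ~0.6 and ~1.9 kb distal
units; lengths between bins return "unknown" rather than guessing).

Spanning reads (p13E-11 plus a distal feature present) are grouped by the
exact key (chromosome, A/B, subtype, RU structure); no ±1 merging is applied
because published spanning-read counts are exact. Nonspanning reads attach to
a group only when exactly one group is compatible with their evidence
(chromosome, A/B, subtype when known, and observed RU count ≤ group RU) — a
reconstruction of the narrative "confidently assigned" rule in the source
description. The mosaic fraction of a group is its share of same-chromosome
spanning reads with a 95% Wilson interval; because spanning probability falls
steeply with array length, this is a read-level, not cell-level, proportion —
the simulator's fragment-length model reproduces exactly this distortion.
Two alleles identical in every key are indistinguishable from reads and
collapse into one group; single-group chromosomes carry a note to that
effect.

# Consensus and unit variants

The consensus engine replaces an external polisher with the same contract.
The longest spanning read is the backbone; every member read is oriented and
anchored to it **unit-by-unit** before any base-level alignment — each unit
and each inter-unit interval aligns only to its positional counterpart. This
is the step that prevents the repeat-register slippage generic polishers
suffer on macrosatellites and the reason the engine can guarantee structure
preservation. Per column, votes (A/C/G/T/N/gap) are tallied across reads with
ties broken toward the backbone (determinism); insertions are adopted when
more than half of the covering reads agree on the identical inserted string.
Block alignments are computed with 50 bp margins into the neighboring blocks
and scored only over the core columns, so alignment edge artifacts fall
outside the vote. Two polishing rounds are applied (the published two-step
description gives no round count; two rounds with re-annotation between them
is this package's default, and from the second round on every member read —
including the original backbone — votes against the current template). After
polishing, the consensus is re-annotated; any change in RU structure aborts
with a diagnostic — a restructured consensus is never emitted. A group with
one spanning read passes through unpolished and flagged.

On the simulator's default error profile (3% total) with ten spanning reads
over a 5-unit allele, the consensus reaches ≥ 99.9% identity to the true
allele sequence, and is always closer to the truth than the median member
read (both properties are asserted in the test suite).

Units extracted from a consensus are each globally aligned to the canonical
unit (match +1, mismatch −1, gap open −2, extend −1; the published pipeline
does not state scoring) and their variants tabulated as events (SNV,
insertion, deletion) in canonical coordinates. Whether a unit is aligned
globally or to a local canonical window is decided from seed coverage, not
length, so an internally deleted unit is aligned globally and its deletion
becomes an event, while a true terminal partial maps to its window with
everything outside recorded as missing. Applying a unit's events back onto
the canonical unit reconstructs the unit byte-exactly (asserted as an
involution test). The display rule that hides indels < 4 nt not shared
between units is applied only at render time; storage always keeps every
event. Allele comparison normalizes disagreement by event length per unit
and calls identical / related (≥ 0.98) / distinct, with disagreement at the
XapI/BlnI diagnostic columns forcing "distinct".

# Methylation

Per-read CpG calls are consumed from a plain TSV dialect (`read_id`,
`read_pos` 0-based position of the CpG C on the read forward strand,
`strand`, `prob_5mC`); modified-base BAMs can be converted upstream so the
core never needs BAM. A call is methylated when `prob_5mC` ≥ 0.5 — a call at
exactly 0.5 counts methylated (threshold is ≥; the published description is
silent on the boundary).

Calls are lifted onto the allele reference (consensus, or the longest
spanning read as surrogate) through the unit-anchored coordinate map: seed
anchors of positionally matched unit instances plus matched feature
endpoints, linearly interpolated between anchors, snapped to the nearest
reference CpG within 3 bp. Spanning reads match units 1:1; nonspanning reads
anchor from whichever array end they cover; interior-only reads are
ambiguous in a tandem repeat and are skipped with a count. Counts are pooled
per site and strand-combined.

All rates are pooled-count means — total methylated calls over total calls —
never means of site means: the global rate over the array span, the
final-full-unit rate, and per-unit DR1 (unit positions 563–814) and TSS
(1688 ± 200) window means. Regions with zero calls yield NA, not 0. Site-level
profile statistics (smoothing, autocorrelation) additionally require site
coverage ≥ 5.

The smoothed profile is a running coverage-weighted mean over a 2000 bp
window (weighting by coverage is a choice exposed as a flag; the published
plots do not state theirs), with a loess alternative (span 0.2).

The autocorrelation is computed on a vector of length n (the reference
length) holding %5mC at covered CpG sites and NA elsewhere. Because a stock
autocorrelation routine fed NAs either fails or propagates them, the
estimator is defined explicitly as pairwise-complete: mean and variance over
observed entries, lag-l covariance over pairs with both entries observed,
normalized by the variance; acf(0) = 1 by construction. On fully observed
vectors it matches the standard biased estimator up to pair-count
normalization; results may therefore differ from an NA-passing standard
routine, which is documented here deliberately. Because CpG sites sit at
irregular positions, the number of pairs at any exact integer lag is small;
the dominant-peak locator therefore takes the argmax of an 11-lag moving
average of the ACF. In simulations carrying the within-unit DR1/TSS
oscillation, the long-range ACF (lags to 10,000 nt) peaks at the unit length
(~3.3 kbp); with the 180 bp nucleosome-scale cosine component, the
short-range ACF (lags to 500 nt) peaks near 180 bp.

One interaction deserves emphasis: in the generator, the DR1/TSS oscillation
is a sharp-edged box, and box edges dominate the short-lag ACF, masking the
weak 180 bp ripple. Real arrays do not have this problem to the same degree
(their within-unit profile is smooth). The nucleosome-periodicity scenario
therefore isolates the nucleosome component (DR1/TSS amplitudes set to zero
for that run), and uses a 25-unit array at 30× coverage so that each exact
lag has enough site pairs for a stable peak estimate. The unit-periodicity
scenario uses the full default model on a 30-unit array at 20×.

Repeat-length-versus-methylation correlations (Pearson and Spearman, with
linear-fit parameters) are computed per cohort on ≥ 3 alleles; degenerate
variance yields NA.

# The simulator

The generator is first-class, tested code that defines the study conditions.

**Sequences.** All synthetic features are uniform-random DNA with diagnostic
motifs planted at fixed offsets: the canonical unit is 4qA-type (KpnI at
position 1, XapI at 1525, a BlnI near-miss at 2210) and 10q-type units are
derived by the two SNVs that destroy XapI and create BlnI; pLAM carries the
PAS at offset 400, mutated to the 10q variant for 10q alleles; D4S2463 is
the reverse complement of the distal 1.5 kb of the unit. Stray motif matches
are scrubbed so the planted sites are the only diagnostic signal. The shared
4q/10q upstream homology region defaults to 42 kb — the distance over which
the two subtelomeres are indistinguishable — so chromosome assignment from
upstream flanks genuinely requires reads that long. CpG positions are the
natural CG dinucleotides of the generated sequence (~1 per 16 bp in uniform
random DNA): denser than and statistically equivalent to planting sites every
25 ± 10 bp, and guaranteed not to corrupt planted motifs.

**Alleles.** A specification gives chromosome, A/B, subtype (distal partial
~300/600/1900 bp), per-segment RU counts with spacer lengths (spacers are
drawn from a single subtelomeric pool, mirroring the observation that
duplication spacers reuse distal subtelomeric sequence), leading proximal
partials for duplicated segments, inverted upstream units, an optional
internally deleted unit, a translocation flag (unit/pLAM identity swapped
against flank identity) and a mosaic weight.

**Reads.** Fragments are sampled by allele mosaic weight with a lognormal
length model (median ~40 kb), placed uniformly, strand randomized, and
per-base errors injected at 1.5% substitutions, 0.75% insertions and 0.75%
deletions — a ~3% aggregate profile typical of older pore chemistries
(configurable). The length model is what makes spanning reads for short
arrays vastly outnumber those for long arrays, the same distortion seen in
targeted sequencing. `length_bias = FALSE` emits whole-molecule reads for
controlled experiments, and a guaranteed-spanning generator exists for
single-read tests. Everything is reproducible from a seed, including the
per-base coordinate map from allele to read positions that methylation
simulation consumes.

**Methylation.** Site rates compose: a logistic proximal-to-distal gradient
in cumulative unit index (0.30 at the proximal end rising to a 0.85 plateau,
midpoint unit 5, scale 1.5 — plateau around unit ten); a flat 0.08 for
contracted arrays (≤ 4 RU, matching the severe 1–4 RU range; published
contracted final-unit rates fall in 0.064–0.097); DR1 depression (−0.4) and
TSS elevation (+0.3) — amplitudes are not published and these are exposed
placeholders; a 180 bp cosine (amplitude 0.10); flat 0.70 outside the array
and 0.15 over inverted upstream units (hypomethylated, as observed); and a
global SMCHD1 factor (1 wild type, 0.3 in mutant-cohort examples). Rates are
clipped to [0.01, 0.99]; per-read calls are Bernoulli draws emitted as
0.98/0.02 ± 0.015 jitter so thresholding is genuinely exercised.

**What the simulator does not emulate** — and therefore what passing tests do
not show about real data: real D4Z4 sequence composition (GC content, CpG
islands, the actual unit sequence and its subhaplotype variant spectrum),
basecaller-specific error structure (homopolymer compression, methylation-
dependent miscalls), per-unit sequence heterogeneity within an array beyond
the planted diagnostics, cell-type methylation differences, and any coupling
between sequence errors and methylation calls. Tests prove the machinery —
counting, segmentation, evidence logic, consensus fidelity, estimator
correctness — under a controlled error model, not performance on clinical
samples.

# Numerical choices and desk scales

| Parameter | Default | Why |
|---|---|---|
| `seed_k` / `seed_stride` | 15 / 25 bp | unique 15-mers in a 3.3 kb unit; ~10 seeds per 250 bp boundary tolerance keeps terminal-partial classification robust at 3% error |
| `min_unit_identity` | 0.70 | tolerant of older-chemistry error; not a published value |
| `spacer_min_gap` | 4000 bp | between intra-array gaps (≪ 1 kb) and observed spacers (6.5–20 kb) |
| `boundary_tol` / `trunc_tol` | 250 / 500 bp | anchor-coverage tolerance; truncation-vs-full margin |
| `subtype_bins` | 450 / 1000 / 1500 bp | brackets ~0.3 / ~0.6 / ~1.9 kb distal units |
| `meth_call_threshold` | 0.5 (≥) | published threshold; boundary behavior documented |
| `min_site_coverage` | 5 | published site filter |
| `smoothing_window` | 2000 bp | published smoothing window |
| ACF lags | 10,000 / 500 nt | published lag ranges (~3 units / nucleosome scale) |
| `loess_span` | 0.2 | published span |
| `consensus_rounds` | 2 | two-step contract; round count is ours |

Test and acceptance problem sizes are deliberately desk-scale: structure
round-trips use single reads of alleles up to 40 RU (~137 kb reads);
consensus fidelity uses 10 reads over a 5 RU allele; methylome scenarios use
20–30× coverage over 12–30 RU alleles; the mosaic-fraction replicate study
runs 25 whole-molecule replicates; cohort separation uses five RU levels per
cohort at 5×. Tests that annotate many whole-molecule reads use a
reduced-homology bundle (2 kb instead of 42 kb) where the homology length is
irrelevant to the property under test.

# Known limitations

* Interior-only reads (no array end in view) cannot be placed within a
  tandem array and are excluded from methylation anchoring; they still
  contribute lower-bound RU counts.
* Identity of long unit instances is estimated on a 1 kb anchored slice, so
  a pathologically localized error burst could pass the identity filter.
* Homozygous or otherwise key-identical alleles collapse into one group;
  resolving them needs external information (e.g. pedigree or variant
  phasing), which is out of scope.
* The evidence precedence (flank > distal > motif) will report, not resolve,
  genuinely contradictory rearrangements beyond the translocation pattern.
* Consensus building needs at least one spanning read; alleles seen only in
  nonspanning reads get a surrogate reference (longest read), with
  correspondingly local methylation anchoring.
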