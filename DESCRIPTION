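Package: dazzle
Title: Annotation, Haplotyping and Methylation Analysis of D4Z4 Macrosatellite
    Arrays from Long Reads
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of the D4Z4 macrosatellite repeat at
    chromosome 4q35 (and its 10q26 homolog) from long noisy reads, as used in
    the molecular work-up of facioscapulohumeral muscular dystrophy (FSHD).
    Detects and counts KpnI-KpnI D4Z4 repeat units in raw reads, annotates
    flanking features (p13E-11, pLAM, qB-distal), scans diagnostic restriction
    motifs (XapI, BlnI) and poly(A) signals, classifies spanning reads, assigns
    4q/10q and A/B haplotypes and distal subtypes (4qAS/4qAM/4qAL), resolves
    mosaicism and in-cis duplicated or inverted arrays, builds allele consensus
    sequences with per-unit variant matrices, and computes allele-anchored CpG
    methylation statistics (region means, smoothed profiles, missing-aware
    autocorrelation, repeat-length correlations). A seeded simulator generates
    alleles, reads and methylation calls with ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, Epigenetics, MethylSeq, Coverage,
    StructuralVariation
RoxygenNote: 7.3.3
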