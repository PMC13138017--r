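# Reference bundle, motif set, unit coordinate conventions and pipeline
# parameters. Every other module consumes these objects.
#
# Coordinates: internal arithmetic is 0-based half-open; every position in a
# reported table or printed object is 1-based inclusive, matching the unit
# coordinate convention used in the field (DR1 at unit positions 563-814).

## ---------------------------------------------------------------------------
## MotifSet

#' Diagnostic motif set
#'
#' Holds the IUPAC motifs scanned in every read: the XapI (RAATTY) and BlnI
#' (CCTAGG) restriction sites whose per-unit presence distinguishes 4q from
#' 10q repeat units, the KpnI site (GGTACC) bounding each repeat unit, the
#' chromosome-specific poly(A)-signal variants carried by pLAM, the telomeric
#' repeat, and any user-supplied extra motifs (e.g. a beta-satellite probe).
#' Degenerate IUPAC codes are kept degenerate and expanded at scan time.
#'
#' @slot motifs named character vector of IUPAC motifs.
#' @export
setClass("MotifSet", representation(motifs = "character"))

setValidity("MotifSet", function(object) {
  m <- object@motifs
  if (is.null(names(m)) || any(!nzchar(names(m))))
    return("all motifs must be named")
  if (any(!nzchar(m))) return("motifs must be nonempty")
  if (any(grepl("[^ACGTRYSWKMBDHVN]", m)))
    return("motifs must be IUPAC nucleotide strings")
  need <- c("xapi", "blni", "kpni", "pas_4qA", "pas_10qA", "telomere")
  if (!all(need %in% names(m)))
    return(paste("missing motifs:", paste(setdiff(need, names(m)), collapse = ", ")))
  if (m[["pas_4qA"]] == m[["pas_10qA"]])
    return("pas_4qA and pas_10qA must differ")
  TRUE
})

#' Construct a MotifSet
#'
#' @param pas_4qA,pas_10qA poly(A)-signal motifs for A-type 4q and 10q alleles.
#'   The defaults (ATTAAA / ATCAAA) come from prior literature on the PAS SNV
#'   distinguishing the two chromosomes and are overridable.
#' @param extra named character vector of additional motifs.
#' @return a \linkS4class{MotifSet}
#' @examples
#' motifSet()
#' @export
motifSet <- function(pas_4qA = "ATTAAA", pas_10qA = "ATCAAA", extra = character(0)) {
  m <- c(xapi = "RAATTY", blni = "CCTAGG", kpni = "GGTACC",
         pas_4qA = toupper(pas_4qA), pas_10qA = toupper(pas_10qA),
         telomere = "TTAGGG", toupper(extra))
  new("MotifSet", motifs = m)
}

#' @describeIn motifSet accessor for the named motif vector
#' @param x a MotifSet
#' @export
motifs <- function(x) x@motifs

setMethod("show", "MotifSet", function(object) {
  cat("MotifSet with", length(object@motifs), "motifs\n")
  for (n in names(object@motifs)) cat(sprintf("  %-10s %s\n", n, object@motifs[[n]]))
})

## ---------------------------------------------------------------------------
## UnitCoords

#' Fixed landmark coordinates within the canonical D4Z4 unit
#'
#' 1-based inclusive positions in KpnI-KpnI unit coordinates: the DR1 region
#' (563-814, distal part of the CTCF-insulator-associated segment,
#' characteristically hypomethylated) and the DUX4 transcription start site
#' (unit position 1688), assessed over a +/- 200 nt window.
#'
#' @slot dr1_start,dr1_end,tss_pos,tss_window integer scalars.
#' @export
setClass("UnitCoords", representation(
  dr1_start = "integer", dr1_end = "integer",
  tss_pos = "integer", tss_window = "integer"))

setValidity("UnitCoords", function(object) {
  if (object@dr1_start < 1L || object@dr1_start >= object@dr1_end)
    return("need 1 <= dr1_start < dr1_end")
  if (object@tss_pos <= object@tss_window)
    return("tss window must fit within the unit")
  TRUE
})

#' @rdname UnitCoords-class
#' @param dr1_start,dr1_end,tss_pos,tss_window landmark positions (1-based unit
#'   coordinates) and TSS half-window in nt.
#' @return a \linkS4class{UnitCoords}
#' @export
unitCoords <- function(dr1_start = 563L, dr1_end = 814L,
                       tss_pos = 1688L, tss_window = 200L) {
  new("UnitCoords", dr1_start = as.integer(dr1_start),
      dr1_end = as.integer(dr1_end), tss_pos = as.integer(tss_pos),
      tss_window = as.integer(tss_window))
}

## ---------------------------------------------------------------------------
## PipelineParams

#' Tunable pipeline parameters
#'
#' All thresholds used across annotation, haplotyping, consensus and
#' methylation, with their defaults. See the methods vignette for the
#' rationale behind each default.
#'
#' @slot seed_k k-mer size for seed anchoring (default 15).
#' @slot seed_stride sampling stride for reference seeds in bp (default 25).
#' @slot min_unit_identity minimum edit-distance identity for a retained
#'   unit/feature hit (default 0.70, tolerant of older-chemistry error rates).
#' @slot spacer_min_gap read-space gap (bp) above which consecutive units are
#'   split into separate array segments (default 4000; observed spacers in
#'   duplicated alleles run 6.5-20 kb while intra-array gaps are far below 1 kb).
#' @slot boundary_tol unit-coordinate tolerance (bp) for deciding whether a
#'   detected instance reaches the KpnI anchor at either unit end (default 250).
#' @slot trunc_tol span shortfall (bp) below which a both-ends-anchored unit is
#'   still called full rather than internally truncated (default 500).
#' @slot subtype_bins numeric length-3 vector: distal-partial length bins for
#'   the S/M/L distal subtypes: S <= bins[1], M in (bins[1], bins[2]],
#'   L >= bins[3] (defaults 450/1000/1500 bp around the ~0.3/~0.6/~1.9 kb
#'   distal units).
#' @slot meth_call_threshold probability at or above which a per-read CpG call
#'   is counted methylated (default 0.5).
#' @slot min_site_coverage minimum per-site read coverage for profile
#'   statistics (default 5).
#' @slot smoothing_window smoothing window in bp (default 2000).
#' @slot acf_max_lag_long,acf_max_lag_short autocorrelation lag ranges (10000 /
#'   500 nt).
#' @slot loess_span span for optional loess smoothing (default 0.2).
#' @slot consensus_rounds polishing rounds for the allele consensus (default 2).
#' @slot rng_seed integer seed threaded through stochastic operations.
#' @export
setClass("PipelineParams", representation(
  seed_k = "integer", seed_stride = "integer",
  min_unit_identity = "numeric", spacer_min_gap = "integer",
  boundary_tol = "integer", trunc_tol = "integer",
  subtype_bins = "numeric",
  meth_call_threshold = "numeric", min_site_coverage = "integer",
  smoothing_window = "integer",
  acf_max_lag_long = "integer", acf_max_lag_short = "integer",
  loess_span = "numeric", consensus_rounds = "integer",
  rng_seed = "integer"))

setValidity("PipelineParams", function(object) {
  if (object@seed_k < 8L) return("seed_k too small")
  if (object@seed_stride < 1L) return("seed_stride must be positive")
  if (object@min_unit_identity <= 0 || object@min_unit_identity > 1)
    return("min_unit_identity must be in (0, 1]")
  if (object@meth_call_threshold <= 0 || object@meth_call_threshold >= 1)
    return("meth_call_threshold must be in (0, 1)")
  if (any(c(object@spacer_min_gap, object@min_site_coverage,
            object@smoothing_window, object@acf_max_lag_long,
            object@acf_max_lag_short, object@consensus_rounds) <= 0))
    return("all thresholds must be positive")
  if (length(object@subtype_bins) != 3L || any(diff(object@subtype_bins) < 0))
    return("subtype_bins must be 3 nondecreasing lengths")
  TRUE
})

#' Construct pipeline parameters
#'
#' @param ... named overrides of any \linkS4class{PipelineParams} slot.
#' @return a \linkS4class{PipelineParams}
#' @examples
#' pipelineParams(min_unit_identity = 0.8)
#' @export
pipelineParams <- function(...) {
  d <- list(seed_k = 15L, seed_stride = 25L, min_unit_identity = 0.70,
            spacer_min_gap = 4000L, boundary_tol = 250L, trunc_tol = 500L,
            subtype_bins = c(450, 1000, 1500),
            meth_call_threshold = 0.5, min_site_coverage = 5L,
            smoothing_window = 2000L, acf_max_lag_long = 10000L,
            acf_max_lag_short = 500L, loess_span = 0.2,
            consensus_rounds = 2L, rng_seed = 1L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(d))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  d[names(ov)] <- ov
  ints <- c("seed_k", "seed_stride", "spacer_min_gap", "boundary_tol",
            "trunc_tol", "min_site_coverage", "smoothing_window",
            "acf_max_lag_long", "acf_max_lag_short", "consensus_rounds",
            "rng_seed")
  for (nm in ints) d[[nm]] <- as.integer(d[[nm]])
  do.call(new, c(list("PipelineParams"), d))
}

setMethod("show", "PipelineParams", function(object) {
  cat("PipelineParams\n")
  for (s in slotNames(object))
    cat(sprintf("  %-20s %s\n", s, paste(slot(object, s), collapse = ", ")))
})

#' Read pipeline parameters from a YAML config
#'
#' The YAML keys mirror the \linkS4class{PipelineParams} slot names.
#' @param path path to a YAML file.
#' @return a \linkS4class{PipelineParams}
#' @export
readParams <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineParams, cfg)
}

## ---------------------------------------------------------------------------
## ReferenceBundle

.bundle_roles <- c("unit", "p13E-11", "pLAM", "qB", "flank4q_up", "flank10q_up",
                   "flank4q_down", "flank10q_down", "D4S2463")

#' Reference feature bundle
#'
#' The feature sequences every annotation decision consults: the canonical
#' KpnI-KpnI D4Z4 unit (~3.3 kb, starting with the KpnI recognition sequence
#' GGTACC), the proximal p13E-11 flank, pLAM (end of the last unit through DUX4
#' exon 3, A-haplotype diagnostic), the qB-distal sequence (B-haplotype
#' diagnostic), the chromosome-unique upstream/downstream flanks beyond the
#' ~42 kb 4q/10q homology, and the D4S2463 inverted truncated unit (~1.5 kb,
#' ~42 kb upstream of 4q arrays). Real analyses load a bundle extracted from
#' CHM13v2.0 (see the vignette for the recipe); tests load simulator-built
#' bundles — the canonical unit is parameterized, never hard-coded.
#'
#' @slot sequences named character vector of uppercase ACGTN sequences, names
#'   drawn from the standard role set.
#' @slot motifs the \linkS4class{MotifSet} scanned in reads.
#' @slot coords the \linkS4class{UnitCoords} landmark positions.
#' @slot diagnostics named integer vector of optional unit-coordinate
#'   positions of diagnostic sites (xapi_pos, blni_pos) and the PAS offset
#'   within pLAM (pas_pos); used to genotype per-unit XapI/BlnI status.
#' @slot extra list of auxiliary sequences (e.g. the shared 4q/10q upstream
#'   homology region used by the simulator).
#' @export
setClass("ReferenceBundle", representation(
  sequences = "character", motifs = "MotifSet", coords = "UnitCoords",
  diagnostics = "integer", extra = "list"))

setValidity("ReferenceBundle", function(object) {
  s <- object@sequences
  if (!"unit" %in% names(s)) return("bundle must contain a 'unit' sequence")
  if (nchar(s[["unit"]]) < 3000 || nchar(s[["unit"]]) > 3500)
    return("unit sequence length must be within [3000, 3500]")
  if (substr(s[["unit"]], 1, 6) != "GGTACC")
    return("unit sequence must begin with the KpnI site GGTACC")
  if (any(grepl("[^ACGTN]", s)))
    return("bundle sequences must be uppercase ACGTN")
  bad <- setdiff(names(s), .bundle_roles)
  if (length(bad)) return(paste("unknown feature role(s):", paste(bad, collapse = ", ")))
  TRUE
})

#' @describeIn ReferenceBundle-class named feature sequences
#' @param x a ReferenceBundle
#' @export
bundleSeqs <- function(x) x@sequences

#' @describeIn ReferenceBundle-class one feature sequence by role name
#' @param role feature role name
#' @export
bundleSeq <- function(x, role) {
  if (!role %in% names(x@sequences)) return(NA_character_)
  x@sequences[[role]]
}

#' @describeIn ReferenceBundle-class length of the canonical unit (bp)
#' @export
unitLength <- function(x) nchar(x@sequences[["unit"]])

#' @describeIn ReferenceBundle-class TRUE when the bundle lacks the qB-distal
#'   sequence, in which case B-haplotyping is disabled
#' @export
bHaplotypingDisabled <- function(x) !("qB" %in% names(x@sequences))

setMethod("show", "ReferenceBundle", function(object) {
  cat("ReferenceBundle:", length(object@sequences), "feature sequences\n")
  for (n in names(object@sequences))
    cat(sprintf("  %-14s %6d bp\n", n, nchar(object@sequences[[n]])))
  if (bHaplotypingDisabled(object))
    cat("  [qB absent: B-haplotyping disabled]\n")
})

#' Assemble a ReferenceBundle from named sequences
#'
#' @param sequences named character vector or list; names are feature roles
#'   (\code{unit}, \code{p13E-11}, \code{pLAM}, \code{qB}, \code{flank4q_up},
#'   \code{flank10q_up}, \code{flank4q_down}, \code{flank10q_down},
#'   \code{D4S2463}). Lowercase input is normalized to uppercase. Only
#'   \code{unit} is mandatory; missing optional features trigger a warning.
#' @param motifs a \linkS4class{MotifSet}.
#' @param coords a \linkS4class{UnitCoords}.
#' @param diagnostics optional named integer vector (\code{xapi_pos},
#'   \code{blni_pos}, \code{pas_pos}).
#' @param extra list of auxiliary sequences.
#' @return a \linkS4class{ReferenceBundle}
#' @export
referenceBundle <- function(sequences, motifs = motifSet(), coords = unitCoords(),
                            diagnostics = integer(0), extra = list()) {
  sequences <- vapply(sequences, function(s) .norm_dna(s, "bundle sequence"),
                      character(1))
  if (!"unit" %in% names(sequences))
    stop("reference bundle is missing the canonical 'unit' sequence")
  missing_opt <- setdiff(.bundle_roles, names(sequences))
  if (length(missing_opt))
    warning("bundle missing optional feature(s): ",
            paste(missing_opt, collapse = ", "),
            if ("qB" %in% missing_opt) " (B-haplotyping disabled)" else "")
  diagnostics <- stats::setNames(as.integer(diagnostics), names(diagnostics))
  new("ReferenceBundle", sequences = sequences, motifs = motifs,
      coords = coords, diagnostics = diagnostics, extra = extra)
}

#' Load a reference bundle from a multi-FASTA file
#'
#' Record IDs name the feature roles
#' (\code{unit|p13E-11|pLAM|qB|flank4q_up|flank10q_up|flank4q_down|flank10q_down|D4S2463}).
#' A missing \code{unit} record is fatal; missing optional features load with a
#' warning; lowercase bases are normalized; non-ACGTN characters are fatal.
#'
#' @param path FASTA file (plain or gzip).
#' @param ... passed to [referenceBundle()].
#' @return a \linkS4class{ReferenceBundle}
#' @export
loadBundle <- function(path, ...) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  referenceBundle(seqs, ...)
}

#' Write a reference bundle to a multi-FASTA file
#' @param bundle a \linkS4class{ReferenceBundle}
#' @param path output FASTA path
#' @return invisibly, \code{path}
#' @export
writeBundle <- function(bundle, path) {
  ss <- Biostrings::DNAStringSet(bundle@sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Canonical-unit consensus from extracted units

#' Build a canonical unit reference by per-column plurality
#'
#' Anchors every unit to a backbone (the medoid-length unit) by global
#' alignment and takes the most frequent value (nucleotide or gap) at each
#' backbone column; gap-majority columns are deleted and majority insertions
#' retained. Equivalent in contract to taking the per-column plurality of a
#' multiple sequence alignment of all full-length units. Ties are broken in
#' favor of the backbone base, which also makes the result invariant to input
#' order.
#'
#' @param units character vector of >= 2 full-length unit sequences of similar
#'   length (pairwise length overlap of at least 50\% is required).
#' @return a single consensus DNA string
#' @export
buildUnitReference <- function(units) {
  units <- vapply(units, .norm_dna, character(1), what = "unit")
  if (length(units) < 2L) stop("need at least 2 unit sequences")
  lens <- nchar(units)
  if (min(lens) < 0.5 * max(lens))
    stop("unit sequences differ too much in length (<50% overlap)")
  ## medoid-length backbone: deterministic regardless of input order
  med <- stats::median(lens)
  cand <- which(abs(lens - med) == min(abs(lens - med)))
  backbone <- sort(units[cand])[1L]
  others <- units[-match(backbone, units)]
  .column_vote(backbone, others)
}

## column plurality vote of `others` against `backbone`, gaps included;
## ties -> backbone base; majority insertions included
.column_vote <- function(backbone, others) {
  n <- nchar(backbone)
  bases <- c("A", "C", "G", "T", "N", "-")
  votes <- matrix(0L, nrow = 6L, ncol = n, dimnames = list(bases, NULL))
  bvec <- strsplit(backbone, "")[[1]]
  votes[cbind(match(bvec, bases), seq_len(n))] <- 1L
  ins <- list()   # key: after-position, value: table of inserted strings
  depth <- rep(1L, n)
  for (s in others) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), Biostrings::DNAString(backbone),
      type = "global", gapOpening = 2, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    q <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    bpos <- 0L
    pending <- character(0)
    for (i in seq_along(q)) {
      if (q[i] == "-") {          # insertion in this unit relative to backbone
        pending <- c(pending, p[i])
      } else {
        if (length(pending)) {
          key <- as.character(bpos)
          ins[[key]] <- c(ins[[key]], paste(pending, collapse = ""))
          pending <- character(0)
        }
        bpos <- bpos + 1L
        votes[match(p[i], bases), bpos] <- votes[match(p[i], bases), bpos] + 1L
        depth[bpos] <- depth[bpos] + 1L
      }
    }
  }
  ## plurality with backbone tie-break
  win <- character(n)
  for (j in seq_len(n)) {
    v <- votes[, j]
    mx <- max(v)
    cand <- bases[v == mx]
    win[j] <- if (bvec[j] %in% cand) bvec[j] else cand[1L]
  }
  total <- length(others) + 1L
  out <- win
  ## majority insertions (more than half of all sequences share the string)
  if (length(ins)) {
    add <- vapply(names(ins), function(key) {
      tb <- sort(table(ins[[key]]), decreasing = TRUE)
      if (tb[1L] > total / 2) names(tb)[1L] else ""
    }, character(1))
    keep <- nzchar(add)
    if (any(keep)) {
      pieces <- character(0)
      cuts <- c(0L, as.integer(names(ins)[keep]), n)
      addv <- c("", unname(add[keep]), "")
      ord <- order(cuts[-length(cuts)])
      segs <- character(0)
      prev <- 0L
      for (idx in order(as.integer(names(ins)[keep]))) {
        at <- as.integer(names(ins)[keep][idx])
        segs <- c(segs, paste(out[seq_len(at - prev) + prev], collapse = ""),
                  unname(add[keep][idx]))
        prev <- at
      }
      segs <- c(segs, paste(out[seq_len(n - prev) + prev], collapse = ""))
      return(gsub("-", "", paste(segs, collapse = "")))
    }
  }
  gsub("-", "", paste(out, collapse = ""))
}
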