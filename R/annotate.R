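# Per-read detection of D4Z4 repeat units, flanking features, diagnostic
# motifs, array segmentation (in-cis duplications, inverted upstream units)
# and spanning classification.
#
# Unit/feature detection is seed-and-extend: k-mers sampled every
# `seed_stride` bp from the reference feature are matched exactly against all
# read k-mers; co-linear anchor runs are chained into instances; instance
# boundaries are refined by greedy base-wise extension toward the feature
# ends; instance identity is the edit-distance identity of the implied
# interval. This is deterministic and self-contained; an external aligner can
# be slotted in behind the same contract provided it applies a primary-only
# (non-secondary, non-supplementary) filter.

## ---------------------------------------------------------------------------
## anchors

## exact seed matches of `refseq` seeds in precomputed read k-mers.
## returns data.frame(rpos, tpos), 1-based starts.
.anchor_scan <- function(read_kmers, refseq, k, stride) {
  n <- nchar(refseq)
  if (n < k) return(data.frame(rpos = integer(0), tpos = integer(0)))
  starts <- seq.int(1L, n - k + 1L, by = stride)
  tk <- substring(refseq, starts, starts + k - 1L)
  ## reference seeds must identify a unique offset; drop duplicated seeds
  dup <- duplicated(tk) | duplicated(tk, fromLast = TRUE)
  tk <- tk[!dup]; starts <- starts[!dup]
  m <- match(read_kmers, tk)
  hit <- which(!is.na(m))
  data.frame(rpos = hit, tpos = starts[m[hit]])
}

## forward and reverse-complement k-mer tables of a read, computed once and
## shared by unit and feature detection
.read_kmers <- function(read, k) {
  list(fw = .kmers(read, k), rc = .kmers(revcomp(read), k))
}

## seed dictionary over several reference sequences: one match() per strand
## instead of one per feature
.multi_anchor_scan <- function(read_kmers, refseqs, k, stride) {
  tks <- character(0); tps <- integer(0); role <- character(0)
  for (nm in names(refseqs)) {
    n <- nchar(refseqs[[nm]])
    if (n < k) next
    starts <- seq.int(1L, n - k + 1L, by = stride)
    tks <- c(tks, substring(refseqs[[nm]], starts, starts + k - 1L))
    tps <- c(tps, starts)
    role <- c(role, rep(nm, length(starts)))
  }
  dup <- duplicated(tks) | duplicated(tks, fromLast = TRUE)
  tks <- tks[!dup]; tps <- tps[!dup]; role <- role[!dup]
  m <- match(read_kmers, tks)
  hit <- which(!is.na(m))
  data.frame(rpos = hit, tpos = tps[m[hit]], role = role[m[hit]],
             stringsAsFactors = FALSE)
}

## chain anchors (sorted by rpos) into co-linear instances.
## a new instance opens when the target coordinate wraps backwards or when the
## read advances much further than the target (spacer / foreign sequence).
.chain_anchors <- function(anc, min_anchors = 3L, jump = 400L) {
  if (nrow(anc) == 0L) return(integer(0))
  anc <- anc[order(anc$rpos), , drop = FALSE]
  id <- integer(nrow(anc))
  cur <- 1L
  id[1L] <- cur
  if (nrow(anc) > 1L) for (i in 2:nrow(anc)) {
    dt <- anc$tpos[i] - anc$tpos[i - 1L]
    dr <- anc$rpos[i] - anc$rpos[i - 1L]
    if (dt < -100L || (dr - dt) > jump) cur <- cur + 1L
    id[i] <- cur
  }
  id
}

## greedy base-wise boundary extension with a mismatch budget.
## walks read and target together from (rpos, tpos) in direction dir (+1/-1)
## until either sequence ends or 4 consecutive mismatches accrue.
.extend_boundary <- function(read, tseq, rpos, tpos, dir) {
  nr <- nchar(read); nt <- nchar(tseq)
  streak <- 0L
  last_r <- rpos; last_t <- tpos   # last matching position
  repeat {
    r2 <- rpos + dir; t2 <- tpos + dir
    if (r2 < 1L || r2 > nr || t2 < 1L || t2 > nt) break
    if (substr(read, r2, r2) == substr(tseq, t2, t2)) {
      streak <- 0L
      last_r <- r2; last_t <- t2
    } else {
      streak <- streak + 1L
      if (streak >= 4L) break
    }
    rpos <- r2; tpos <- t2
  }
  c(last_r, last_t)   # boundary snapped to the last agreeing base
}

## chain precomputed anchors of one reference on one strand of the read into
## boundary-refined instances. read: forward read if strand "+", else its
## reverse complement; coordinates are in the supplied read's frame and are
## mapped by the caller.
.detect_instances <- function(read, anc, refseq, params, min_anchors = 3L) {
  k <- params@seed_k
  if (nrow(anc) == 0L)
    return(.empty_instances())
  anc <- anc[order(anc$rpos), , drop = FALSE]
  id <- .chain_anchors(anc)
  out <- lapply(split(seq_len(nrow(anc)), id), function(ix) {
    if (length(ix) < min_anchors) return(NULL)
    a <- anc[ix, , drop = FALSE]
    ## refine boundaries from the outermost anchors
    st <- .extend_boundary(read, refseq, a$rpos[1L], a$tpos[1L], -1L)
    en <- .extend_boundary(read, refseq,
                           a$rpos[nrow(a)] + k - 1L, a$tpos[nrow(a)] + k - 1L, 1L)
    ## center of the longest co-linear anchor run: a safe spot to measure
    ## identity even when the instance has a large internal deletion
    m <- nrow(a)
    run_id <- cumsum(c(1L, abs(diff(a$tpos) - diff(a$rpos)) > 50L))
    runs <- split(seq_len(m), run_id)
    best <- runs[[which.max(vapply(runs, length, integer(1)))]]
    ctr <- best[(length(best) + 1L) %/% 2L]
    data.frame(read_start = st[1L], read_end = en[1L],
               tstart = st[2L], tend = en[2L],
               ctr_rpos = a$rpos[ctr], ctr_tpos = a$tpos[ctr],
               run_len = a$tpos[best[length(best)]] - a$tpos[best[1L]] + k,
               n_anchors = length(ix))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(.empty_instances())
  rownames(out) <- NULL
  out
}

.empty_instances <- function() {
  data.frame(read_start = integer(0), read_end = integer(0),
             tstart = integer(0), tend = integer(0),
             ctr_rpos = integer(0), ctr_tpos = integer(0),
             run_len = integer(0), n_anchors = integer(0))
}

## edit-distance identity of an instance. Short instances are measured over
## the full implied interval; long ones over a 1 kb alignment slice centered
## on the instance's longest co-linear anchor run (an unbiased estimate under
## a uniform error process at a fraction of the O(n*m) cost, and immune to
## large internal deletions, which are structural, not base-level, events).
.instance_identity <- function(rseq, tseq, inst, slice = 1000L) {
  tlen <- inst$tend - inst$tstart + 1L
  if (tlen <= 1500L || inst$run_len < 600L)
    return(.identity(substr(rseq, inst$read_start, inst$read_end),
                     substr(tseq, inst$tstart, inst$tend)))
  w <- min(slice, inst$run_len - 50L) %/% 2L
  t_lo <- max(inst$tstart, inst$ctr_tpos - w)
  t_hi <- min(inst$tend, inst$ctr_tpos + w)
  r_lo <- inst$ctr_rpos - (inst$ctr_tpos - t_lo)
  r_hi <- inst$ctr_rpos + (t_hi - inst$ctr_tpos)
  .identity(substr(rseq, r_lo, r_hi), substr(tseq, t_lo, t_hi))
}

## map instance intervals from reverse-complement frame to forward frame
.mirror_intervals <- function(df, read_len) {
  if (nrow(df) == 0L) return(df)
  rs <- read_len - df$read_end + 1L
  re <- read_len - df$read_start + 1L
  df$read_start <- rs
  df$read_end <- re
  df
}

## ---------------------------------------------------------------------------
## detectUnits

#' Detect D4Z4 unit instances in a read
#'
#' Finds all instances of the canonical KpnI-KpnI unit on both strands of a
#' read, snaps boundaries to the alignment position of the unit's KpnI start
#' (the alignment coordinate wins when the motif itself is corrupted by
#' sequencing error), and classifies each instance by which unit ends it
#' reaches: \code{full} (both KpnI anchors), \code{truncated_internal} (both
#' anchors but an internal deletion, still counted in RU counts),
#' \code{partial_proximal} / \code{partial_distal} (exactly one anchor, at an
#' array or read end). Reads shorter than the seed window yield an empty
#' result, not an error.
#'
#' @param read character scalar, the read sequence (>= 1 kb for meaningful
#'   results).
#' @param bundle a \linkS4class{ReferenceBundle}.
#' @param params a \linkS4class{PipelineParams}.
#' @param kmers optional precomputed k-mer tables from an internal shared
#'   scan (used by [annotateRead()] to avoid recomputation).
#' @return data.frame of unit hits: \code{read_start}, \code{read_end}
#'   (1-based inclusive, forward-read coordinates), \code{strand},
#'   \code{umin}, \code{umax} (unit-coordinate coverage), \code{length},
#'   \code{completeness} (raw labels; terminal labels finalized by
#'   [segmentArrays()]), \code{identity}, \code{n_anchors}. The anchor table
#'   used for coordinate lifting is attached as attribute \code{"anchors"}.
#' @export
detectUnits <- function(read, bundle, params = pipelineParams(), kmers = NULL) {
  read <- toupper(read)
  unit <- bundleSeq(bundle, "unit")
  k <- params@seed_k
  n <- nchar(read)
  empty <- .unit_hits_frame()
  if (n < k) return(empty)
  if (is.null(kmers)) kmers <- .read_kmers(read, k)
  rc <- revcomp(read)

  res <- list(); ancs <- list()
  for (strand in c("+", "-")) {
    rk <- if (strand == "+") kmers$fw else kmers$rc
    rseq <- if (strand == "+") read else rc
    anc <- .anchor_scan(rk, unit, k, params@seed_stride)
    inst <- .detect_instances(rseq, anc, unit, params)
    if (nrow(inst) == 0L) next
    inst$identity <- vapply(seq_len(nrow(inst)), function(i)
      .instance_identity(rseq, unit, inst[i, ]), numeric(1))
    ## anchors for coordinate lifting (forward-frame read positions)
    if (strand == "-" && nrow(anc)) anc$rpos <- n - (anc$rpos + k - 1L) + 1L
    if (nrow(anc)) { anc$strand <- strand; ancs[[strand]] <- anc }
    if (strand == "-") inst <- .mirror_intervals(inst, n)
    inst$strand <- strand
    res[[strand]] <- inst
  }
  inst <- do.call(rbind, res)
  if (is.null(inst) || nrow(inst) == 0L) return(empty)
  inst <- inst[inst$identity >= params@min_unit_identity, , drop = FALSE]
  if (nrow(inst) == 0L) return(empty)
  inst <- inst[order(inst$read_start), , drop = FALSE]

  inst <- inst[, setdiff(names(inst), c("ctr_rpos", "ctr_tpos", "run_len")),
               drop = FALSE]
  ulen <- unitLength(bundle)
  tol <- params@boundary_tol
  covers_start <- inst$tstart <= tol
  covers_end   <- inst$tend >= ulen - tol
  ## instances clipped by the read ends cannot claim anchors beyond the clip
  at_edge_left  <- inst$read_start <= 2L
  at_edge_right <- inst$read_end >= n - 1L
  span <- inst$read_end - inst$read_start + 1L
  comp <- character(nrow(inst))
  for (i in seq_len(nrow(inst))) {
    cs <- covers_start[i]; ce <- covers_end[i]
    ## for a minus-strand instance the read-edge clip flips in unit space
    clip_start <- if (inst$strand[i] == "+") at_edge_left[i] else at_edge_right[i]
    clip_end   <- if (inst$strand[i] == "+") at_edge_right[i] else at_edge_left[i]
    if (cs && ce) {
      comp[i] <- if (span[i] < ulen - params@trunc_tol) "truncated_internal" else "full"
    } else if (cs) {
      comp[i] <- if (clip_end) "clipped" else "open_end"      # distal-type partial
    } else if (ce) {
      comp[i] <- if (clip_start) "clipped" else "open_start"  # proximal-type partial
    } else comp[i] <- "fragment"
  }
  out <- data.frame(read_start = inst$read_start, read_end = inst$read_end,
                    strand = inst$strand, umin = inst$tstart, umax = inst$tend,
                    length = span, completeness = comp,
                    identity = inst$identity, n_anchors = inst$n_anchors,
                    stringsAsFactors = FALSE)
  attr(out, "anchors") <- if (length(ancs)) do.call(rbind, ancs) else NULL
  out
}

.unit_hits_frame <- function() {
  out <- data.frame(read_start = integer(0), read_end = integer(0),
                    strand = character(0), umin = integer(0), umax = integer(0),
                    length = integer(0), completeness = character(0),
                    identity = numeric(0), n_anchors = integer(0),
                    stringsAsFactors = FALSE)
  out
}

## ---------------------------------------------------------------------------
## segmentArrays

#' Group unit hits into array segments
#'
#' Splits an ordered run of unit hits wherever the inter-unit read-space gap
#' reaches \code{spacer_min_gap} or the strand flips, producing one segment
#' per tandem array (the main array plus any in-cis duplicated arrays or
#' inverted upstream arrays). Per segment, finalizes terminal-partial labels,
#' counts full units (\code{full} + \code{truncated_internal}; terminal
#' partials excluded per the KpnI-KpnI counting convention) and measures
#' proximal/distal partial lengths. "Proximal" within a segment means the side
#' carrying the end of a unit (sequence upstream of a KpnI site); this is
#' orientation-free because unit coordinates travel with the hits.
#'
#' @param units data.frame from [detectUnits()], sorted by read coordinate.
#' @param params a \linkS4class{PipelineParams}.
#' @return list with \code{segments} (data.frame: \code{segment},
#'   \code{read_start}, \code{read_end}, \code{strand},
#'   \code{full_unit_count}, \code{n_units}, \code{proximal_partial_len},
#'   \code{distal_partial_len}) and \code{units} (input with final
#'   \code{completeness} labels and a \code{segment} column).
#' @export
segmentArrays <- function(units, params = pipelineParams()) {
  if (nrow(units) == 0L) {
    segs <- data.frame(segment = integer(0), read_start = integer(0),
                       read_end = integer(0), strand = character(0),
                       full_unit_count = integer(0), n_units = integer(0),
                       proximal_partial_len = integer(0),
                       distal_partial_len = integer(0))
    return(list(segments = segs, units = cbind(units, segment = integer(0))))
  }
  units <- units[order(units$read_start), , drop = FALSE]
  seg <- integer(nrow(units)); cur <- 1L; seg[1L] <- cur
  if (nrow(units) > 1L) for (i in 2:nrow(units)) {
    gap <- units$read_start[i] - units$read_end[i - 1L] - 1L
    if (gap >= params@spacer_min_gap || units$strand[i] != units$strand[i - 1L])
      cur <- cur + 1L
    seg[i] <- cur
  }
  units$segment <- seg

  segs <- lapply(split(seq_len(nrow(units)), seg), function(ix) {
    u <- units[ix, , drop = FALSE]
    strand <- u$strand[1L]
    ## finalize raw completeness labels within the segment:
    ## terminal open/fragment instances become terminal partials; internal
    ## ones are internally truncated units (counted).
    comp <- u$completeness
    m <- nrow(u)
    for (j in seq_len(m)) {
      if (comp[j] %in% c("full", "truncated_internal")) next
      terminal_left <- j == 1L
      terminal_right <- j == m
      if (comp[j] == "clipped") {
        ## clipped by the read end: a terminal partial by construction
        comp[j] <- if ((strand == "+") == terminal_left)
          "partial_proximal" else "partial_distal"
        next
      }
      ## open_end covers the unit start (KpnI side): distal-type partial
      ## open_start covers the unit end: proximal-type partial
      if (terminal_left || terminal_right) {
        comp[j] <- if (comp[j] == "open_end") "partial_distal"
                   else if (comp[j] == "open_start") "partial_proximal"
                   else if ((strand == "+") == terminal_left)
                     "partial_proximal" else "partial_distal"
      } else comp[j] <- "truncated_internal"
    }
    units$completeness[ix] <<- comp
    full_n <- sum(comp %in% c("full", "truncated_internal"))
    pp <- sum(u$length[comp == "partial_proximal"])
    dp <- sum(u$length[comp == "partial_distal"])
    data.frame(segment = u$segment[1L], read_start = min(u$read_start),
               read_end = max(u$read_end), strand = strand,
               full_unit_count = full_n, n_units = m,
               proximal_partial_len = as.integer(pp),
               distal_partial_len = as.integer(dp))
  })
  segs <- do.call(rbind, segs)
  rownames(segs) <- NULL
  list(segments = segs, units = units)
}

## ---------------------------------------------------------------------------
## scanMotifs

#' Scan a read for exact motif matches
#'
#' Exact matching of every motif in a \linkS4class{MotifSet} on both strands,
#' with IUPAC degenerate bases (e.g. XapI RAATTY) expanded at scan time.
#' Positions are 1-based starts on the forward read; palindromic motifs
#' (KpnI GGTACC, BlnI CCTAGG, XapI RAATTY) are reported once on "+".
#'
#' @param read character scalar.
#' @param motifset a \linkS4class{MotifSet} (or a ReferenceBundle, whose motif
#'   set is used).
#' @return named list; per motif a data.frame with \code{pos} and
#'   \code{strand}.
#' @export
scanMotifs <- function(read, motifset) {
  if (is(motifset, "ReferenceBundle")) motifset <- motifset@motifs
  ms <- motifs(motifset)
  subj <- Biostrings::DNAString(toupper(read))
  out <- lapply(ms, function(m) {
    pat <- Biostrings::DNAString(m)
    fwd <- Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = FALSE))
    rcp <- Biostrings::reverseComplement(pat)
    palin <- as.character(rcp) == as.character(pat)
    rev <- if (palin) integer(0) else
      Biostrings::start(Biostrings::matchPattern(rcp, subj, fixed = FALSE))
    data.frame(pos = c(fwd, rev),
               strand = c(rep("+", length(fwd)), rep("-", length(rev))),
               stringsAsFactors = FALSE)
  })
  names(out) <- names(ms)
  out
}

## ---------------------------------------------------------------------------
## detectFeatures

#' Detect flanking-feature hits in a read
#'
#' Seed-and-extend detection of every non-unit bundle feature (p13E-11, pLAM,
#' qB-distal, chromosome-unique flanks, D4S2463) on both strands, keeping
#' non-overlapping hits with identity >= \code{min_unit_identity}. Telomeric
#' runs (>= 8 consecutive TTAGGG on either strand) are reported as feature
#' \code{"telomere"}.
#'
#' @param read character scalar.
#' @param bundle a \linkS4class{ReferenceBundle}.
#' @param params a \linkS4class{PipelineParams}.
#' @param kmers optional precomputed k-mer tables (see [detectUnits()]).
#' @return data.frame of feature hits: \code{feature}, \code{read_start},
#'   \code{read_end}, \code{strand}, \code{identity}, \code{tstart},
#'   \code{tend}.
#' @export
detectFeatures <- function(read, bundle, params = pipelineParams(),
                           kmers = NULL) {
  read <- toupper(read)
  k <- params@seed_k
  n <- nchar(read)
  empty <- data.frame(feature = character(0), read_start = integer(0),
                      read_end = integer(0), strand = character(0),
                      identity = numeric(0), tstart = integer(0),
                      tend = integer(0), stringsAsFactors = FALSE)
  if (n < k) return(empty)
  if (is.null(kmers)) kmers <- .read_kmers(read, k)
  rc <- revcomp(read)
  feats <- bundleSeqs(bundle)[setdiff(names(bundleSeqs(bundle)), "unit")]
  rows <- list()
  for (strand in c("+", "-")) {
    rk <- if (strand == "+") kmers$fw else kmers$rc
    rseq <- if (strand == "+") read else rc
    anc_all <- .multi_anchor_scan(rk, feats, k, params@seed_stride)
    if (nrow(anc_all) == 0L) next
    for (role in unique(anc_all$role)) {
      fseq <- feats[[role]]
      anc <- anc_all[anc_all$role == role, c("rpos", "tpos"), drop = FALSE]
      inst <- .detect_instances(rseq, anc, fseq, params)
      if (nrow(inst) == 0L) next
      inst$identity <- vapply(seq_len(nrow(inst)), function(i)
        .instance_identity(rseq, fseq, inst[i, ]), numeric(1))
      if (strand == "-") inst <- .mirror_intervals(inst, n)
      keep <- inst$identity >= params@min_unit_identity
      if (!any(keep)) next
      inst <- inst[keep, , drop = FALSE]
      rows[[paste(role, strand)]] <- data.frame(
        feature = role, read_start = inst$read_start,
        read_end = inst$read_end, strand = strand,
        identity = inst$identity, tstart = inst$tstart, tend = inst$tend,
        stringsAsFactors = FALSE)
    }
  }
  ## telomeric runs
  for (pat in c("(TTAGGG){8,}", "(CCCTAA){8,}")) {
    m <- gregexpr(pat, read)[[1]]
    if (m[1L] != -1L) {
      rows[[paste("tel", pat)]] <- data.frame(
        feature = "telomere", read_start = as.integer(m),
        read_end = as.integer(m) + attr(m, "match.length") - 1L,
        strand = if (startsWith(pat, "(T")) "+" else "-",
        identity = 1, tstart = NA_integer_, tend = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$read_start), , drop = FALSE]
  ## resolve overlaps per feature: keep the higher-identity hit
  keep <- rep(TRUE, nrow(out))
  for (role in unique(out$feature)) {
    ix <- which(out$feature == role)
    if (length(ix) < 2L) next
    ix <- ix[order(-out$identity[ix])]
    taken <- logical(0); ivs <- list()
    for (i in ix) {
      ov <- any(vapply(ivs, function(iv)
        out$read_start[i] <= iv[2L] && out$read_end[i] >= iv[1L], logical(1)))
      if (ov) keep[i] <- FALSE
      else ivs[[length(ivs) + 1L]] <- c(out$read_start[i], out$read_end[i])
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## ReadAnnotation class

#' Per-read annotation
#'
#' The composite annotation of one read (or assembly contig): detected unit
#' hits, array segments, feature hits, motif positions, spanning status
#' (p13E-11 present AND a distal feature, pLAM or qB, present), orientation of
#' the main array relative to the read, and the segment index of an inverted
#' upstream array (minus-strand segment proximal to the main array, the
#' D4S2463 configuration) if one exists.
#'
#' @slot read_id character.
#' @slot read_length integer.
#' @slot units,segments,features data.frames (see [detectUnits()],
#'   [segmentArrays()], [detectFeatures()]).
#' @slot motif_sites named list of motif position data.frames.
#' @slot spanning logical.
#' @slot orientation "+" if the main array runs proximal-to-distal along the
#'   read, "-" otherwise.
#' @slot inverted_upstream integer segment index or NA.
#' @slot anchors data.frame of (rpos, tpos, strand) seed anchors for
#'   coordinate lifting.
#' @export
setClass("ReadAnnotation", representation(
  read_id = "character", read_length = "integer",
  units = "data.frame", segments = "data.frame", features = "data.frame",
  motif_sites = "list", spanning = "logical", orientation = "character",
  inverted_upstream = "integer", anchors = "data.frame"))

setMethod("show", "ReadAnnotation", function(object) {
  cat("ReadAnnotation", object@read_id, sprintf("(%d bp)\n", object@read_length))
  cat("  segments:", nrow(object@segments),
      " RU structure:", .structure_label(ruStructure(object)), "\n")
  cat("  features:", paste(unique(object@features$feature), collapse = ", "), "\n")
  cat("  spanning:", object@spanning,
      " orientation:", object@orientation,
      " inverted upstream:", !is.na(object@inverted_upstream), "\n")
})

#' @describeIn ReadAnnotation-class TRUE if the read spans the whole array
#' @param ann a ReadAnnotation
#' @export
isSpanning <- function(ann) ann@spanning

#' RU structure of the main array chain
#'
#' Full-unit counts of the co-oriented main-array segments, ordered proximal
#' to distal (e.g. \code{c(15, 2, 5)} for an in-cis triplication). Segments on
#' the opposite strand (inverted upstream arrays) are excluded.
#'
#' @param ann a \linkS4class{ReadAnnotation}.
#' @return integer vector (possibly empty)
#' @export
ruStructure <- function(ann) {
  segs <- ann@segments
  if (nrow(segs) == 0L) return(integer(0))
  main <- segs[segs$strand == ann@orientation, , drop = FALSE]
  if (nrow(main) == 0L) return(integer(0))
  ord <- order(main$read_start)
  if (ann@orientation == "-") ord <- rev(ord)
  as.integer(main$full_unit_count[ord])
}

#' Distal partial unit length of the main array
#'
#' Length (bp) of the partial D4Z4 unit at the distal end of the most distal
#' co-oriented segment — the quantity that defines the 4qA S/M/L subtypes
#' (~0.3 / ~0.6 / ~1.9 kb).
#'
#' @param ann a \linkS4class{ReadAnnotation}.
#' @return integer (0 when absent)
#' @export
distalPartialLength <- function(ann) {
  segs <- ann@segments
  main <- segs[segs$strand == ann@orientation, , drop = FALSE]
  if (nrow(main) == 0L) return(0L)
  last <- if (ann@orientation == "+") which.max(main$read_start)
          else which.min(main$read_start)
  as.integer(main$distal_partial_len[last])
}

## ---------------------------------------------------------------------------
## annotateRead

#' Annotate one read
#'
#' Composes [detectUnits()], [segmentArrays()], [scanMotifs()] and
#' [detectFeatures()]; classifies the read as spanning when it contains both
#' p13E-11 and a distal feature (pLAM or qB); determines the main-array
#' orientation; and flags an inverted upstream segment when a minus-strand
#' (relative to the main array) segment lies on the proximal side of the main
#' array.
#'
#' @param read character scalar.
#' @param bundle a \linkS4class{ReferenceBundle}.
#' @param params a \linkS4class{PipelineParams}.
#' @param read_id identifier stored in the annotation.
#' @return a \linkS4class{ReadAnnotation}
#' @export
annotateRead <- function(read, bundle, params = pipelineParams(),
                         read_id = "read") {
  read <- toupper(read)
  kmers <- if (nchar(read) >= params@seed_k)
    .read_kmers(read, params@seed_k) else NULL
  units <- detectUnits(read, bundle, params, kmers = kmers)
  anchors <- attr(units, "anchors")
  if (is.null(anchors))
    anchors <- data.frame(rpos = integer(0), tpos = integer(0),
                          strand = character(0))
  sa <- segmentArrays(units, params)
  feats <- detectFeatures(read, bundle, params, kmers = kmers)
  msites <- scanMotifs(read, bundle@motifs)

  has <- function(f) f %in% feats$feature
  spanning <- has("p13E-11") && (has("pLAM") || has("qB"))

  ## main-array orientation: strand of the largest segment; fall back to the
  ## relative order of p13E-11 and the array
  segs <- sa$segments
  orientation <- "+"
  if (nrow(segs)) {
    main_i <- order(-segs$full_unit_count, -(segs$read_end - segs$read_start))[1L]
    orientation <- segs$strand[main_i]
    if (has("p13E-11")) {
      p13 <- feats[feats$feature == "p13E-11", , drop = FALSE][1L, ]
      orientation <- if (p13$read_start <= segs$read_start[main_i])
        if (p13$strand == "+") "+" else orientation
      else if (p13$strand == "-") "-" else orientation
    }
  }

  ## inverted upstream segment: opposite strand, proximal side of main array
  inv <- NA_integer_
  if (nrow(segs) >= 2L) {
    main_i <- which(segs$strand == orientation)
    if (length(main_i)) {
      main_start <- min(segs$read_start[main_i])
      main_end <- max(segs$read_end[main_i])
      opp <- which(segs$strand != orientation)
      for (j in opp) {
        upstream <- if (orientation == "+") segs$read_end[j] < main_start
                    else segs$read_start[j] > main_end
        if (upstream) { inv <- segs$segment[j]; break }
      }
    }
  }

  new("ReadAnnotation", read_id = as.character(read_id),
      read_length = nchar(read), units = sa$units, segments = segs,
      features = feats, motif_sites = msites, spanning = spanning,
      orientation = orientation, inverted_upstream = inv,
      anchors = anchors)
}

#' Annotate a set of reads
#'
#' @param reads named character vector (or DNAStringSet) of reads.
#' @param bundle a \linkS4class{ReferenceBundle}.
#' @param params a \linkS4class{PipelineParams}.
#' @param min_length reads shorter than this are skipped (default 1000).
#' @return named list of \linkS4class{ReadAnnotation}; reads with no unit or
#'   feature content are dropped.
#' @export
annotateReads <- function(reads, bundle, params = pipelineParams(),
                          min_length = 1000L) {
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
  out <- list()
  for (id in names(reads)) {
    if (nchar(reads[[id]]) < min_length) next
    ann <- annotateRead(reads[[id]], bundle, params, read_id = id)
    if (nrow(ann@units) == 0L && nrow(ann@features) == 0L) next
    out[[id]] <- ann
  }
  out
}

#' Annotate assembly contigs
#'
#' Runs the same annotation as for reads over assembled contigs. Spanning is
#' not a meaningful concept for an assembly but is reported anyway; a
#' \code{split} flag marks contigs whose array is clipped by a contig edge
#' (the array continues on another scaffold), in which case unit counts are
#' lower bounds.
#'
#' @param contigs named character vector, DNAStringSet, or path to a FASTA
#'   file.
#' @param bundle a \linkS4class{ReferenceBundle}.
#' @param params a \linkS4class{PipelineParams}.
#' @return named list of \linkS4class{ReadAnnotation}, each with a
#'   \code{split} attribute.
#' @export
annotateAssembly <- function(contigs, bundle, params = pipelineParams()) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- Biostrings::readDNAStringSet(contigs)
  if (is(contigs, "XStringSet")) contigs <- as.character(contigs)
  if (is.null(names(contigs))) names(contigs) <- paste0("contig_", seq_along(contigs))
  out <- list()
  for (id in names(contigs)) {
    ann <- annotateRead(contigs[[id]], bundle, params, read_id = id)
    n <- nchar(contigs[[id]])
    split <- nrow(ann@units) > 0L &&
      (min(ann@units$read_start) <= 2L || max(ann@units$read_end) >= n - 1L)
    attr(ann, "split") <- split
    out[[id]] <- ann
  }
  out
}
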