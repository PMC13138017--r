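# Chromosome (4q/10q), A/B and distal-subtype assignment; allele grouping of
# spanning reads; mosaic fractions; reporting.
#
# Evidence precedence for the chromosome call: upstream unique flank (only
# present when the read extends beyond the ~42 kb 4q/10q homology) > distal
# evidence (chromosome-unique downstream flank, and the PAS variant within
# pLAM) > per-unit XapI/BlnI motif majority. Flank evidence is locus-unique;
# motifs recur per unit and are individually error-prone. A disagreement
# between levels (e.g. a 10q upstream flank over XapI-carrying units — the
# 4q-to-10q translocation configuration) sets the conflict flag while the
# higher-precedence source wins.

#' Haplotype call for one read
#'
#' @slot chrom "4q", "10q" or "unknown".
#' @slot ab "A", "B" or "unknown".
#' @slot subtype "AS", "AM", "AL", "none" (B alleles) or "unknown".
#' @slot evidence named list of per-source verdicts (flank_up, flank_down,
#'   pas, xapi_blni, distal_feature).
#' @slot conflict TRUE when non-unknown evidence sources disagree.
#' @export
setClass("HaplotypeCall", representation(
  chrom = "character", ab = "character", subtype = "character",
  evidence = "list", conflict = "logical"))

setValidity("HaplotypeCall", function(object) {
  if (!object@chrom %in% c("4q", "10q", "unknown")) return("bad chrom")
  if (!object@ab %in% c("A", "B", "unknown")) return("bad ab")
  if (!object@subtype %in% c("AS", "AM", "AL", "none", "unknown"))
    return("bad subtype")
  if (object@subtype %in% c("AS", "AM", "AL") && object@ab != "A")
    return("subtype other than none/unknown requires ab = A")
  TRUE
})

setMethod("show", "HaplotypeCall", function(object) {
  cat(sprintf("HaplotypeCall: %s%s%s%s\n",
              object@chrom,
              if (object@ab == "unknown") "?" else object@ab,
              if (object@subtype %in% c("AS", "AM", "AL"))
                substr(object@subtype, 2, 2) else "",
              if (object@conflict) " [conflict]" else ""))
  ev <- vapply(object@evidence, function(e) paste(e, collapse = "/"), character(1))
  for (n in names(ev)) cat(sprintf("  %-14s %s\n", n, ev[n]))
})

#' Haplotype label as printed in reports (e.g. "4qAL", "10qA", "4qB")
#' @param call a \linkS4class{HaplotypeCall}
#' @return character scalar
#' @export
haplotypeLabel <- function(call) {
  ab <- if (call@ab == "unknown") "?" else call@ab
  sub <- if (call@chrom == "4q" && call@subtype %in% c("AS", "AM", "AL"))
    substr(call@subtype, 2, 2) else ""
  paste0(call@chrom, ab, sub)
}

## map a unit-coordinate position into forward read coordinates using the
## seed anchors of one unit instance
.unit_pos_to_read <- function(ann, unit_row, upos, k = 15L) {
  anc <- ann@anchors
  if (nrow(anc) == 0L) return(NA_integer_)
  sel <- anc$strand == unit_row$strand &
    anc$rpos >= unit_row$read_start - 20L & anc$rpos <= unit_row$read_end + 20L
  a <- anc[sel, , drop = FALSE]
  if (nrow(a) == 0L) return(NA_integer_)
  i <- which.min(abs(a$tpos - upos))
  if (unit_row$strand == "+") a$rpos[i] + (upos - a$tpos[i])
  else a$rpos[i] + (k - 1L) - (upos - a$tpos[i])
}

## per-unit XapI/BlnI genotype at the diagnostic unit coordinates
.unit_motif_votes <- function(ann, bundle, window = 30L, k = 15L) {
  diag <- bundle@diagnostics
  if (!all(c("xapi_pos", "blni_pos") %in% names(diag)))
    return(data.frame(xapi = logical(0), blni = logical(0)))
  units <- ann@units
  units <- units[units$completeness %in% c("full", "truncated_internal"), ,
                 drop = FALSE]
  if (nrow(units) == 0L)
    return(data.frame(xapi = logical(0), blni = logical(0)))
  xp <- ann@motif_sites$xapi$pos
  bp <- ann@motif_sites$blni$pos
  res <- lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, , drop = FALSE]
    px <- .unit_pos_to_read(ann, u, diag[["xapi_pos"]], k)
    pb <- .unit_pos_to_read(ann, u, diag[["blni_pos"]], k)
    data.frame(
      xapi = !is.na(px) && length(xp) > 0L && any(abs(xp - px) <= window),
      blni = !is.na(pb) && length(bp) > 0L && any(abs(bp - pb) <= window))
  })
  do.call(rbind, res)
}

#' Call 4q/10q chromosome and A/B haplotype for an annotated read
#'
#' Chromosome: upstream-flank evidence when the read extends beyond the 4q/10q
#' homology, else distal evidence (downstream flank; PAS variant inside the
#' pLAM hit), else the per-unit XapI/BlnI majority. A/B: pLAM hit means A, qB
#' hit means B (disabled with a warning-free unknown when the bundle lacks
#' qB). The subtype is derived from the distal partial unit length. Conflicts
#' between evidence sources (translocation configurations) are flagged, with
#' the higher-precedence source deciding.
#'
#' @param ann a \linkS4class{ReadAnnotation}.
#' @param bundle a \linkS4class{ReferenceBundle}.
#' @param params a \linkS4class{PipelineParams}.
#' @return a \linkS4class{HaplotypeCall}
#' @export
callHaplotype <- function(ann, bundle, params = pipelineParams()) {
  feats <- ann@features
  hasf <- function(f) f %in% feats$feature

  ## -- chromosome evidence -------------------------------------------------
  ev_up <- if (hasf("flank4q_up")) "4q" else if (hasf("flank10q_up")) "10q"
           else "unknown"
  ev_down <- if (hasf("flank4q_down")) "4q" else if (hasf("flank10q_down")) "10q"
             else "unknown"

  ## PAS variant within the pLAM hit
  ev_pas <- "unknown"
  diag <- bundle@diagnostics
  if (hasf("pLAM") && "pas_pos" %in% names(diag)) {
    h <- feats[feats$feature == "pLAM", , drop = FALSE][1L, ]
    ppos <- if (h$strand == "+") h$read_start + (diag[["pas_pos"]] - h$tstart)
            else h$read_end - (diag[["pas_pos"]] - h$tstart)
    near <- function(df) length(df$pos) > 0L && any(abs(df$pos - ppos) <= 30L)
    p4 <- near(ann@motif_sites$pas_4qA)
    p10 <- near(ann@motif_sites$pas_10qA)
    if (p4 && !p10) ev_pas <- "4q" else if (p10 && !p4) ev_pas <- "10q"
  }

  votes <- .unit_motif_votes(ann, bundle, k = params@seed_k)
  n4 <- sum(votes$xapi & !votes$blni)
  n10 <- sum(votes$blni & !votes$xapi)
  ev_motif <- if (nrow(votes) == 0L || n4 == n10) "unknown"
              else if (n4 > n10) "4q" else "10q"

  ## distal evidence combines downstream flank and PAS
  ev_distal <- if (ev_down != "unknown") ev_down else ev_pas
  chrom <- if (ev_up != "unknown") ev_up
           else if (ev_distal != "unknown") ev_distal
           else ev_motif
  known <- setdiff(unique(c(ev_up, ev_down, ev_pas, ev_motif)), "unknown")
  conflict <- length(known) > 1L

  ## -- A/B -----------------------------------------------------------------
  has_plam <- hasf("pLAM")
  has_qb <- hasf("qB")
  ab <- if (has_plam && has_qb) {
    conflict <- TRUE
    a_id <- max(feats$identity[feats$feature == "pLAM"])
    b_id <- max(feats$identity[feats$feature == "qB"])
    if (a_id >= b_id) "A" else "B"
  } else if (has_plam) "A" else if (has_qb) "B" else "unknown"

  subtype <- callSubtype(distalPartialLength(ann), ab, params)

  new("HaplotypeCall", chrom = chrom, ab = ab, subtype = subtype,
      evidence = list(flank_up = ev_up, flank_down = ev_down, pas = ev_pas,
                      xapi_blni = ev_motif,
                      distal_feature = if (has_plam) "pLAM"
                                       else if (has_qb) "qB" else "none"),
      conflict = conflict)
}

#' Distal subtype from the distal partial unit length
#'
#' A-type alleles are subtyped by the length of the partial D4Z4 unit distal
#' to the last complete unit: S for ~0.3 kb, M for ~0.6 kb (a distal structure
#' between the classical S and L forms), L for ~1.9 kb. Bin edges are
#' configurable via \code{subtype_bins} (defaults: S <= 450 bp, M in
#' (450, 1000], L >= 1500; lengths between bins give "unknown").
#'
#' @param distal_partial_len length in bp (0 or NA gives "unknown").
#' @param ab "A", "B" or "unknown"; B gives subtype "none".
#' @param params a \linkS4class{PipelineParams}.
#' @return one of "AS", "AM", "AL", "none", "unknown"
#' @export
callSubtype <- function(distal_partial_len, ab, params = pipelineParams()) {
  if (identical(ab, "B")) return("none")
  if (!identical(ab, "A")) return("unknown")
  b <- params@subtype_bins
  l <- distal_partial_len
  if (is.na(l) || l <= 0) return("unknown")
  if (l <= b[1L]) "AS"
  else if (l <= b[2L]) "AM"
  else if (l >= b[3L]) "AL"
  else "unknown"
}

## ---------------------------------------------------------------------------
## AlleleGroup

#' A set of reads assigned to one allele
#'
#' Spanning reads are bucketed by the exact key (chromosome, A/B, subtype, RU
#' structure); nonspanning reads are attached when exactly one group is
#' compatible with their evidence. The mosaic fraction is the group's share of
#' same-chromosome spanning reads, with a Wilson score interval. Spanning-read
#' proportions are length-biased (short arrays fragment less and sequence
#' preferentially), so the fraction is an estimate of the read-level, not
#' cell-level, mosaic proportion.
#'
#' @slot chrom,ab,subtype haplotype key.
#' @slot structure integer vector of per-segment RU counts, proximal to
#'   distal.
#' @slot spanning_ids,nonspanning_ids read identifiers.
#' @slot mosaic_fraction,mosaic_ci fraction of same-chromosome spanning reads
#'   and its 95\% Wilson interval.
#' @slot distal_partial_len median distal partial length (bp) over members.
#' @slot upstream_inverted TRUE if any member read captured an inverted
#'   upstream segment (the D4S2463 configuration).
#' @slot note free-text caveats (e.g. indistinguishable-allele collapse).
#' @export
setClass("AlleleGroup", representation(
  chrom = "character", ab = "character", subtype = "character",
  structure = "integer", spanning_ids = "character",
  nonspanning_ids = "character", mosaic_fraction = "numeric",
  mosaic_ci = "numeric", distal_partial_len = "integer",
  upstream_inverted = "logical", note = "character"))

setMethod("show", "AlleleGroup", function(object) {
  cat(sprintf("AlleleGroup %s%s%s  RU %s  (%d spanning, %d attached)\n",
              object@chrom, object@ab,
              if (object@subtype %in% c("AS", "AM", "AL"))
                substr(object@subtype, 2, 2) else "",
              .structure_label(object@structure),
              length(object@spanning_ids), length(object@nonspanning_ids)))
})

#' @describeIn AlleleGroup-class total RU count over all segments
#' @param x an AlleleGroup
#' @export
ruTotal <- function(x) sum(x@structure)

#' Group annotated reads into alleles
#'
#' @param annotations named list of \linkS4class{ReadAnnotation}.
#' @param bundle a \linkS4class{ReferenceBundle}.
#' @param params a \linkS4class{PipelineParams}.
#' @param calls optional pre-computed list of \linkS4class{HaplotypeCall}
#'   parallel to \code{annotations}.
#' @return list of \linkS4class{AlleleGroup}, sorted within chromosome by
#'   total RU; empty (with a warning) when no spanning read is present.
#' @export
groupAlleles <- function(annotations, bundle, params = pipelineParams(),
                         calls = NULL) {
  if (is.null(calls))
    calls <- lapply(annotations, callHaplotype, bundle = bundle, params = params)
  span <- vapply(annotations, isSpanning, logical(1))
  if (!any(span)) {
    warning("no spanning reads: returning empty allele grouping")
    return(list())
  }
  keys <- vapply(names(annotations), function(id) {
    if (!span[[id]]) return(NA_character_)
    cl <- calls[[id]]
    paste(cl@chrom, cl@ab, cl@subtype,
          .structure_label(ruStructure(annotations[[id]])), sep = "|")
  }, character(1))

  groups <- list()
  for (key in unique(stats::na.omit(keys))) {
    ids <- names(annotations)[!is.na(keys) & keys == key]
    cl <- calls[[ids[1L]]]
    anns <- annotations[ids]
    dpl <- as.integer(round(median(vapply(anns, distalPartialLength, integer(1)))))
    inv <- any(vapply(anns, function(a) !is.na(a@inverted_upstream), logical(1)))
    groups[[key]] <- new("AlleleGroup",
      chrom = cl@chrom, ab = cl@ab, subtype = cl@subtype,
      structure = ruStructure(anns[[1L]]), spanning_ids = ids,
      nonspanning_ids = character(0), mosaic_fraction = NA_real_,
      mosaic_ci = c(NA_real_, NA_real_), distal_partial_len = dpl,
      upstream_inverted = inv, note = character(0))
  }

  ## mosaic fractions over same-chromosome spanning reads
  chroms <- vapply(groups, function(g) g@chrom, character(1))
  for (ch in unique(chroms)) {
    ix <- which(chroms == ch)
    tot <- sum(vapply(groups[ix], function(g) length(g@spanning_ids), integer(1)))
    for (i in ix) {
      n <- length(groups[[i]]@spanning_ids)
      groups[[i]]@mosaic_fraction <- n / tot
      groups[[i]]@mosaic_ci <- .wilson(n, tot)
      if (length(ix) == 1L)
        groups[[i]]@note <- paste("single group for", ch, ":",
          "homozygous or indistinguishable alleles collapse into one group")
    }
  }

  ## attach nonspanning reads to a unique compatible group
  for (id in names(annotations)[!span]) {
    cl <- calls[[id]]
    ru_lb <- sum(ruStructure(annotations[[id]]))
    compatible <- vapply(groups, function(g) {
      (cl@chrom == "unknown" || g@chrom == cl@chrom) &&
      (cl@ab == "unknown" || g@ab == cl@ab) &&
      (cl@subtype %in% c("unknown") || cl@ab == "unknown" ||
         g@subtype == cl@subtype) &&
      ru_lb <= ruTotal(g)
    }, logical(1))
    if (sum(compatible) == 1L) {
      j <- which(compatible)
      groups[[j]]@nonspanning_ids <- c(groups[[j]]@nonspanning_ids, id)
    }
  }

  ## sort: chromosome, then total RU
  ord <- order(vapply(groups, function(g) g@chrom, character(1)),
               vapply(groups, ruTotal, numeric(1)))
  unname(groups[ord])
}

#' Tabulate allele groups
#'
#' One row per allele with the columns of a haplotyping summary: chromosome,
#' haplotype label, RU structure rendered "15 + 2 + 5" for in-cis duplicated
#' alleles, spanning/attached read counts, whether the inverted upstream
#' D4S2463 unit was captured, and the mosaic fraction with its interval.
#' An empty grouping yields a header-only table.
#'
#' @param groups list of \linkS4class{AlleleGroup}.
#' @return data.frame
#' @export
reportTable <- function(groups) {
  cols <- data.frame(chrom = character(0), haplotype = character(0),
                     ru = character(0), ru_total = integer(0),
                     n_spanning = integer(0), n_attached = integer(0),
                     upstream_D4S2463 = character(0),
                     mosaic_fraction = numeric(0), mosaic_lo = numeric(0),
                     mosaic_hi = numeric(0), stringsAsFactors = FALSE)
  if (length(groups) == 0L) return(cols)
  rows <- lapply(groups, function(g) {
    lab <- paste0(g@chrom, if (g@ab == "unknown") "?" else g@ab,
                  if (g@chrom == "4q" && g@subtype %in% c("AS", "AM", "AL"))
                    substr(g@subtype, 2, 2) else "")
    data.frame(chrom = g@chrom, haplotype = lab,
               ru = .structure_label(g@structure), ru_total = ruTotal(g),
               n_spanning = length(g@spanning_ids),
               n_attached = length(g@nonspanning_ids),
               upstream_D4S2463 = if (g@upstream_inverted) "Y" else "N",
               mosaic_fraction = round(g@mosaic_fraction, 4),
               mosaic_lo = round(g@mosaic_ci[1L], 4),
               mosaic_hi = round(g@mosaic_ci[2L], 4),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
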