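# Allele consensus from spanning reads, and per-unit variant matrices.
#
# The consensus engine anchors every read to the backbone (longest spanning
# read) unit-by-unit before any base-level alignment: each array unit and each
# inter-unit interval is aligned to its positional counterpart only. This
# prevents the repeat-register slippage generic polishers suffer on
# macrosatellites — a read can never be corrected against the wrong unit copy
# — and is why the consensus provably preserves the raw-read array structure
# (the invariant is re-checked after polishing and violations abort). Column
# calls are plurality votes including gaps, ties broken toward the backbone;
# insertions are adopted when more than half of the covering reads agree on
# the inserted string.

#' Allele consensus sequence
#'
#' @slot allele_key label of the allele group.
#' @slot seq consensus DNA string.
#' @slot backbone_id read id of the backbone (longest spanning read).
#' @slot rounds polishing rounds applied (0 = single-read passthrough).
#' @slot support mean per-column vote support fraction.
#' @slot support_profile per-column support fractions.
#' @slot structure RU structure of the consensus (validated against the
#'   group).
#' @slot flags character vector of caveats ("unpolished", "reads_skipped:n").
#' @export
setClass("AlleleConsensus", representation(
  allele_key = "character", seq = "character", backbone_id = "character",
  rounds = "integer", support = "numeric", support_profile = "numeric",
  structure = "integer", flags = "character"))

setMethod("show", "AlleleConsensus", function(object) {
  cat(sprintf("AlleleConsensus %s: %d bp, RU %s, %d round(s), support %.4f%s\n",
              object@allele_key, nchar(object@seq),
              .structure_label(object@structure), object@rounds,
              object@support,
              if (length(object@flags)) paste0(" [", paste(object@flags,
                collapse = ", "), "]") else ""))
})

#' @describeIn AlleleConsensus-class the consensus sequence
#' @param x an AlleleConsensus
#' @export
consensusSeq <- function(x) x@seq

## orient a read so its main array runs proximal -> distal ("+")
.orient_read <- function(read, ann, bundle, params) {
  if (ann@orientation == "-") {
    read <- revcomp(read)
    ann <- annotateRead(read, bundle, params, read_id = ann@read_id)
  }
  list(read = read, ann = ann)
}

## block cut points of an annotated sequence: alternating inter/unit blocks
## over the main-chain unit instances (plus-oriented annotation expected)
.blocks_of <- function(ann) {
  u <- ann@units[ann@units$strand == "+", , drop = FALSE]
  u <- u[order(u$read_start), , drop = FALSE]
  n <- ann@read_length
  if (nrow(u) == 0L)
    return(data.frame(start = 1L, end = n, unit = NA_integer_))
  rows <- list()
  prev <- 1L
  for (i in seq_len(nrow(u))) {
    if (u$read_start[i] > prev)
      rows[[length(rows) + 1L]] <- data.frame(start = prev,
        end = u$read_start[i] - 1L, unit = NA_integer_)
    rows[[length(rows) + 1L]] <- data.frame(start = u$read_start[i],
      end = u$read_end[i], unit = i)
    prev <- u$read_end[i] + 1L
  }
  if (prev <= n)
    rows[[length(rows) + 1L]] <- data.frame(start = prev, end = n,
                                            unit = NA_integer_)
  do.call(rbind, rows)
}

## one polishing round: vote all reads against the backbone, block-anchored
.polish_round <- function(backbone, bb_ann, reads, anns, params) {
  bases <- c("A", "C", "G", "T", "N", "-")
  n <- nchar(backbone)
  votes <- matrix(0L, nrow = 6L, ncol = n)
  cov <- integer(n)
  ins_tally <- new.env(parent = emptyenv())
  bvec <- strsplit(backbone, "")[[1]]
  votes[cbind(match(bvec, bases), seq_len(n))] <- 1L
  cov <- cov + 1L

  bb_blocks <- .blocks_of(bb_ann)
  bb_units <- which(!is.na(bb_blocks$unit))
  skipped <- 0L

  for (id in names(reads)) {
    rb <- .blocks_of(anns[[id]])
    r_units <- which(!is.na(rb$unit))
    if (length(r_units) != length(bb_units)) { skipped <- skipped + 1L; next }
    read <- reads[[id]]
    ## pair blocks positionally: unit i <-> unit i; inter-blocks by flanking
    ## unit indices (pre-array, between units, post-array)
    nb <- nrow(bb_blocks)
    for (bi in seq_len(nb)) {
      bu <- bb_blocks$unit[bi]
      ri <- if (!is.na(bu)) r_units[match(bi, bb_units)]
            else {
              ## inter block: find read block in the same junction slot
              slot <- sum(bb_units < bi)   # number of units before this block
              rcand <- which(is.na(rb$unit))
              rsel <- rcand[vapply(rcand, function(j) sum(r_units < j),
                                   integer(1)) == slot]
              if (length(rsel)) rsel[1L] else NA_integer_
            }
      if (is.na(ri)) next
      bs <- bb_blocks$start[bi]; be <- bb_blocks$end[bi]
      bseq <- substr(backbone, bs, be)
      rseq <- substr(read, rb$start[ri], rb$end[ri])
      if (nchar(rseq) < 15L) next
      terminal <- bi == 1L || bi == nb
      if (identical(bseq, rseq)) {
        ## fast path: identical block, vote the diagonal
        j <- (bs - 1L) + seq_len(nchar(bseq))
        votes[cbind(match(strsplit(bseq, "")[[1]], bases), j)] <-
          votes[cbind(match(strsplit(bseq, "")[[1]], bases), j)] + 1L
        cov[j] <- cov[j] + 1L
        next
      }
      ## extend both sides by a margin so alignment edge artifacts fall
      ## outside the scored core; votes are kept for core columns only
      mrg <- 50L
      b_lo <- max(1L, bs - mrg); b_hi <- min(n, be + mrg)
      r_lo <- max(1L, rb$start[ri] - mrg)
      r_hi <- min(nchar(read), rb$end[ri] + mrg)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(substr(read, r_lo, r_hi)),
        Biostrings::DNAString(substr(backbone, b_lo, b_hi)),
        type = if (terminal) "overlap" else "global",
        gapOpening = 4, gapExtension = 1)
      p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
      q <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
      ## alignedSubject() spans the whole subject for global alignments and
      ## only the aligned window for ends-free ones
      s_off <- (b_lo - 1L) +
        (if (terminal) Biostrings::start(Biostrings::subject(al)) - 1L else 0L)
      qg <- q == "-"
      spos <- cumsum(!qg)
      nz <- !qg
      j <- s_off + spos[nz]
      core <- j >= bs & j <= be
      idx <- cbind(match(p[nz][core], bases), j[core])
      votes[idx] <- votes[idx] + 1L
      cov[j[core]] <- cov[j[core]] + 1L
      if (any(qg)) {
        at <- s_off + spos[qg]       # insertion after this subject position
        keep_ins <- at >= bs & at <= be
        if (any(keep_ins)) {
          tt <- tapply(p[qg][keep_ins], at[keep_ins], paste, collapse = "")
          for (a in names(tt)) {
            cur <- if (!is.null(ins_tally[[a]])) ins_tally[[a]] else character(0)
            ins_tally[[a]] <- c(cur, tt[[a]])
          }
        }
      }
    }
  }

  ## plurality call with backbone tie-break
  win <- integer(n)
  mx <- apply(votes, 2L, max)
  bb_idx <- match(bvec, bases)
  bb_is_max <- votes[cbind(bb_idx, seq_len(n))] == mx
  win[bb_is_max] <- bb_idx[bb_is_max]
  if (any(!bb_is_max)) win[!bb_is_max] <- apply(votes[, !bb_is_max, drop = FALSE],
                                                2L, which.max)
  support <- votes[cbind(win, seq_len(n))] / pmax(1L, cov)
  chars <- bases[win]
  ## majority insertions
  ins_keys <- ls(ins_tally)
  ins_at <- integer(0); ins_str <- character(0)
  for (key in ins_keys) {
    tb <- sort(table(ins_tally[[key]]), decreasing = TRUE)
    at <- as.integer(key)
    if (tb[1L] > cov[max(1L, at)] / 2) {
      ins_at <- c(ins_at, at)
      ins_str <- c(ins_str, names(tb)[1L])
    }
  }
  if (length(ins_at)) {
    ord <- order(ins_at)
    pieces <- character(0); prev <- 0L
    for (i in ord) {
      pieces <- c(pieces, paste(chars[seq_len(ins_at[i] - prev) + prev],
                                collapse = ""), ins_str[i])
      prev <- ins_at[i]
    }
    pieces <- c(pieces, paste(chars[seq_len(n - prev) + prev], collapse = ""))
    seq <- paste(pieces, collapse = "")
  } else seq <- paste(chars, collapse = "")
  list(seq = gsub("-", "", seq), support = support, skipped = skipped)
}

#' Build an allele consensus from spanning reads
#'
#' The longest spanning read serves as the backbone; every other member read
#' is anchored to it unit-by-unit, column plurality votes (including gaps and
#' majority insertions) are applied, and the procedure is repeated for
#' \code{consensus_rounds} rounds with re-annotation between rounds. A group
#' with a single spanning read is passed through unpolished (flagged). After
#' polishing, the consensus is re-annotated and its RU structure compared to
#' the group's: any change aborts with a diagnostic — a restructured consensus
#' is never emitted.
#'
#' @param group an \linkS4class{AlleleGroup}.
#' @param reads named character vector covering at least the group's spanning
#'   reads.
#' @param bundle a \linkS4class{ReferenceBundle}.
#' @param params a \linkS4class{PipelineParams}.
#' @return an \linkS4class{AlleleConsensus}
#' @export
buildConsensus <- function(group, reads, bundle, params = pipelineParams()) {
  ids <- group@spanning_ids
  miss <- setdiff(ids, names(reads))
  if (length(miss)) stop("missing member reads: ", paste(miss, collapse = ", "))
  key <- paste0(group@chrom, group@ab,
                if (group@subtype %in% c("AS", "AM", "AL"))
                  substr(group@subtype, 2, 2) else "",
                "_", paste(group@structure, collapse = "_"))

  if (length(ids) == 1L) {
    or <- .orient_read(reads[[ids]], annotateRead(reads[[ids]], bundle, params,
                                                  ids), bundle, params)
    return(new("AlleleConsensus", allele_key = key, seq = or$read,
               backbone_id = ids, rounds = 0L, support = 1,
               support_profile = rep(1, nchar(or$read)),
               structure = ruStructure(or$ann), flags = "unpolished"))
  }

  oriented <- list(); anns <- list()
  for (id in ids) {
    ann <- annotateRead(reads[[id]], bundle, params, read_id = id)
    or <- .orient_read(reads[[id]], ann, bundle, params)
    oriented[[id]] <- or$read
    anns[[id]] <- or$ann
  }
  bb_id <- ids[which.max(nchar(unlist(oriented[ids])))]
  backbone <- oriented[[bb_id]]
  bb_ann <- anns[[bb_id]]
  others <- unlist(oriented[setdiff(ids, bb_id)])

  flags <- character(0)
  skipped_total <- 0L
  cons <- backbone; cons_ann <- bb_ann
  support <- rep(1, nchar(backbone))
  for (round in seq_len(params@consensus_rounds)) {
    ## round 1: the backbone read is the template, so it votes implicitly;
    ## later rounds: every member read votes against the current consensus
    voters <- if (round == 1L) setdiff(ids, bb_id) else ids
    pr <- .polish_round(cons, cons_ann, oriented[voters], anns[voters], params)
    skipped_total <- max(skipped_total, pr$skipped)
    if (pr$skipped > length(ids) / 2)
      stop("consensus aborted: ", pr$skipped, " of ", length(ids) - 1L,
           " reads do not share the backbone's array structure ",
           "(mixed-allele group?)")
    cons <- pr$seq
    support <- pr$support
    cons_ann <- annotateRead(cons, bundle, params, read_id = "consensus")
  }
  if (skipped_total > 0L)
    flags <- c(flags, paste0("reads_skipped:", skipped_total))

  got <- ruStructure(cons_ann)
  if (!identical(as.integer(got), as.integer(group@structure)))
    stop("consensus aborted: polishing changed the array structure (",
         .structure_label(group@structure), " -> ", .structure_label(got),
         "); refusing to emit a restructured consensus")
  new("AlleleConsensus", allele_key = key, seq = cons, backbone_id = bb_id,
      rounds = params@consensus_rounds, support = mean(support),
      support_profile = support, structure = as.integer(got), flags = flags)
}

#' Extract unit sequences from a consensus (or any allele-scale sequence)
#'
#' KpnI-anchored unit substrings in proximal-to-distal order, terminal
#' partials labeled; internal deletions are extracted intact.
#'
#' @param consensus an \linkS4class{AlleleConsensus} or character sequence.
#' @param bundle a \linkS4class{ReferenceBundle}.
#' @param params a \linkS4class{PipelineParams}.
#' @return data.frame: \code{seq}, \code{completeness}, \code{start},
#'   \code{end}, \code{length}; rows ordered proximal to distal.
#' @export
extractUnits <- function(consensus, bundle, params = pipelineParams()) {
  seq <- if (is(consensus, "AlleleConsensus")) consensus@seq else consensus
  ann <- annotateRead(seq, bundle, params, read_id = "consensus")
  u <- ann@units[ann@units$strand == ann@orientation, , drop = FALSE]
  u <- u[order(u$read_start), , drop = FALSE]
  if (ann@orientation == "-") u <- u[rev(seq_len(nrow(u))), , drop = FALSE]
  if (nrow(u) == 0L)
    return(data.frame(seq = character(0), completeness = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  seqs <- substring(seq, u$read_start, u$read_end)
  if (ann@orientation == "-") seqs <- vapply(seqs, revcomp, character(1))
  data.frame(seq = unname(seqs), completeness = u$completeness,
             start = u$read_start, end = u$read_end,
             length = u$length, stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## unit variant matrix

## align one unit against the canonical unit and tabulate variant events.
## events: data.frame(pos [1-based canonical], type SNV/ins/del, ref, alt)
.unit_events <- function(unit, canonical) {
  ## decide full vs partial from seed coverage of the canonical unit, so that
  ## a full-length unit with a large internal deletion is still aligned
  ## globally (the deletion becomes a del event) while a true terminal
  ## partial is aligned to its local canonical window
  anc <- .anchor_scan(.kmers(unit, 15L), canonical, 15L, 10L)
  partial <- if (nrow(anc) < 3L) nchar(unit) < 0.9 * nchar(canonical)
             else !(min(anc$tpos) <= 100L &&
                      max(anc$tpos) + 14L >= nchar(canonical) - 100L)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(unit), Biostrings::DNAString(canonical),
    type = if (partial) "global-local" else "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  q <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ## alignedSubject() spans the whole subject for global alignments and only
  ## the aligned window for pattern-global/subject-local ones
  s_off <- if (partial) Biostrings::start(Biostrings::subject(al)) - 1L else 0L
  cpos <- s_off + cumsum(q != "-")
  ev <- list()
  i <- 1L; n <- length(p)
  while (i <= n) {
    if (q[i] != "-" && p[i] != "-" && p[i] != q[i]) {
      ev[[length(ev) + 1L]] <- data.frame(pos = cpos[i], type = "SNV",
                                          ref = q[i], alt = p[i])
      i <- i + 1L
    } else if (q[i] != "-" && p[i] == "-") {
      j <- i
      while (j < n && q[j + 1L] != "-" && p[j + 1L] == "-") j <- j + 1L
      ev[[length(ev) + 1L]] <- data.frame(pos = cpos[i], type = "del",
        ref = paste(q[i:j], collapse = ""), alt = "")
      i <- j + 1L
    } else if (q[i] == "-") {
      j <- i
      while (j < n && q[j + 1L] == "-") j <- j + 1L
      ## pos = the next canonical base: the insertion sits before it
      ev[[length(ev) + 1L]] <- data.frame(pos = cpos[i] + 1L, type = "ins",
        ref = "", alt = paste(p[i:j], collapse = ""))
      i <- j + 1L
    } else i <- i + 1L
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(pos = integer(0), type = character(0),
                            ref = character(0), alt = character(0))
  list(events = events,
       coverage = c(s_off + 1L, s_off + sum(q != "-")))
}

#' Apply recorded variant events back onto the canonical unit
#'
#' Inverse of [callUnitVariants()] for one unit: applying a unit's events to
#' the canonical sequence (restricted to the unit's coverage interval)
#' reconstructs the unit byte-exactly.
#'
#' @param canonical canonical unit sequence.
#' @param events events data.frame (pos, type, ref, alt).
#' @param coverage integer pair: covered canonical interval (1-based
#'   inclusive).
#' @return reconstructed unit sequence
#' @export
applyUnitVariants <- function(canonical, events,
                              coverage = c(1L, nchar(canonical))) {
  seq <- substr(canonical, coverage[1L], coverage[2L])
  off <- coverage[1L] - 1L
  if (nrow(events) == 0L) return(seq)
  ev <- events[order(-events$pos), , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    p <- ev$pos[i] - off
    if (ev$type[i] == "SNV") {
      substr(seq, p, p) <- ev$alt[i]
    } else if (ev$type[i] == "del") {
      seq <- paste0(substr(seq, 1L, p - 1L),
                    substr(seq, p + nchar(ev$ref[i]), nchar(seq)))
    } else {  # ins: insertion after canonical position p-1 (before p)... the
      ## event records the canonical position of the next reference base
      seq <- paste0(substr(seq, 1L, p - 1L), ev$alt[i],
                    substr(seq, p, nchar(seq)))
    }
  }
  seq
}

#' Call per-unit variants against the canonical unit
#'
#' Globally aligns every extracted unit to the canonical unit (match +1,
#' mismatch -1, gap open -2, extend -1) and tabulates SNVs and indels. The
#' full event set is always stored; the display filter that hides small
#' inconsistent indels is applied only at render time by
#' [renderVariantMatrix()], never at storage. XapI/BlnI genotype columns
#' record the motif status of each unit at the diagnostic sites.
#'
#' @param units data.frame from [extractUnits()] (or character vector of unit
#'   sequences).
#' @param bundle a \linkS4class{ReferenceBundle} (canonical unit +
#'   diagnostics).
#' @param params a \linkS4class{PipelineParams}.
#' @return an object of class \code{"UnitVariantMatrix"}: list with
#'   \code{matrix} (units x variant-site character matrix with entries
#'   ref/alt/"missing"), \code{events} (per-unit event tables),
#'   \code{coverage}, \code{site_info}, \code{genotypes} (XapI/BlnI logical
#'   matrix), \code{canonical_md5}.
#' @export
callUnitVariants <- function(units, bundle, params = pipelineParams()) {
  if (is.data.frame(units)) {
    seqs <- units$seq
    labels <- units$completeness
  } else { seqs <- units; labels <- rep("full", length(seqs)) }
  canonical <- bundleSeq(bundle, "unit")
  res <- lapply(seqs, .unit_events, canonical = canonical)
  events <- lapply(res, `[[`, "events")
  coverage <- lapply(res, `[[`, "coverage")

  keys <- unique(unlist(lapply(events, function(e)
    if (nrow(e)) paste(e$pos, e$type, e$alt, sep = ":") else character(0))))
  keys <- keys[order(as.integer(sub(":.*", "", keys)))]
  m <- matrix("ref", nrow = length(seqs), ncol = length(keys),
              dimnames = list(paste0("unit_", seq_along(seqs)), keys))
  for (i in seq_along(seqs)) {
    e <- events[[i]]
    if (nrow(e)) {
      ek <- paste(e$pos, e$type, e$alt, sep = ":")
      m[i, match(ek, keys)] <- ifelse(e$type == "del", "del", e$alt)
    }
    ## positions outside this unit's coverage are missing, not ref
    kp <- as.integer(sub(":.*", "", keys))
    out_of_cov <- kp < coverage[[i]][1L] | kp > coverage[[i]][2L]
    m[i, out_of_cov & m[i, ] == "ref"] <- "missing"
  }
  site_info <- data.frame(
    key = keys, pos = as.integer(sub(":.*", "", keys)),
    type = sub("^[0-9]+:([a-zA-Z]+):.*$", "\\1", keys),
    len = vapply(strsplit(keys, ":"), function(x)
      if (x[2] == "SNV") 1L else nchar(x[3]) + (x[2] == "del") * 0L,
      integer(1)), stringsAsFactors = FALSE)
  ## deletion lengths come from the event tables
  for (i in seq_along(events)) {
    e <- events[[i]]
    if (!nrow(e)) next
    dl <- e$type == "del"
    if (any(dl)) {
      ek <- paste(e$pos[dl], "del", e$alt[dl], sep = ":")
      site_info$len[match(ek, site_info$key)] <- nchar(e$ref[dl])
    }
  }

  diag <- bundle@diagnostics
  gt <- matrix(NA, nrow = length(seqs), ncol = 2L,
               dimnames = list(rownames(m), c("XapI", "BlnI")))
  if (all(c("xapi_pos", "blni_pos") %in% names(diag))) {
    for (i in seq_along(seqs)) {
      site <- function(pos, pat) {
        lo <- max(1L, pos - coverage[[i]][1L] + 1L - 30L)
        hi <- min(nchar(seqs[i]), pos - coverage[[i]][1L] + 1L + 35L)
        if (hi <= lo) return(NA)
        grepl(pat, substr(seqs[i], lo, hi))
      }
      gt[i, "XapI"] <- site(diag[["xapi_pos"]], "[AG]AATT[CT]")
      gt[i, "BlnI"] <- site(diag[["blni_pos"]], "CCTAGG")
    }
  }
  structure(list(matrix = m, events = events, coverage = coverage,
                 site_info = site_info, genotypes = gt, labels = labels,
                 canonical_len = nchar(canonical),
                 canonical_md5 = .hash(canonical)),
            class = "UnitVariantMatrix")
}

#' @export
print.UnitVariantMatrix <- function(x, ...) {
  cat(sprintf("UnitVariantMatrix: %d units x %d variant sites\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Render a variant matrix with the small-indel display filter
#'
#' Indels shorter than \code{min_indel} nt that are not shared by at least two
#' units are hidden (render-time only; storage keeps everything).
#'
#' @param uvm a \code{UnitVariantMatrix}.
#' @param min_indel threshold (default 4 nt).
#' @return filtered character matrix
#' @export
renderVariantMatrix <- function(uvm, min_indel = 4L) {
  keep <- rep(TRUE, ncol(uvm$matrix))
  for (j in seq_len(ncol(uvm$matrix))) {
    si <- uvm$site_info[j, ]
    if (si$type %in% c("ins", "del") && si$len < min_indel) {
      shared <- sum(!uvm$matrix[, j] %in% c("ref", "missing"))
      if (shared < 2L) keep[j] <- FALSE
    }
  }
  uvm$matrix[, keep, drop = FALSE]
}

#' Compare two allele variant matrices
#'
#' Per-unit and aggregate identity over the union of variant sites, with a
#' verdict: \code{identical} (same unit count, every shared call equal),
#' \code{related} (aggregate identity >= \code{related_min}), else
#' \code{distinct}. Disagreement at the chromosome-diagnostic XapI/BlnI
#' genotype columns forces \code{distinct}. Matrices must be on the same
#' canonical unit.
#'
#' @param a,b \code{UnitVariantMatrix} objects.
#' @param related_min aggregate-identity threshold for "related" (default
#'   0.98).
#' @return list: \code{verdict}, \code{aggregate_identity},
#'   \code{per_unit_identity}, \code{n_mismatch}, \code{diagnostic_conflict}
#' @export
compareAlleles <- function(a, b, related_min = 0.98) {
  if (!identical(a$canonical_md5, b$canonical_md5))
    stop("variant matrices are on different canonical unit references")
  n <- min(nrow(a$matrix), nrow(b$matrix))
  keys <- union(colnames(a$matrix), colnames(b$matrix))
  get <- function(m, i, k) {
    v <- rep("ref", length(k))
    hit <- match(k, colnames(m))
    v[!is.na(hit)] <- m[i, hit[!is.na(hit)]]
    v
  }
  ## per-unit identity normalized by canonical length: every disagreeing
  ## variant site costs its event length in bases
  site_len <- stats::setNames(
    pmax(1L, c(a$site_info$len, b$site_info$len)),
    c(a$site_info$key, b$site_info$key))
  ulen <- a$canonical_len
  per_unit <- numeric(n); mm <- 0L
  for (i in seq_len(n)) {
    va <- get(a$matrix, i, keys); vb <- get(b$matrix, i, keys)
    use <- va != "missing" & vb != "missing"
    bad <- use & va != vb
    per_unit[i] <- if (any(use))
      1 - sum(site_len[keys[bad]]) / ulen else NA_real_
    mm <- mm + sum(bad)
  }
  gt_conf <- FALSE
  if (!any(is.na(a$genotypes)) && !any(is.na(b$genotypes))) {
    ga <- colMeans(a$genotypes) >= 0.5
    gb <- colMeans(b$genotypes) >= 0.5
    gt_conf <- any(ga != gb)
  }
  agg <- mean(per_unit, na.rm = TRUE)
  same_shape <- nrow(a$matrix) == nrow(b$matrix)
  verdict <- if (gt_conf) "distinct"
    else if (same_shape && mm == 0L) "identical"
    else if (agg >= related_min) "related"
    else "distinct"
  list(verdict = verdict, aggregate_identity = agg,
       per_unit_identity = per_unit, n_mismatch = mm,
       diagnostic_conflict = gt_conf)
}

#' Write a variant matrix as TSV and minimal VCF
#'
#' The VCF uses one pseudo-contig per allele with positions
#' \code{(unit - 1) * unit_length + canonical position} (1-based per VCF
#' convention).
#'
#' @param uvm a \code{UnitVariantMatrix}.
#' @param bundle a \linkS4class{ReferenceBundle}.
#' @param allele_key contig name.
#' @param tsv,vcf output paths (NULL to skip either).
#' @return invisibly, the paths written
#' @export
writeVariantMatrix <- function(uvm, bundle, allele_key, tsv = NULL, vcf = NULL) {
  if (!is.null(tsv)) {
    df <- as.data.frame(uvm$matrix, stringsAsFactors = FALSE)
    df <- cbind(unit = rownames(uvm$matrix),
                XapI = uvm$genotypes[, "XapI"], BlnI = uvm$genotypes[, "BlnI"],
                df)
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(vcf)) {
    ulen <- unitLength(bundle)
    canonical <- bundleSeq(bundle, "unit")
    con <- file(vcf, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##contig=<ID=%s>", allele_key),
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    for (i in seq_along(uvm$events)) {
      e <- uvm$events[[i]]
      if (!nrow(e)) next
      for (r in seq_len(nrow(e))) {
        pos <- (i - 1L) * ulen + e$pos[r]
        if (e$type[r] == "SNV") {
          ref <- e$ref[r]; alt <- e$alt[r]
        } else if (e$type[r] == "del") {
          pos <- pos - 1L
          anch <- substr(canonical, e$pos[r] - 1L, e$pos[r] - 1L)
          ref <- paste0(anch, e$ref[r]); alt <- anch
        } else {
          pos <- pos - 1L
          anch <- substr(canonical, e$pos[r] - 1L, e$pos[r] - 1L)
          ref <- anch; alt <- paste0(anch, e$alt[r])
        }
        writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tUNIT=%d;TYPE=%s",
                           allele_key, pos, ref, alt, i, e$type[r]), con)
      }
    }
  }
  invisible(c(tsv = tsv, vcf = vcf))
}
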