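# Allele-anchored CpG methylation aggregation and statistics: pooled region
# means (DR1 / TSS windows, global and final-unit rates), coverage-filtered
# smoothed profiles, missing-aware autocorrelation, and repeat-length vs
# methylation correlations.
#
# Calls are consumed from a plain TSV dialect (read_id, read_pos [0-based
# position of the CpG C on the read forward strand], strand, prob_5mC); a
# modified-base BAM can be converted to this dialect upstream so the core
# never needs BAM. A call is counted methylated when prob_5mC >= the
# threshold (0.5 by default; calls at exactly 0.5 count methylated).

#' Per-allele aggregated methylome
#'
#' CpG-site-level methylation counts on an allele reference (consensus or
#' surrogate read), pooled over all reads assigned to the allele, plus the
#' per-read site-state matrix for single-molecule views.
#'
#' @slot allele_key allele label.
#' @slot ref the allele reference sequence the calls were anchored to.
#' @slot sites 1-based positions of the CpG C on the reference.
#' @slot n_meth,n_unmeth per-site methylated/unmethylated call counts.
#' @slot per_read long data.frame (read_id, site, state) for single-molecule
#'   analyses.
#' @slot units unit table of the annotated reference (for region statistics).
#' @slot orientation orientation of the reference's array.
#' @slot n_skipped_reads,n_skipped_calls reads not anchorable to the
#'   reference / calls not liftable to a CpG site.
#' @slot min_site_coverage,threshold parameters the methylome was built with.
#' @export
setClass("AlleleMethylome", representation(
  allele_key = "character", ref = "character", sites = "integer",
  n_meth = "integer", n_unmeth = "integer", per_read = "data.frame",
  units = "data.frame", orientation = "character",
  n_skipped_reads = "integer", n_skipped_calls = "integer",
  min_site_coverage = "integer", threshold = "numeric"))

setValidity("AlleleMethylome", function(object) {
  if (length(object@n_meth) != length(object@sites) ||
      length(object@n_unmeth) != length(object@sites))
    return("per-site count vectors must match the site vector")
  TRUE
})

setMethod("show", "AlleleMethylome", function(object) {
  cov <- object@n_meth + object@n_unmeth
  cat(sprintf("AlleleMethylome %s: %d CpG sites on %d bp reference\n",
              object@allele_key, length(object@sites), nchar(object@ref)))
  cat(sprintf("  covered sites: %d (>= %dx: %d); pooled 5mC rate %.4f\n",
              sum(cov > 0), object@min_site_coverage,
              sum(cov >= object@min_site_coverage),
              sum(object@n_meth) / max(1, sum(cov))))
})

#' @describeIn AlleleMethylome-class per-site coverage
#' @param x an AlleleMethylome
#' @export
siteCoverage <- function(x) x@n_meth + x@n_unmeth

#' @describeIn AlleleMethylome-class per-site fraction modified
#'   (n_meth / coverage; NaN where uncovered)
#' @export
fractionModified <- function(x) x@n_meth / (x@n_meth + x@n_unmeth)

#' @describeIn AlleleMethylome-class site table (1-based site, counts,
#'   coverage, fraction)
#' @export
methSiteTable <- function(x) {
  data.frame(site = x@sites, n_meth = x@n_meth, n_unmeth = x@n_unmeth,
             coverage = siteCoverage(x), fraction = fractionModified(x))
}

## ---------------------------------------------------------------------------
## anchoring

## coordinate map between an oriented read and the allele reference, built
## from shared seed anchors of matched unit instances and matched feature
## hits; returns a function read_pos -> ref_pos (approximate, to be snapped)
.read_ref_anchor_pairs <- function(ann_r, ann_R) {
  ## match unit instances between read and reference by array order
  ur <- ann_r@units[ann_r@units$strand == "+", , drop = FALSE]
  uR <- ann_R@units[ann_R@units$strand == "+", , drop = FALSE]
  ur <- ur[order(ur$read_start), , drop = FALSE]
  uR <- uR[order(uR$read_start), , drop = FALSE]
  fr <- ann_r@features; fR <- ann_R@features
  hasf <- function(fd, f) f %in% fd$feature
  nr <- nrow(ur); nR <- nrow(uR)
  if (nr == 0L || nR == 0L) return(NULL)
  offset <- if (isSpanning(ann_r) || nr == nR) 0L
    else if (hasf(fr, "p13E-11")) 0L
    else if (hasf(fr, "pLAM") || hasf(fr, "qB")) nR - nr
    else return(NULL)   # interior read: placement within the array ambiguous
  if (offset < 0L || nr + offset > nR) return(NULL)

  pairs <- list()
  ar <- ann_r@anchors; aR <- ann_R@anchors
  for (i in seq_len(nr)) {
    Ri <- i + offset
    sr <- ar[ar$strand == "+" & ar$rpos >= ur$read_start[i] &
               ar$rpos <= ur$read_end[i], , drop = FALSE]
    sR <- aR[aR$strand == "+" & aR$rpos >= uR$read_start[Ri] &
               aR$rpos <= uR$read_end[Ri], , drop = FALSE]
    j <- match(sr$tpos, sR$tpos)
    ok <- !is.na(j)
    if (any(ok))
      pairs[[length(pairs) + 1L]] <- data.frame(r = sr$rpos[ok],
                                                R = sR$rpos[j[ok]])
  }
  ## matched features contribute their endpoints as anchors
  common <- intersect(fr$feature, fR$feature)
  for (f in setdiff(common, "telomere")) {
    hr <- fr[fr$feature == f, , drop = FALSE][1L, ]
    hR <- fR[fR$feature == f, , drop = FALSE][1L, ]
    if (hr$strand == "+" && hR$strand == "+")
      pairs[[length(pairs) + 1L]] <- data.frame(
        r = c(hr$read_start, hr$read_end), R = c(hR$read_start, hR$read_end))
  }
  if (!length(pairs)) return(NULL)
  p <- unique(do.call(rbind, pairs))
  p <- p[order(p$r), , drop = FALSE]
  ## enforce monotonicity (defensive against stray anchor collisions)
  keep <- c(TRUE, diff(p$R) > 0)
  p[keep, , drop = FALSE]
}

#' Anchor per-read CpG calls onto an allele reference
#'
#' Lifts read-space methylation calls of the reads assigned to one allele onto
#' the CpG sites of the allele's consensus (or surrogate) reference, using the
#' unit-anchored coordinate map (seed anchors of positionally matched unit
#' instances plus matched feature endpoints, interpolated between anchors and
#' snapped to the nearest reference CpG within \code{snap} bp). Calls are
#' binarized at \code{meth_call_threshold} and combined across strands per
#' CpG. Reads that cannot be anchored (no shared units, ambiguous interior
#' placement) are skipped and counted.
#'
#' @param calls data.frame in the methylation TSV dialect
#'   ([readMethTSV()]).
#' @param annotations named list of \linkS4class{ReadAnnotation} for the
#'   allele's reads.
#' @param reads named character vector of read sequences.
#' @param reference allele reference: an \linkS4class{AlleleConsensus} or
#'   character sequence.
#' @param bundle a \linkS4class{ReferenceBundle}.
#' @param params a \linkS4class{PipelineParams}.
#' @param allele_key label for the methylome.
#' @param snap maximum lift distance to a reference CpG (default 3 bp).
#' @return an \linkS4class{AlleleMethylome}
#' @export
anchorCalls <- function(calls, annotations, reads, reference, bundle,
                        params = pipelineParams(), allele_key = "allele",
                        snap = 3L) {
  ref <- if (is(reference, "AlleleConsensus")) reference@seq else reference
  ann_R <- annotateRead(ref, bundle, params, read_id = "ref")
  sites <- Biostrings::start(
    Biostrings::matchPattern("CG", Biostrings::DNAString(ref)))
  nm <- integer(length(sites)); nu <- integer(length(sites))
  per_read <- list()
  skip_reads <- 0L; skip_calls <- 0L

  for (id in names(annotations)) {
    cr <- calls[calls$read_id == id, , drop = FALSE]
    if (nrow(cr) == 0L) next
    ann_r <- annotations[[id]]
    read <- reads[[id]]
    pos1 <- cr$read_pos + 1L       # 1-based C position on read forward strand
    if (ann_r@orientation == "-") {
      n <- nchar(read)
      read <- revcomp(read)
      ann_r <- annotateRead(read, bundle, params, read_id = id)
      pos1 <- n - pos1             # C of the CpG in oriented coordinates
    }
    pairs <- .read_ref_anchor_pairs(ann_r, ann_R)
    if (is.null(pairs) || nrow(pairs) < 2L) { skip_reads <- skip_reads + 1L; next }
    lifted <- round(approx(pairs$r, pairs$R, xout = pos1, rule = 2)$y)
    ## snap to the nearest reference CpG
    si <- findInterval(lifted, sites)
    cand_lo <- pmax(si, 1L)
    cand_hi <- pmin(si + 1L, length(sites))
    d_lo <- abs(lifted - sites[cand_lo])
    d_hi <- abs(lifted - sites[cand_hi])
    pick <- ifelse(d_lo <= d_hi, cand_lo, cand_hi)
    dist <- pmin(d_lo, d_hi)
    ok <- dist <= snap & si >= 0L
    skip_calls <- skip_calls + sum(!ok)
    if (!any(ok)) next
    state <- as.integer(cr$prob_5mC[ok] >= params@meth_call_threshold)
    site_idx <- pick[ok]
    ## one call per site per read (strand-combined)
    dup <- duplicated(site_idx)
    state <- state[!dup]; site_idx <- site_idx[!dup]
    nm[site_idx] <- nm[site_idx] + state
    nu[site_idx] <- nu[site_idx] + (1L - state)
    per_read[[id]] <- data.frame(read_id = id, site = sites[site_idx],
                                 state = state, stringsAsFactors = FALSE)
  }
  pr <- if (length(per_read)) do.call(rbind, per_read)
        else data.frame(read_id = character(0), site = integer(0),
                        state = integer(0))
  rownames(pr) <- NULL
  new("AlleleMethylome", allele_key = allele_key, ref = ref,
      sites = as.integer(sites), n_meth = nm, n_unmeth = nu, per_read = pr,
      units = ann_R@units, orientation = ann_R@orientation,
      n_skipped_reads = skip_reads, n_skipped_calls = skip_calls,
      min_site_coverage = params@min_site_coverage,
      threshold = params@meth_call_threshold)
}

## ---------------------------------------------------------------------------
## region statistics

## pooled methylation rate over sites within [lo, hi] on the reference
.pooled_rate <- function(m, lo, hi) {
  sel <- m@sites >= lo & m@sites <= hi
  tot <- sum(m@n_meth[sel]) + sum(m@n_unmeth[sel])
  if (tot == 0L) return(NA_real_)
  sum(m@n_meth[sel]) / tot
}

#' Region methylation statistics for one allele
#'
#' Pooled-count means (total methylated calls / total calls, never a mean of
#' site means) for: the DR1 and TSS windows within each full unit, the whole
#' array (global rate), and the final full unit. Regions with zero calls
#' yield NA, not 0.
#'
#' @param methylome an \linkS4class{AlleleMethylome}.
#' @param coords a \linkS4class{UnitCoords}.
#' @return list: \code{per_unit} (data.frame unit, dr1_mean, tss_mean,
#'   unit_mean), \code{global_rate}, \code{final_unit_rate}, \code{ru_count}
#' @export
regionStats <- function(methylome, coords = unitCoords()) {
  m <- methylome
  if (m@orientation != "+")
    stop("region statistics expect a proximal-to-distal (+) reference")
  u <- m@units[m@units$strand == "+", , drop = FALSE]
  u <- u[order(u$read_start), , drop = FALSE]
  full <- u[u$completeness %in% c("full", "truncated_internal"), , drop = FALSE]
  per_unit <- if (nrow(full)) do.call(rbind, lapply(seq_len(nrow(full)),
    function(i) {
      st <- full$read_start[i]
      data.frame(unit = i,
        dr1_mean = .pooled_rate(m, st + coords@dr1_start - 1L,
                                st + coords@dr1_end - 1L),
        tss_mean = .pooled_rate(m, st + coords@tss_pos - 1L - coords@tss_window,
                                st + coords@tss_pos - 1L + coords@tss_window),
        unit_mean = .pooled_rate(m, st, full$read_end[i]))
    })) else data.frame(unit = integer(0), dr1_mean = numeric(0),
                        tss_mean = numeric(0), unit_mean = numeric(0))
  global <- if (nrow(u)) .pooled_rate(m, min(u$read_start), max(u$read_end))
            else NA_real_
  final <- if (nrow(full)) per_unit$unit_mean[nrow(full)] else NA_real_
  list(per_unit = per_unit, global_rate = global, final_unit_rate = final,
       ru_count = nrow(full))
}

## ---------------------------------------------------------------------------
## smoothing

#' Smoothed methylation profile
#'
#' Running mean of per-site fraction modified over a window (default 2000 bp),
#' coverage-weighted by default, over sites passing the coverage filter. A
#' loess smoother (span 0.2) is available for percent-5mC style plots.
#'
#' @param methylome an \linkS4class{AlleleMethylome}.
#' @param window window width in bp.
#' @param min_coverage site coverage filter (defaults to the methylome's).
#' @param weight_by_coverage weight sites by coverage (TRUE) or equally.
#' @param method "window" (running mean) or "loess".
#' @param span loess span (used when \code{method = "loess"}).
#' @return data.frame: \code{pos}, \code{smoothed}, \code{coverage}
#' @export
smoothProfile <- function(methylome, window = 2000L,
                          min_coverage = methylome@min_site_coverage,
                          weight_by_coverage = TRUE, method = c("window", "loess"),
                          span = 0.2) {
  method <- match.arg(method)
  cov <- siteCoverage(methylome)
  keep <- cov >= min_coverage
  pos <- methylome@sites[keep]
  frac <- fractionModified(methylome)[keep]
  w <- if (weight_by_coverage) cov[keep] else rep(1, sum(keep))
  if (!length(pos))
    return(data.frame(pos = integer(0), smoothed = numeric(0),
                      coverage = numeric(0)))
  if (method == "loess") {
    fit <- stats::loess(frac ~ pos, weights = w, span = span,
                        degree = 2, family = "gaussian")
    return(data.frame(pos = pos, smoothed = as.numeric(stats::fitted(fit)),
                      coverage = w))
  }
  half <- window / 2
  cw <- cumsum(w); cwf <- cumsum(w * frac)
  lo <- findInterval(pos - half, pos, left.open = TRUE)   # first index >= pos-half is lo+1
  hi <- findInterval(pos + half, pos)
  cw_lo <- cwf_lo <- numeric(length(lo))
  cw_lo[lo > 0] <- cw[lo[lo > 0]]
  cwf_lo[lo > 0] <- cwf[lo[lo > 0]]
  sm <- (cwf[hi] - cwf_lo) / (cw[hi] - cw_lo)
  data.frame(pos = pos, smoothed = sm, coverage = w)
}

## ---------------------------------------------------------------------------
## autocorrelation

#' Missing-aware autocorrelation of a methylation profile
#'
#' Builds a vector of length n (the reference length) holding the fraction
#' modified at CpG sites with coverage at or above the filter and NA
#' elsewhere, then computes the pairwise-complete autocorrelation: mean and
#' variance over observed entries; lag-l covariance over pairs with both
#' entries observed; normalized by the variance. acf(0) = 1 by construction.
#' This makes the NA handling explicit (a stock autocorrelation routine fed an
#' NA-laden vector either fails or propagates NA); on a fully observed vector
#' it agrees with the standard biased-denominator estimator up to the
#' pair-count normalization.
#'
#' @param methylome an \linkS4class{AlleleMethylome}, or a numeric vector with
#'   NAs for unobserved positions.
#' @param max_lag maximum lag in nt (10000 covers ~3 unit lengths; 500 for
#'   nucleosome-scale structure).
#' @param min_coverage site coverage filter (ignored for vector input).
#' @return data.frame: \code{lag} (0..max_lag), \code{acf} (NA where no pair
#'   exists)
#' @export
methylationAcf <- function(methylome, max_lag = 10000L,
                           min_coverage = NULL) {
  if (is(methylome, "AlleleMethylome")) {
    if (is.null(min_coverage)) min_coverage <- methylome@min_site_coverage
    x <- rep(NA_real_, nchar(methylome@ref))
    cov <- siteCoverage(methylome)
    keep <- cov >= min_coverage
    x[methylome@sites[keep]] <- fractionModified(methylome)[keep]
  } else x <- as.numeric(methylome)
  o <- which(!is.na(x))
  if (length(o) < 2L) stop("need at least 2 observed sites for autocorrelation")
  v <- x[o]
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  if (s2 == 0) stop("degenerate (constant) profile: autocorrelation undefined")
  d <- v - mu
  num <- numeric(max_lag + 1L); cnt <- numeric(max_lag + 1L)
  num[1L] <- sum(d^2); cnt[1L] <- length(o)
  n <- length(o)
  hi_all <- findInterval(o + max_lag, o)
  chunk <- 4000L
  for (st in seq.int(1L, n, by = chunk)) {
    en <- min(n, st + chunk - 1L)
    i_idx <- st:en
    lens <- hi_all[i_idx] - i_idx
    lens[lens < 0L] <- 0L
    if (sum(lens) == 0) next
    i_rep <- rep(i_idx, lens)
    j_idx <- sequence(lens) + i_rep
    lag <- o[j_idx] - o[i_rep]
    pr <- d[i_rep] * d[j_idx]
    agg <- rowsum(cbind(pr, 1), lag)
    lg <- as.integer(rownames(agg))
    num[lg + 1L] <- num[lg + 1L] + agg[, 1L]
    cnt[lg + 1L] <- cnt[lg + 1L] + agg[, 2L]
  }
  acf <- ifelse(cnt > 0, (num / pmax(cnt, 1)) / s2, NA_real_)
  data.frame(lag = 0:max_lag, acf = acf)
}

#' Dominant autocorrelation peak within a lag window
#'
#' CpG sites sit at irregular positions, so the number of site pairs at any
#' one exact integer lag is small and the raw per-lag estimates are noisy; the
#' peak is therefore located on a short moving average of the ACF (half-width
#' \code{smooth} lags, default 5) before taking the argmax.
#'
#' @param acf data.frame from [methylationAcf()].
#' @param lo,hi lag window (nt).
#' @param smooth moving-average half-width in lags (0 = raw argmax).
#' @return the lag (nt) of the maximum (smoothed) acf value within [lo, hi]
#' @export
acfPeak <- function(acf, lo, hi, smooth = 5L) {
  v <- acf$acf
  if (smooth > 0L) {
    n <- length(v)
    obs <- !is.na(v)
    vv <- ifelse(obs, v, 0)
    cs <- cumsum(vv); cn <- cumsum(as.numeric(obs))
    i <- seq_len(n)
    lo_i <- pmax(i - smooth, 1L); hi_i <- pmin(i + smooth, n)
    v <- (cs[hi_i] - cs[lo_i] + vv[lo_i]) /
         pmax(1, cn[hi_i] - cn[lo_i] + obs[lo_i])
  }
  sel <- acf$lag >= lo & acf$lag <= hi & !is.na(v)
  if (!any(sel)) return(NA_integer_)
  acf$lag[sel][which.max(v[sel])]
}

## ---------------------------------------------------------------------------
## length vs methylation correlation

#' Correlate repeat number with methylation rate across alleles
#'
#' Pearson and Spearman coefficients of (RU count, rate) per group, with
#' linear-fit parameters. Needs at least 3 alleles per group; degenerate
#' variance yields NA coefficients.
#'
#' @param stats data.frame with columns \code{ru}, \code{rate} and optionally
#'   \code{group}.
#' @return data.frame: group, n, pearson, spearman, slope, intercept
#' @export
lengthMethylationCorrelation <- function(stats) {
  if (!"group" %in% names(stats)) stats$group <- "all"
  out <- lapply(split(stats, stats$group), function(g) {
    g <- g[!is.na(g$rate) & !is.na(g$ru), , drop = FALSE]
    n <- nrow(g)
    if (n < 3L || stats::var(g$ru) == 0 || stats::var(g$rate) == 0) {
      return(data.frame(group = g$group[1L], n = n, pearson = NA_real_,
                        spearman = NA_real_, slope = NA_real_,
                        intercept = NA_real_))
    }
    fit <- lm(rate ~ ru, data = g)
    data.frame(group = g$group[1L], n = n,
               pearson = cor(g$ru, g$rate, method = "pearson"),
               spearman = cor(g$ru, g$rate, method = "spearman"),
               slope = unname(coef(fit)[2L]),
               intercept = unname(coef(fit)[1L]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## bedMethyl-style export

#' Write per-site methylation in bedMethyl style
#'
#' 0-based half-open intervals, strand-combined CpG sites, coverage and
#' percent modified — the tabular form produced by standard modified-base
#' pileup tools with CpG merging.
#'
#' @param methylome an \linkS4class{AlleleMethylome}.
#' @param path output path.
#' @param name contig name (defaults to the allele key).
#' @return invisibly, \code{path}
#' @export
writeBedMethyl <- function(methylome, path, name = methylome@allele_key) {
  cov <- siteCoverage(methylome)
  sel <- cov > 0
  df <- data.frame(chrom = name, start = methylome@sites[sel] - 1L,
                   end = methylome@sites[sel] + 1L, name = "m",
                   score = pmin(1000L, cov[sel]), strand = ".",
                   thickStart = methylome@sites[sel] - 1L,
                   thickEnd = methylome@sites[sel] + 1L, color = "0,0,0",
                   coverage = cov[sel],
                   percent = round(100 * fractionModified(methylome)[sel], 2))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
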