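# Seeded generator of synthetic reference bundles, alleles, long reads and
# per-read CpG methylation calls, with ground truth emitted for every run.
#
# Synthetic feature sequences are uniform-random DNA with diagnostic motifs
# planted at fixed offsets: the canonical unit is 4qA-type (XapI site present,
# BlnI-near-miss), and 10q-type units are derived by the two single-nucleotide
# variants that destroy the XapI site and create the BlnI site — mirroring how
# the two chromosomes are distinguished in restriction-based assays. A real
# CHM13-derived bundle is a drop-in replacement. CpG positions are the natural
# CG dinucleotides of the generated sequence (~1 per 16 bp in uniform-random
# DNA, denser than real D4Z4 but uniformly spread, which is what the
# methylation statistics need).

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

## replace the middle base of every regex match not overlapping a protected
## interval; iterate because replacement can create new matches
.scrub <- function(seq, pattern, protect = NULL) {
  for (round in 1:8) {
    m <- gregexpr(pattern, seq)[[1]]
    if (m[1L] == -1L) return(seq)
    hit <- as.integer(m)
    if (!is.null(protect))
      hit <- hit[!(hit >= protect[1L] - 6L & hit <= protect[2L])]
    if (!length(hit)) return(seq)
    for (p in hit) {
      at <- p + 2L
      old <- substr(seq, at, at)
      substr(seq, at, at) <- setdiff(.BASES, old)[1L]
    }
  }
  seq
}

#' Generate a synthetic reference bundle
#'
#' Builds the full feature set from seeded random DNA: a canonical 4qA-type
#' unit beginning with the KpnI site and carrying an XapI site at a fixed
#' offset (with a BlnI near-miss one SNV away at a second offset), p13E-11,
#' pLAM with the 4q poly(A) signal planted at a fixed offset, the qB-distal
#' sequence, chromosome-unique upstream/downstream flanks, the D4S2463
#' inverted truncated unit (reverse complement of the distal portion of the
#' unit), a shared 4q/10q upstream homology region, and a subtelomeric pool
#' from which in-cis duplication spacers are drawn. Stray KpnI/BlnI/XapI/PAS
#' motif matches are scrubbed from the generated sequences so planted sites
#' are the only diagnostic signal.
#'
#' @param seed integer seed; the bundle is reproducible from it.
#' @param unit_len canonical unit length in bp (default 3300).
#' @param homology_len length of the shared 4q/10q upstream homology region
#'   (default 42000 bp, the distance over which the two subtelomeres are
#'   indistinguishable).
#' @param xapi_pos,blni_pos,pas_pos diagnostic offsets (unit / pLAM
#'   coordinates).
#' @return a \linkS4class{ReferenceBundle}
#' @export
syntheticBundle <- function(seed = 1L, unit_len = 3300L, homology_len = 42000L,
                            xapi_pos = 1525L, blni_pos = 2210L,
                            pas_pos = 400L) {
  with_seed(seed, {
    unit <- paste0("GGTACC", .random_dna(unit_len - 6L))
    substr(unit, xapi_pos, xapi_pos + 5L) <- "GAATTC"     # XapI (RAATTY)
    substr(unit, blni_pos, blni_pos + 5L) <- "CCTCGG"     # BlnI one SNV away
    unit <- .scrub(unit, "GGTACC", protect = c(1L, 6L))
    unit <- .scrub(unit, "CCTAGG")
    unit <- .scrub(unit, "[AG]AATT[CT]", protect = c(xapi_pos, xapi_pos + 5L))
    ## re-assert planted sites in case scrubbing walked over them
    substr(unit, xapi_pos, xapi_pos + 5L) <- "GAATTC"
    substr(unit, blni_pos, blni_pos + 5L) <- "CCTCGG"

    clean <- function(s) .scrub(.scrub(s, "GGTACC"), "CCTAGG")
    plam <- clean(.random_dna(800L))
    plam <- .scrub(plam, "AT[TC]AAA")
    substr(plam, pas_pos, pas_pos + 5L) <- "ATTAAA"       # 4q-type PAS
    seqs <- c(
      unit = unit,
      `p13E-11` = clean(.random_dna(1400L)),
      pLAM = plam,
      qB = clean(.random_dna(900L)),
      flank4q_up = clean(.random_dna(3000L)),
      flank10q_up = clean(.random_dna(3000L)),
      flank4q_down = clean(.random_dna(2000L)),
      flank10q_down = clean(.random_dna(2000L)),
      D4S2463 = revcomp(substr(unit, unit_len - 1500L + 1L, unit_len)))
    extra <- list(
      upstream_homology = clean(.random_dna(homology_len)),
      subtel_pool = clean(.random_dna(25000L)))
    referenceBundle(seqs,
                    diagnostics = c(xapi_pos = xapi_pos, blni_pos = blni_pos,
                                    pas_pos = pas_pos),
                    extra = extra)
  })
}

## chromosome-typed unit / pLAM sequences derived from the canonical bundle
.unit_for_chrom <- function(bundle, chrom) {
  u <- bundleSeq(bundle, "unit")
  if (chrom == "4q") return(u)
  d <- bundle@diagnostics
  xp <- d[["xapi_pos"]]; bp <- d[["blni_pos"]]
  substr(u, xp + 2L, xp + 2L) <- "C"   # GAATTC -> GACTTC: XapI destroyed
  substr(u, bp + 3L, bp + 3L) <- "A"   # CCTCGG -> CCTAGG: BlnI created
  u
}

.plam_for_chrom <- function(bundle, chrom) {
  p <- bundleSeq(bundle, "pLAM")
  if (chrom == "4q") return(p)
  pp <- bundle@diagnostics[["pas_pos"]]
  substr(p, pp + 2L, pp + 2L) <- "C"   # ATTAAA -> ATCAAA: 10q-type PAS
  p
}

## ---------------------------------------------------------------------------
## AlleleSpec

#' Specification of one simulated allele
#'
#' @slot name allele label.
#' @slot chrom "4q" or "10q".
#' @slot ab "A" or "B".
#' @slot subtype "AS", "AM", "AL" (A alleles) or "none" (B alleles).
#' @slot distal_partial_len distal partial unit length in bp (defaults by
#'   subtype: S ~300, M ~600, L ~1900; 10qA ~300; B alleles 0).
#' @slot structure integer vector of RU counts per array segment; length > 1
#'   describes in-cis duplication/triplication alleles.
#' @slot spacer_len spacer lengths (bp) between consecutive segments.
#' @slot dup_proximal_offset for each duplicated segment, the unit offset at
#'   which its leading proximal partial begins (e.g. 1500 means the partial
#'   covers unit positions 1500..unit end); 0 suppresses the partial.
#' @slot upstream_inverted lengths (bp) of inverted upstream unit(s):
#'   \code{1500} reproduces the single D4S2463 configuration; longer vectors
#'   describe inverted upstream arrays.
#' @slot truncated_unit integer pair (unit index, deletion bp) introducing an
#'   internal deletion into one unit, or empty.
#' @slot translocation TRUE swaps the unit/pLAM motif identity against the
#'   flank identity (the 4q-to-10q translocation configuration).
#' @slot mosaic_fraction sampling weight of this allele in read simulation.
#' @export
setClass("AlleleSpec", representation(
  name = "character", chrom = "character", ab = "character",
  subtype = "character", distal_partial_len = "integer",
  structure = "integer", spacer_len = "integer",
  dup_proximal_offset = "integer", upstream_inverted = "integer",
  truncated_unit = "integer", translocation = "logical",
  mosaic_fraction = "numeric"))

setValidity("AlleleSpec", function(object) {
  if (!object@chrom %in% c("4q", "10q")) return("chrom must be 4q or 10q")
  if (!object@ab %in% c("A", "B")) return("ab must be A or B")
  if (object@ab == "B" && object@subtype != "none")
    return("B alleles take subtype 'none'")
  if (object@ab == "A" && !object@subtype %in% c("AS", "AM", "AL"))
    return("A alleles need subtype AS/AM/AL")
  if (any(object@structure < 0L)) return("RU counts must be >= 0")
  if (length(object@structure) > 1L &&
      length(object@spacer_len) != length(object@structure) - 1L)
    return("need one spacer length per segment junction")
  if (length(object@truncated_unit) %in% c(1L, 3L))
    return("truncated_unit must be empty or (index, deletion_bp)")
  TRUE
})

#' Construct an allele specification
#' @param name,chrom,ab,subtype,distal_partial_len,structure,spacer_len,dup_proximal_offset,upstream_inverted,truncated_unit,translocation,mosaic_fraction
#'   see \linkS4class{AlleleSpec}.
#' @return an \linkS4class{AlleleSpec}
#' @examples
#' alleleSpec("al40", "4q", "A", "AL", structure = 40)
#' alleleSpec("trip", "10q", "A", structure = c(15, 2, 5),
#'            spacer_len = c(20000, 20000))
#' @export
alleleSpec <- function(name, chrom = "4q", ab = "A",
                       subtype = if (ab == "B") "none" else "AS",
                       distal_partial_len = NULL, structure = 10L,
                       spacer_len = rep(20000L, max(0L, length(structure) - 1L)),
                       dup_proximal_offset = rep(1500L, max(0L, length(structure) - 1L)),
                       upstream_inverted = integer(0),
                       truncated_unit = integer(0), translocation = FALSE,
                       mosaic_fraction = NA_real_) {
  if (is.null(distal_partial_len)) {
    distal_partial_len <- if (ab == "B") 0L
      else if (chrom == "10q") 300L
      else switch(subtype, AS = 300L, AM = 600L, AL = 1900L, 0L)
  }
  new("AlleleSpec", name = name, chrom = chrom, ab = ab, subtype = subtype,
      distal_partial_len = as.integer(distal_partial_len),
      structure = as.integer(structure), spacer_len = as.integer(spacer_len),
      dup_proximal_offset = as.integer(dup_proximal_offset),
      upstream_inverted = as.integer(upstream_inverted),
      truncated_unit = as.integer(truncated_unit),
      translocation = as.logical(translocation),
      mosaic_fraction = mosaic_fraction)
}

setMethod("show", "AlleleSpec", function(object) {
  cat(sprintf("AlleleSpec %s: %s%s%s RU %s%s%s\n", object@name, object@chrom,
              object@ab,
              if (object@subtype %in% c("AS", "AM", "AL"))
                substr(object@subtype, 2, 2) else "",
              .structure_label(object@structure),
              if (length(object@upstream_inverted)) " +inv-upstream" else "",
              if (object@translocation) " [translocation]" else ""))
})

## ---------------------------------------------------------------------------
## allele assembly

#' Build the full DNA sequence of a simulated allele
#'
#' Concatenates, proximal to distal: the chromosome-unique upstream flank,
#' optional inverted upstream unit(s)/array, the shared 4q/10q homology
#' region, p13E-11, the array segments (each KpnI-anchored, with spacer
#' sequence drawn from the subtelomeric pool and an optional leading proximal
#' partial before duplicated segments), the distal partial unit, pLAM (A
#' alleles, PAS variant per chromosome) or the qB-distal sequence (B alleles),
#' and the downstream flank. Chromosome-diagnostic XapI/BlnI SNVs are carried
#' by every unit.
#'
#' @param spec an \linkS4class{AlleleSpec}.
#' @param bundle a \linkS4class{ReferenceBundle} (needs the simulator extras;
#'   see [syntheticBundle()]).
#' @return a list of class \code{"SimAllele"}: \code{name}, \code{seq},
#'   \code{spec}, and \code{truth} (feature/unit coordinate tables, array
#'   span, structure).
#' @export
buildAlleleSequence <- function(spec, bundle) {
  validObject(spec)
  ulen <- unitLength(bundle)
  unit_chrom <- if (spec@translocation) setdiff(c("4q", "10q"), spec@chrom)
                else spec@chrom
  unit <- .unit_for_chrom(bundle, unit_chrom)

  pieces <- character(0); labels <- list()
  at <- 0L
  add <- function(seqpiece, label, meta = list()) {
    pieces[[length(pieces) + 1L]] <<- seqpiece
    labels[[length(labels) + 1L]] <<- c(list(label = label,
      start = at + 1L, end = at + nchar(seqpiece)), meta)
    at <<- at + nchar(seqpiece)
  }

  add(bundleSeq(bundle, paste0("flank", sub("q", "", spec@chrom), "q_up")),
      "flank_up")
  if (length(spec@upstream_inverted)) {
    inv <- paste(vapply(spec@upstream_inverted, function(l) {
      if (l >= ulen) unit else substr(unit, ulen - l + 1L, ulen)
    }, character(1)), collapse = "")
    add(revcomp(inv), "inverted_upstream")
  }
  hom <- bundle@extra$upstream_homology
  if (is.null(hom)) hom <- ""
  if (nzchar(hom)) add(hom, "homology")
  add(bundleSeq(bundle, "p13E-11"), "p13E-11")

  uidx <- 0L
  nseg <- length(spec@structure)
  for (s in seq_len(nseg)) {
    if (s > 1L) {
      add(substr(bundle@extra$subtel_pool, 1L, spec@spacer_len[s - 1L]),
          "spacer", list(segment = s))
      off <- spec@dup_proximal_offset[s - 1L]
      if (off > 0L)
        add(substr(unit, off + 1L, ulen), "proximal_partial",
            list(segment = s))
    }
    for (i in seq_len(spec@structure[s])) {
      uidx <- uidx + 1L
      useq <- unit
      if (length(spec@truncated_unit) == 2L && spec@truncated_unit[1L] == uidx) {
        dlen <- spec@truncated_unit[2L]
        mid <- (ulen - dlen) %/% 2L
        useq <- paste0(substr(unit, 1L, mid), substr(unit, mid + dlen + 1L, ulen))
      }
      add(useq, "unit", list(segment = s, index = uidx))
    }
  }
  if (spec@distal_partial_len > 0L)
    add(substr(unit, 1L, spec@distal_partial_len), "distal_partial",
        list(segment = nseg))
  if (spec@ab == "A") add(.plam_for_chrom(bundle, unit_chrom), "pLAM")
  else add(bundleSeq(bundle, "qB"), "qB")
  add(bundleSeq(bundle, paste0("flank", sub("q", "", spec@chrom), "q_down")),
      "flank_down")

  seq <- paste(pieces, collapse = "")
  lab <- do.call(rbind, lapply(labels, function(l)
    data.frame(label = l$label, start = l$start, end = l$end,
               segment = if (is.null(l$segment)) NA_integer_ else l$segment,
               index = if (is.null(l$index)) NA_integer_ else l$index,
               stringsAsFactors = FALSE)))
  arr <- lab[lab$label %in% c("unit", "proximal_partial", "distal_partial"), ,
             drop = FALSE]
  truth <- list(
    features = lab,
    structure = spec@structure,
    array_start = min(arr$start), array_end = max(arr$end),
    distal_partial_len = spec@distal_partial_len,
    chrom = spec@chrom, ab = spec@ab, subtype = spec@subtype,
    unit_chrom = unit_chrom)
  structure(list(name = spec@name, seq = seq, spec = spec, truth = truth),
            class = "SimAllele")
}

#' @export
print.SimAllele <- function(x, ...) {
  cat(sprintf("SimAllele %s: %d bp, %s%s RU %s\n", x$name, nchar(x$seq),
              x$truth$chrom, x$truth$ab, .structure_label(x$truth$structure)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## read simulation

## inject substitution/insertion/deletion errors; returns the mutated read,
## a map from input position to read position (NA where deleted) and counts
.inject_errors <- function(seq, sub = 0, ins = 0, del = 0) {
  n <- nchar(seq)
  v <- strsplit(seq, "")[[1]]
  if (sub + ins + del > 0) {
    u <- runif(n)
    is_del <- u < del
    is_sub <- !is_del & u < del + sub
    if (any(is_sub)) {
      shift <- sample.int(3L, sum(is_sub), replace = TRUE)
      v[is_sub] <- .BASES[((match(v[is_sub], .BASES) - 1L + shift) %% 4L) + 1L]
    }
    is_ins <- runif(n) < ins
    piece <- v
    piece[is_del] <- ""
    if (any(is_ins))
      piece[is_ins] <- paste0(piece[is_ins],
                              sample(.BASES, sum(is_ins), replace = TRUE))
    emitted <- (!is_del) + is_ins
    pos <- cumsum(emitted) - emitted + 1L
    map <- ifelse(is_del, NA_integer_, as.integer(pos))
    list(read = paste(piece, collapse = ""), map = map,
         n_sub = sum(is_sub), n_ins = sum(is_ins), n_del = sum(is_del))
  } else {
    list(read = seq, map = seq_len(n), n_sub = 0L, n_ins = 0L, n_del = 0L)
  }
}

#' Simulate long reads from a set of alleles
#'
#' Reads are sampled by allele mosaic weight, fragmented with a lognormal
#' fragment-length model (so the probability of spanning an array falls
#' steeply with array length, reproducing the strong excess of spanning reads
#' for short alleles seen in targeted sequencing), placed uniformly, strand
#' chosen at random, and per-base errors injected. Fully deterministic given
#' the seed.
#'
#' @param alleles list of \code{SimAllele} from [buildAlleleSequence()].
#' @param n_reads number of reads.
#' @param error_rates named numeric: \code{sub}, \code{ins}, \code{del}
#'   per-base rates (default 1.5\%/0.75\%/0.75\%, a ~3\% aggregate error
#'   profile typical of older pore chemistries).
#' @param length_bias TRUE (default) uses the fragment-length model; FALSE
#'   emits whole-molecule reads covering each allele end to end.
#' @param length_meanlog,length_sdlog lognormal fragment-length parameters
#'   (default median ~40 kb).
#' @param min_len minimum read length (default 1000).
#' @param seed integer seed.
#' @return list with \code{reads} (named character), \code{truth} (data.frame:
#'   read_id, allele, start, end, strand, n_sub, n_ins, n_del) and \code{maps}
#'   (per read, fragment-position to read-position integer map).
#' @export
simulateReads <- function(alleles, n_reads,
                          error_rates = c(sub = 0.015, ins = 0.0075, del = 0.0075),
                          length_bias = TRUE,
                          length_meanlog = log(40000), length_sdlog = 0.55,
                          min_len = 1000L, seed = 1L) {
  stopifnot(length(alleles) >= 1L)
  w <- vapply(alleles, function(a) a$spec@mosaic_fraction, numeric(1))
  if (all(is.na(w))) w <- rep(1, length(alleles))
  w[is.na(w)] <- mean(w, na.rm = TRUE)
  w <- w / sum(w)
  lens <- vapply(alleles, function(a) nchar(a$seq), integer(1))
  with_seed(seed, {
    pick <- sample.int(length(alleles), n_reads, replace = TRUE, prob = w)
    reads <- character(n_reads); maps <- vector("list", n_reads)
    tr <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      a <- alleles[[pick[i]]]; n <- lens[pick[i]]
      if (length_bias) {
        L <- max(min_len, min(n, round(rlnorm(1, length_meanlog, length_sdlog))))
        st <- sample.int(n - L + 1L, 1L)
      } else { L <- n; st <- 1L }
      en <- st + L - 1L
      strand <- sample(c("+", "-"), 1L)
      frag <- substr(a$seq, st, en)
      if (strand == "-") frag <- revcomp(frag)
      er <- .inject_errors(frag, error_rates[["sub"]], error_rates[["ins"]],
                           error_rates[["del"]])
      id <- sprintf("sim_%05d_%s", i, a$name)
      reads[i] <- er$read; names(reads)[i] <- id
      maps[[i]] <- er$map
      tr[[i]] <- data.frame(read_id = id, allele = a$name, start = st,
                            end = en, strand = strand, n_sub = er$n_sub,
                            n_ins = er$n_ins, n_del = er$n_del,
                            stringsAsFactors = FALSE)
    }
    names(maps) <- names(reads)
    list(reads = reads, truth = do.call(rbind, tr), maps = maps)
  })
}

#' Simulate one read guaranteed to span the array
#'
#' Extracts the interval from just upstream of p13E-11 to just downstream of
#' the distal feature (pLAM or qB) and injects errors at the requested rates.
#'
#' @param allele a \code{SimAllele}.
#' @param error_rates as in [simulateReads()] (default error-free).
#' @param margin bp of extra flank on each side (default 300).
#' @param strand "+" or "-".
#' @param seed integer seed.
#' @return same shape as [simulateReads()] with a single read.
#' @export
simulateSpanningRead <- function(allele, error_rates = c(sub = 0, ins = 0, del = 0),
                                 margin = 300L, strand = "+", seed = 1L) {
  f <- allele$truth$features
  st <- max(1L, f$start[f$label == "p13E-11"][1L] - margin)
  dist_end <- max(f$end[f$label %in% c("pLAM", "qB")])
  en <- min(nchar(allele$seq), dist_end + margin)
  frag <- substr(allele$seq, st, en)
  if (strand == "-") frag <- revcomp(frag)
  with_seed(seed, {
    er <- .inject_errors(frag, error_rates[["sub"]], error_rates[["ins"]],
                         error_rates[["del"]])
    id <- paste0("span_", allele$name)
    reads <- stats::setNames(er$read, id)
    list(reads = reads,
         truth = data.frame(read_id = id, allele = allele$name, start = st,
                            end = en, strand = strand, n_sub = er$n_sub,
                            n_ins = er$n_ins, n_del = er$n_del,
                            stringsAsFactors = FALSE),
         maps = stats::setNames(list(er$map), id))
  })
}

#' Write reads to FASTQ (plain or gzip)
#'
#' @param reads named character vector.
#' @param path output path; \code{.gz} suffix gzips.
#' @param qual constant per-base quality character (default "I").
#' @return invisibly, \code{path}
#' @export
writeFastq <- function(reads, path, qual = "I") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  for (id in names(reads)) {
    writeLines(c(paste0("@", id), reads[[id]], "+",
                 strrep(qual, nchar(reads[[id]]))), con)
  }
  invisible(path)
}

#' Read a FASTQ or FASTA file into a named character vector
#' @param path input path (plain or gzip; format by extension/content).
#' @return named character vector of sequences
#' @export
readSeqFile <- function(path) {
  fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  ss <- if (fastq) Biostrings::readDNAStringSet(path, format = "fastq")
        else Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

## ---------------------------------------------------------------------------
## methylation model + simulation

#' Methylation model for the simulator
#'
#' Per-CpG site rates are composed from: a proximal-to-distal logistic
#' gradient in cumulative unit index (stepwise increase over roughly the first
#' ten units, then a plateau), a flat severely hypomethylated regime for
#' contracted arrays, a within-unit oscillation (depression over the DR1
#' window, elevation over the TSS window), a nucleosome-scale cosine
#' modulation with ~180 bp period, distinct flat rates outside the array and
#' over inverted upstream units (hypomethylated), and a global multiplicative
#' factor emulating pathogenic SMCHD1 variants. Site rates are clipped to
#' [0.01, 0.99]; per-read calls are Bernoulli draws from the site rate.
#'
#' @slot base_rate plateau methylation rate of long arrays.
#' @slot prox_rate rate at the proximal-most unit before the gradient rises.
#' @slot gradient_midpoint,gradient_scale logistic parameters in unit index.
#' @slot contracted_rate,contracted_max_ru flat rate applied to arrays whose
#'   total RU count is at most \code{contracted_max_ru}.
#' @slot dr1_depression,tss_elevation additive amplitudes over the DR1/TSS
#'   windows.
#' @slot nucleosome_amp,nucleosome_period cosine modulation (set amp 0 to
#'   disable).
#' @slot flank_rate,inverted_rate flat rates outside the array / over inverted
#'   upstream units.
#' @slot smchd1_factor global multiplier (1 = wild type; < 1 = pathogenic
#'   SMCHD1 variant cohorts).
#' @export
setClass("MethModel", representation(
  base_rate = "numeric", prox_rate = "numeric",
  gradient_midpoint = "numeric", gradient_scale = "numeric",
  contracted_rate = "numeric", contracted_max_ru = "integer",
  dr1_depression = "numeric", tss_elevation = "numeric",
  nucleosome_amp = "numeric", nucleosome_period = "integer",
  flank_rate = "numeric", inverted_rate = "numeric",
  smchd1_factor = "numeric"))

setValidity("MethModel", function(object) {
  rates <- c(object@base_rate, object@prox_rate, object@contracted_rate,
             object@flank_rate, object@inverted_rate)
  if (any(rates < 0 | rates > 1)) return("rates must be in [0, 1]")
  if (object@smchd1_factor <= 0) return("smchd1_factor must be positive")
  if (object@nucleosome_period <= 0) return("nucleosome_period must be positive")
  TRUE
})

#' Construct a methylation model
#' @param ... named overrides of \linkS4class{MethModel} slots.
#' @return a \linkS4class{MethModel}
#' @examples
#' methModel(smchd1_factor = 0.3)
#' @export
methModel <- function(...) {
  d <- list(base_rate = 0.85, prox_rate = 0.30, gradient_midpoint = 5,
            gradient_scale = 1.5, contracted_rate = 0.08,
            contracted_max_ru = 4L, dr1_depression = -0.4,
            tss_elevation = 0.3, nucleosome_amp = 0.10,
            nucleosome_period = 180L, flank_rate = 0.70, inverted_rate = 0.15,
            smchd1_factor = 1)
  ov <- list(...)
  bad <- setdiff(names(ov), names(d))
  if (length(bad)) stop("unknown MethModel parameter(s): ",
                        paste(bad, collapse = ", "))
  d[names(ov)] <- ov
  d$contracted_max_ru <- as.integer(d$contracted_max_ru)
  d$nucleosome_period <- as.integer(d$nucleosome_period)
  do.call(new, c(list("MethModel"), d))
}

#' True per-CpG methylation rates of a simulated allele
#'
#' @param allele a \code{SimAllele}.
#' @param model a \linkS4class{MethModel}.
#' @param coords a \linkS4class{UnitCoords} for the DR1/TSS windows.
#' @return data.frame: \code{site} (1-based position of the CpG C on the
#'   allele sequence) and \code{rate}.
#' @export
computeSiteRates <- function(allele, model = methModel(),
                             coords = unitCoords()) {
  seq <- allele$seq
  sites <- Biostrings::start(
    Biostrings::matchPattern("CG", Biostrings::DNAString(seq)))
  f <- allele$truth$features
  total_ru <- sum(allele$truth$structure)
  contracted <- total_ru <= model@contracted_max_ru

  rate <- rep(model@flank_rate, length(sites))
  ## inverted upstream units: flat hypomethylation
  inv <- f[f$label == "inverted_upstream", , drop = FALSE]
  for (i in seq_len(nrow(inv))) {
    sel <- sites >= inv$start[i] & sites <= inv$end[i]
    rate[sel] <- model@inverted_rate
  }
  ## array units (full and partial): gradient + within-unit components
  arr <- f[f$label %in% c("unit", "proximal_partial", "distal_partial"), ,
           drop = FALSE]
  arr <- arr[order(arr$start), , drop = FALSE]
  ulen_hint <- max(arr$end - arr$start + 1L)
  seqidx <- seq_len(nrow(arr))
  for (i in seqidx) {
    sel <- which(sites >= arr$start[i] & sites <= arr$end[i])
    if (!length(sel)) next
    if (contracted) { rate[sel] <- model@contracted_rate; next }
    u <- i  # sequential instance index, proximal -> distal
    base_u <- model@prox_rate + (model@base_rate - model@prox_rate) /
      (1 + exp(-(u - model@gradient_midpoint) / model@gradient_scale))
    off <- sites[sel] - arr$start[i] + 1L
    ## partials keep their true unit offsets (a proximal partial is the tail
    ## of a unit, a distal partial its head)
    if (arr$label[i] == "proximal_partial")
      off <- off + (ulen_hint - (arr$end[i] - arr$start[i] + 1L))
    r <- rep(base_u, length(off))
    dr1 <- off >= coords@dr1_start & off <= coords@dr1_end
    tss <- abs(off - coords@tss_pos) <= coords@tss_window
    r[dr1] <- r[dr1] + model@dr1_depression
    r[tss] <- r[tss] + model@tss_elevation
    if (model@nucleosome_amp > 0)
      r <- r + model@nucleosome_amp *
        cos(2 * pi * off / model@nucleosome_period)
    rate[sel] <- r
  }
  rate <- pmin(0.99, pmax(0.01, rate * model@smchd1_factor))
  data.frame(site = sites, rate = rate)
}

#' Simulate per-read CpG methylation calls
#'
#' For every simulated read, every allele CpG site covered by the read is
#' assigned a Bernoulli methylation state drawn from the site's true rate;
#' calls are emitted as probabilities near 0.98/0.02 with small jitter so that
#' downstream thresholding is exercised. Positions are 0-based on the read's
#' forward strand (position of the CpG C).
#'
#' @param sim output of [simulateReads()] / [simulateSpanningRead()].
#' @param alleles list of \code{SimAllele} (named as referenced by the sim
#'   truth).
#' @param model a \linkS4class{MethModel}.
#' @param coords a \linkS4class{UnitCoords}.
#' @param seed integer seed.
#' @return list: \code{calls} (data.frame read_id, read_pos, strand,
#'   prob_5mC), \code{site_rates} (per allele, from [computeSiteRates()]).
#' @export
simulateMethylation <- function(sim, alleles, model = methModel(),
                                coords = unitCoords(), seed = 1L) {
  names(alleles) <- vapply(alleles, function(a) a$name, character(1))
  rates <- lapply(alleles, computeSiteRates, model = model, coords = coords)
  with_seed(seed, {
    rows <- vector("list", nrow(sim$truth))
    for (i in seq_len(nrow(sim$truth))) {
      t <- sim$truth[i, ]
      sr <- rates[[t$allele]]
      sel <- sr$site >= t$start & sr$site + 1L <= t$end
      if (!any(sel)) next
      s <- sr$site[sel]; r <- sr$rate[sel]
      frag_pos <- if (t$strand == "+") s - t$start + 1L else t$end - s
      map <- sim$maps[[t$read_id]]
      rp <- map[frag_pos]
      ok <- !is.na(rp)
      if (!any(ok)) next
      state <- rbinom(sum(ok), 1L, r[ok])
      prob <- ifelse(state == 1L, 0.98, 0.02) +
        runif(sum(ok), -0.015, 0.015)
      rows[[i]] <- data.frame(read_id = t$read_id, read_pos = rp[ok] - 1L,
                              strand = "+", prob_5mC = pmin(1, pmax(0, prob)),
                              stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, rows)
    if (is.null(calls))
      calls <- data.frame(read_id = character(0), read_pos = integer(0),
                          strand = character(0), prob_5mC = numeric(0))
    list(calls = calls, site_rates = rates)
  })
}

#' Write / read the methylation call TSV dialect
#'
#' Columns: \code{read_id}, \code{read_pos} (0-based position of the CpG C on
#' the read forward strand), \code{strand}, \code{prob_5mC}.
#' @param calls data.frame of calls.
#' @param path TSV path (plain or gzip).
#' @return invisibly \code{path} / the calls data.frame
#' @export
writeMethTSV <- function(calls, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMethTSV
#' @export
readMethTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "read_pos", "strand", "prob_5mC")
  if (!all(need %in% names(df)))
    stop("methylation TSV must have columns: ", paste(need, collapse = ", "))
  df
}
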