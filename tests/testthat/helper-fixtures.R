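# Shared fixtures and independent oracles. Fixtures are generated in code at
# test time; the bundle builders are memoized so each is built once per run.

.fixture_cache <- new.env(parent = emptyenv())

## full-scale synthetic bundle (42 kb upstream homology)
tb <- function() {
  if (is.null(.fixture_cache$bundle))
    .fixture_cache$bundle <- syntheticBundle(seed = 42L)
  .fixture_cache$bundle
}

## reduced-homology bundle for tests where many whole-allele reads are
## annotated and the upstream homology length is irrelevant to the property
tb_small <- function() {
  if (is.null(.fixture_cache$bundle_small))
    .fixture_cache$bundle_small <- syntheticBundle(seed = 42L,
                                                   homology_len = 2000L)
  .fixture_cache$bundle_small
}

## n spanning reads of one allele, alternating strands
spanning_set <- function(allele, n, error = c(sub = 0, ins = 0, del = 0),
                         seed = 1L, prefix = "r") {
  out <- list(reads = character(0), truth = NULL, maps = list())
  for (i in seq_len(n)) {
    s <- simulateSpanningRead(allele, error_rates = error,
                              strand = if (i %% 2) "+" else "-",
                              seed = seed * 1000L + i)
    id <- paste0(prefix, i)
    names(s$reads) <- id
    s$truth$read_id <- id
    names(s$maps) <- id
    out$reads <- c(out$reads, s$reads)
    out$truth <- rbind(out$truth, s$truth)
    out$maps <- c(out$maps, s$maps)
  }
  out
}

## simulate -> annotate -> anchor one allele methylome against the true
## allele span (surrogate consensus), plus-strand reads
make_methylome <- function(allele, bundle, model, coverage, seed, key,
                           params = pipelineParams()) {
  sim <- list(reads = character(0), truth = NULL, maps = list())
  for (i in seq_len(coverage)) {
    s <- simulateSpanningRead(allele, strand = "+", seed = seed * 1000L + i)
    id <- paste0(key, "_", i)
    names(s$reads) <- id; s$truth$read_id <- id; names(s$maps) <- id
    sim$reads <- c(sim$reads, s$reads)
    sim$truth <- rbind(sim$truth, s$truth)
    sim$maps <- c(sim$maps, s$maps)
  }
  meth <- simulateMethylation(sim, list(allele), model, seed = seed)
  anns <- annotateReads(sim$reads, bundle, params)
  f <- allele$truth$features
  ref <- substr(allele$seq,
                f$start[f$label == "p13E-11"][1] - 300L,
                max(f$end[f$label %in% c("pLAM", "qB")]) + 300L)
  anchorCalls(meth$calls, anns, sim$reads, ref, bundle, params,
              allele_key = key)
}

## ---------------------------------------------------------------------------
## independent oracles

## brute-force IUPAC motif scan: O(n * m) sliding window on both strands
naive_motif_scan <- function(seq, motif) {
  codes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  match_at <- function(s, pat, at) {
    for (j in seq_len(nchar(pat))) {
      if (!substr(s, at + j - 1L, at + j - 1L) %in% codes[[substr(pat, j, j)]])
        return(FALSE)
    }
    TRUE
  }
  scan1 <- function(s, pat) {
    n <- nchar(s) - nchar(pat) + 1L
    if (n < 1L) return(integer(0))
    which(vapply(seq_len(n), function(i) match_at(s, pat, i), logical(1)))
  }
  rc_iupac <- function(s) {
    comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  rc <- rc_iupac(motif)
  fwd <- scan1(seq, motif)
  if (rc == motif) {
    data.frame(pos = fwd, strand = rep("+", length(fwd)))
  } else {
    rev <- scan1(seq, rc)
    data.frame(pos = c(fwd, rev),
               strand = c(rep("+", length(fwd)), rep("-", length(rev))))
  }
}

## naive pooled methylation rate straight from the call table
naive_pooled_rate <- function(calls, threshold = 0.5) {
  mean(calls$prob_5mC >= threshold)
}

## O(n * lag) pairwise-complete autocorrelation oracle
naive_acf <- function(x, max_lag) {
  o <- which(!is.na(x))
  v <- x[o]
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  out <- rep(NA_real_, max_lag + 1L)
  for (l in 0:max_lag) {
    a <- x[seq_len(length(x) - l)]
    b <- x[seq_len(length(x) - l) + l]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) out[l + 1L] <- mean((a[ok] - mu) * (b[ok] - mu)) / s2
  }
  data.frame(lag = 0:max_lag, acf = out)
}

## random DNA helper for oracle inputs
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
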