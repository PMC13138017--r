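# Methylation anchoring, region statistics, smoothing, autocorrelation,
# correlations.

## small fixture: an allele whose "reads" are exact copies of the reference,
## so anchoring is exercised without error modeling
.meth_fixture <- function(n_reads = 6L, probs = NULL, bundle = tb_small()) {
  al <- buildAlleleSequence(alleleSpec("mf", "4q", "A", "AS", structure = 2L),
                            bundle)
  f <- al$truth$features
  ref <- substr(al$seq, f$start[f$label == "p13E-11"][1] - 100L,
                max(f$end[f$label == "pLAM"]) + 100L)
  reads <- stats::setNames(rep(ref, n_reads), paste0("rd", seq_len(n_reads)))
  anns <- annotateReads(reads, bundle)
  list(ref = ref, reads = reads, anns = anns, bundle = bundle)
}

test_that("threshold counting at one site gives the pooled fraction", {
  fx <- .meth_fixture(4L)
  site <- Biostrings::start(Biostrings::matchPattern("CG",
    Biostrings::DNAString(fx$ref)))[100]
  calls <- data.frame(read_id = paste0("rd", 1:4), read_pos = site - 1L,
                      strand = "+", prob_5mC = c(0.9, 0.9, 0.1, 0.7))
  m <- anchorCalls(calls, fx$anns, fx$reads, fx$ref, fx$bundle)
  i <- match(site, m@sites)
  expect_equal(m@n_meth[i], 3L)
  expect_equal(m@n_unmeth[i], 1L)
  expect_equal(fractionModified(m)[i], 0.75)
  ## a probability of exactly 0.5 counts methylated (threshold is >=)
  calls2 <- calls; calls2$prob_5mC <- c(0.5, 0.5, 0.49, 0.51)
  m2 <- anchorCalls(calls2, fx$anns, fx$reads, fx$ref, fx$bundle)
  expect_equal(m2@n_meth[match(site, m2@sites)], 3L)
})

test_that("sites below the coverage filter are excluded from profile statistics", {
  fx <- .meth_fixture(4L)
  sites <- Biostrings::start(Biostrings::matchPattern("CG",
    Biostrings::DNAString(fx$ref)))
  calls <- do.call(rbind, lapply(paste0("rd", 1:4), function(id)
    data.frame(read_id = id, read_pos = sites - 1L, strand = "+",
               prob_5mC = 0.9)))
  m <- anchorCalls(calls, fx$anns, fx$reads, fx$ref, fx$bundle)
  ## coverage 4 everywhere: below the default filter of 5
  expect_true(all(siteCoverage(m)[siteCoverage(m) > 0] == 4L))
  expect_equal(nrow(smoothProfile(m)), 0L)
  expect_error(methylationAcf(m), "at least 2 observed")
  ## region stats still pool all calls
  rs <- regionStats(m, fx$bundle@coords)
  expect_equal(rs$global_rate, 1.0)
})

test_that("region statistics pool counts and treat empty regions as missing", {
  fx <- .meth_fixture(6L)
  sites <- Biostrings::start(Biostrings::matchPattern("CG",
    Biostrings::DNAString(fx$ref)))
  ## uniform fully methylated: every rate is 1.0
  calls <- do.call(rbind, lapply(paste0("rd", 1:6), function(id)
    data.frame(read_id = id, read_pos = sites - 1L, strand = "+",
               prob_5mC = 0.98)))
  m <- anchorCalls(calls, fx$anns, fx$reads, fx$ref, fx$bundle)
  rs <- regionStats(m, fx$bundle@coords)
  expect_equal(rs$global_rate, 1.0)
  expect_equal(rs$final_unit_rate, 1.0)
  expect_true(all(rs$per_unit$dr1_mean == 1.0))
  ## half of all calls methylated -> global rate 0.5
  calls$prob_5mC <- rep(c(0.98, 0.02), length.out = nrow(calls))
  m2 <- anchorCalls(calls, fx$anns, fx$reads, fx$ref, fx$bundle)
  expect_equal(regionStats(m2, fx$bundle@coords)$global_rate, 0.5,
               tolerance = 0.02)
  ## no calls at all: missing value, not zero
  m3 <- anchorCalls(calls[0, ], fx$anns, fx$reads, fx$ref, fx$bundle)
  expect_true(is.na(regionStats(m3, fx$bundle@coords)$global_rate))
})

test_that("pooled global rate equals the naive count over all calls", {
  b <- tb_small()
  al <- buildAlleleSequence(alleleSpec("p", "4q", "A", "AS", structure = 2L), b)
  m <- make_methylome(al, b, methModel(), 8L, seed = 21L, key = "p")
  rs <- regionStats(m, b@coords)
  ## oracle: total methylated states / total states over the array interval
  u <- m@units[m@units$strand == "+", ]
  lo <- min(u$read_start); hi <- max(u$read_end)
  pr <- m@per_read[m@per_read$site >= lo & m@per_read$site <= hi, ]
  expect_equal(rs$global_rate, mean(pr$state))
})

test_that("simulated site rates are recovered within binomial error", {
  b <- tb_small()
  al <- buildAlleleSequence(alleleSpec("r", "4q", "A", "AL", structure = 8L), b)
  m <- make_methylome(al, b, methModel(), 20L, seed = 31L, key = "r")
  truth <- computeSiteRates(al, methModel())
  f <- al$truth$features
  off <- f$start[f$label == "p13E-11"][1] - 300L - 1L
  truth$ref_site <- truth$site - off
  got <- methSiteTable(m)
  j <- match(got$site[got$coverage >= 15], truth$ref_site)
  sel <- !is.na(j)
  frac <- got$fraction[got$coverage >= 15][sel]
  rate <- truth$rate[j[sel]]
  ## ~95% of sites inside a 99% binomial interval around the true rate
  z <- 2.58 * sqrt(rate * (1 - rate) / 20)
  expect_gt(mean(abs(frac - rate) <= pmax(z, 0.05)), 0.9)
})

test_that("smoothing preserves constants, ramps steps, keeps unit-scale oscillation", {
  b <- tb_small()
  fx <- .meth_fixture(6L, bundle = b)
  sites <- Biostrings::start(Biostrings::matchPattern("CG",
    Biostrings::DNAString(fx$ref)))
  mk <- function(probs_by_site) {
    calls <- do.call(rbind, lapply(paste0("rd", 1:6), function(id)
      data.frame(read_id = id, read_pos = sites - 1L, strand = "+",
                 prob_5mC = probs_by_site)))
    anchorCalls(calls, fx$anns, fx$reads, fx$ref, fx$bundle)
  }
  ## constant 0.7 -> constant 0.7 (0.7 of reads methylated per site)
  m_const <- mk(rep(1, length(sites)))
  pc <- m_const@per_read
  ## constant profile built directly: fraction 1 everywhere
  sm <- smoothProfile(m_const, window = 2000L, min_coverage = 5L)
  expect_true(all(abs(sm$smoothed - 1) < 1e-12))
  ## step profile -> monotone ramp across the window (closed-form windowed mean)
  half <- which(sites > stats::median(sites))
  probs <- rep(0.02, length(sites)); probs[half] <- 0.98
  m_step <- mk(probs)
  sm2 <- smoothProfile(m_step, window = 2000L, min_coverage = 5L)
  expect_true(all(diff(sm2$smoothed) > -1e-9))
  expect_lt(sm2$smoothed[1], 0.01)
  expect_gt(sm2$smoothed[nrow(sm2)], 0.99)
  ## sinusoid with unit-scale period survives a 2000 bp window
  osc <- 0.5 + 0.5 * sin(2 * pi * sites / 3300)
  m_osc <- mk(ifelse(osc > 0.5, 0.98, 0.02))
  sm3 <- smoothProfile(m_osc, window = 2000L, min_coverage = 5L)
  expect_gt(max(sm3$smoothed) - min(sm3$smoothed), 0.3)
  ## loess smoother runs on the same input
  sm4 <- smoothProfile(m_osc, method = "loess", min_coverage = 5L)
  expect_equal(nrow(sm4), sum(siteCoverage(m_osc) >= 5))
})

test_that("missing-aware autocorrelation matches the brute-force oracle", {
  ## periodic square wave sampled at CpG-like irregular positions
  set.seed(11)
  n <- 20000L
  x <- rep(NA_real_, n)
  pos <- sort(sample.int(n, 1200L))
  x[pos] <- ifelse((pos %% 3300) < 1650, 0.9, 0.1) + runif(1200, -0.02, 0.02)
  got <- methylationAcf(x, max_lag = 4500L)
  oracle <- naive_acf(x, 4500L)
  expect_equal(got$acf, oracle$acf, tolerance = 1e-12)
  ## argmax near the period
  pk <- acfPeak(got, 2500, 4500)
  expect_lt(abs(pk - 3300), 50)
  ## acf(0) = 1 always
  expect_equal(got$acf[1], 1.0)
})

test_that("white-noise profiles show no spurious autocorrelation structure", {
  set.seed(13)
  n <- 30000L
  x <- rep(NA_real_, n)
  pos <- sort(sample.int(n, 2000L))
  x[pos] <- runif(2000)
  a <- methylationAcf(x, max_lag = 300L)
  vals <- a$acf[a$lag > 0 & !is.na(a$acf)]
  ## pairwise counts per lag ~ 2000^2 * 300 / 30000^2; bound loosely at 3/sqrt(n_pairs)
  expect_gt(mean(abs(vals) <= 0.35), 0.99)
  expect_lt(abs(mean(vals)), 0.05)
  ## degenerate inputs error
  expect_error(methylationAcf(rep(NA_real_, 100)), "at least 2")
  expect_error(methylationAcf(c(0.5, 0.5, 0.5)), "degenerate")
})

test_that("repeat-length correlation handles exact, grouped and degenerate input", {
  ## perfectly linear synthetic set -> Pearson 1.0
  df <- data.frame(ru = c(2, 10, 20, 30, 40))
  df$rate <- 0.05 + 0.02 * df$ru
  r <- lengthMethylationCorrelation(df)
  expect_equal(r$pearson, 1.0, tolerance = 1e-9)
  expect_equal(r$spearman, 1.0)
  ## per-group coefficients
  df2 <- rbind(cbind(df, group = "wt"),
               data.frame(ru = df$ru, rate = df$rate * 0.3, group = "mut"))
  r2 <- lengthMethylationCorrelation(df2)
  expect_equal(nrow(r2), 2L)
  expect_true(all(r2$pearson > 0.99))
  ## degenerate variance -> missing coefficients
  r3 <- lengthMethylationCorrelation(data.frame(ru = c(5, 5, 5),
                                                rate = c(0.1, 0.2, 0.3)))
  expect_true(is.na(r3$pearson))
})

test_that("bedMethyl export is 0-based half-open with percent modified", {
  fx <- .meth_fixture(6L)
  sites <- Biostrings::start(Biostrings::matchPattern("CG",
    Biostrings::DNAString(fx$ref)))
  calls <- do.call(rbind, lapply(paste0("rd", 1:6), function(id)
    data.frame(read_id = id, read_pos = sites - 1L, strand = "+",
               prob_5mC = 0.98)))
  m <- anchorCalls(calls, fx$anns, fx$reads, fx$ref, fx$bundle,
                   allele_key = "4qAS_2")
  bm <- tempfile(fileext = ".bed")
  writeBedMethyl(m, bm)
  tab <- utils::read.delim(bm, header = FALSE)
  expect_equal(tab$V2 + 2L, tab$V3)            # 2 bp CpG interval
  expect_equal(tab$V2[1] + 1L, m@sites[m@sites %in% (tab$V2 + 1L)][1])
  expect_true(all(tab$V11 == 100))             # percent scale
})
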