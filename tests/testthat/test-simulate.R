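# Simulator: allele assembly, read generation, methylation model, ground
# truth, determinism.

test_that("allele specifications validate their invariants", {
  expect_error(alleleSpec("x", "4q", "B", subtype = "AS"), "subtype")
  expect_error(alleleSpec("x", "5q", "A", "AS"), "chrom")
  expect_error(alleleSpec("x", "4q", "A", "AS", structure = c(3L, 2L),
                          spacer_len = integer(0)), "spacer")
  ## subtype defaults for distal partial lengths
  expect_equal(alleleSpec("x", "4q", "A", "AS")@distal_partial_len, 300L)
  expect_equal(alleleSpec("x", "4q", "A", "AM")@distal_partial_len, 600L)
  expect_equal(alleleSpec("x", "4q", "A", "AL")@distal_partial_len, 1900L)
  expect_equal(alleleSpec("x", "10q", "A", "AS")@distal_partial_len, 300L)
  expect_equal(alleleSpec("x", "4q", "B")@distal_partial_len, 0L)
})

test_that("built alleles round-trip through assembly annotation", {
  b <- tb()
  al <- buildAlleleSequence(alleleSpec("a", "4q", "A", "AS", structure = 3L), b)
  ann <- annotateAssembly(c(a = al$seq), b)$a
  expect_equal(ruStructure(ann), 3L)
  expect_equal(callSubtype(distalPartialLength(ann), "A"), "AS")
  ## triplication with 20 kb spacers gives three segments
  trip <- buildAlleleSequence(alleleSpec("t", "10q", "A", "AS",
                                         structure = c(15L, 2L, 5L),
                                         spacer_len = c(20000L, 20000L)), b)
  expect_equal(ruStructure(annotateAssembly(c(t = trip$seq), b)$t),
               c(15L, 2L, 5L))
})

test_that("zero-error reads are exact substrings of their source allele", {
  b <- tb_small()
  al <- buildAlleleSequence(alleleSpec("z", "4q", "A", "AS", structure = 2L), b)
  sim <- simulateReads(list(al), 10L, error_rates = c(sub = 0, ins = 0, del = 0),
                       seed = 3L)
  for (i in seq_len(nrow(sim$truth))) {
    t <- sim$truth[i, ]
    frag <- substr(al$seq, t$start, t$end)
    if (t$strand == "-") frag <- dazzle:::revcomp(frag)
    expect_identical(unname(sim$reads[[t$read_id]]), frag)
  }
  expect_true(all(sim$truth$n_sub + sim$truth$n_ins + sim$truth$n_del == 0))
})

test_that("error injection reports counts and a consistent coordinate map", {
  set.seed(1)
  seq <- random_dna(5000L, seed = 5)
  er <- dazzle:::.inject_errors(seq, sub = 0.015, ins = 0.0075, del = 0.0075)
  expect_equal(nchar(er$read), 5000L - er$n_del + er$n_ins)
  ## mapped positions carry the original base unless substituted or deleted
  kept <- which(!is.na(er$map))
  agree <- mean(substring(er$read, er$map[kept], er$map[kept]) ==
                  substring(seq, kept, kept))
  expect_gt(agree, 0.975)
  expect_lt(agree, 1.0)
})

test_that("fragment-length bias starves long alleles of spanning reads", {
  b <- tb_small()
  short <- buildAlleleSequence(alleleSpec("s", "4q", "A", "AL", structure = 1L,
                                          mosaic_fraction = 0.5), b)
  long <- buildAlleleSequence(alleleSpec("l", "4q", "A", "AL", structure = 40L,
                                         mosaic_fraction = 0.5), b)
  sim <- simulateReads(list(short, long), 400L,
                       error_rates = c(sub = 0, ins = 0, del = 0),
                       length_bias = TRUE, seed = 11L)
  spans <- function(al, tr) {
    f <- al$truth$features
    lo <- f$start[f$label == "p13E-11"][1]
    hi <- max(f$end[f$label %in% c("pLAM", "qB")])
    sum(tr$start <= lo & tr$end >= hi)
  }
  n_short <- spans(short, sim$truth[sim$truth$allele == "s", ])
  n_long <- spans(long, sim$truth[sim$truth$allele == "l", ])
  expect_gt(n_short, 4 * max(1L, n_long))
})

test_that("simulation output is byte-identical under a fixed seed", {
  b <- tb_small()
  al <- buildAlleleSequence(alleleSpec("d", "4q", "A", "AS", structure = 2L), b)
  s1 <- simulateReads(list(al), 15L, seed = 42L)
  s2 <- simulateReads(list(al), 15L, seed = 42L)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writeFastq(s1$reads, f1); writeFastq(s2$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  ## a different seed changes the reads
  s3 <- simulateReads(list(al), 15L, seed = 43L)
  expect_false(identical(s1$reads, s3$reads))
})

test_that("methylation model: gradient rises then plateaus near unit ten", {
  b <- tb_small()
  al <- buildAlleleSequence(alleleSpec("g", "4q", "A", "AL", structure = 30L), b)
  rates <- computeSiteRates(al, methModel())
  f <- al$truth$features
  un <- f[f$label == "unit", ]
  per_unit <- vapply(seq_len(nrow(un)), function(i)
    mean(rates$rate[rates$site >= un$start[i] & rates$site <= un$end[i]]),
    numeric(1))
  ## monotone nondecreasing mean over the first ten units
  expect_true(all(diff(per_unit[1:10]) > -0.01))
  expect_gt(per_unit[10] - per_unit[1], 0.3)
  ## plateau: units 12..30 vary little
  expect_lt(max(per_unit[12:30]) - min(per_unit[12:30]), 0.05)
})

test_that("methylation model: DR1 depressed, TSS elevated, inverted units hypomethylated", {
  b <- tb_small()
  al <- buildAlleleSequence(alleleSpec("w", "4q", "A", "AL", structure = 15L,
                                       upstream_inverted = 1500L), b)
  rates <- computeSiteRates(al, methModel())
  f <- al$truth$features
  co <- unitCoords()
  un <- f[f$label == "unit", ][12, ]  # plateau unit
  off <- rates$site - un$start + 1L
  in_unit <- rates$site >= un$start & rates$site <= un$end
  dr1 <- in_unit & off >= co@dr1_start & off <= co@dr1_end
  tss <- in_unit & abs(off - co@tss_pos) <= co@tss_window
  expect_lt(mean(rates$rate[dr1]), 0.5)
  expect_gt(mean(rates$rate[tss]), 0.9)
  inv <- f[f$label == "inverted_upstream", ]
  sel <- rates$site >= inv$start & rates$site <= inv$end
  expect_lt(mean(rates$rate[sel]), 0.2)
})

test_that("contracted arrays are flat-hypomethylated; SMCHD1 factor depresses cohort-wide", {
  b <- tb_small()
  short <- buildAlleleSequence(alleleSpec("c2", "4q", "A", "AS", structure = 2L), b)
  r_short <- computeSiteRates(short, methModel())
  f <- short$truth$features
  arr <- f[f$label %in% c("unit", "distal_partial"), ]
  sel <- r_short$site >= min(arr$start) & r_short$site <= max(arr$end)
  expect_true(all(abs(r_short$rate[sel] - 0.08) < 1e-9))
  ## smchd1_factor 0.3 multiplies every array rate down
  long <- buildAlleleSequence(alleleSpec("c20", "4q", "A", "AL", structure = 20L), b)
  wt <- computeSiteRates(long, methModel())
  mut <- computeSiteRates(long, methModel(smchd1_factor = 0.3))
  expect_true(all(mut$rate <= wt$rate + 1e-12))
  expect_lt(mean(mut$rate) / mean(wt$rate), 0.45)
})

test_that("simulated calls recover a contracted allele's rate and exercise thresholding", {
  b <- tb_small()
  al <- buildAlleleSequence(alleleSpec("c", "4q", "A", "AS", structure = 2L), b)
  ## plus-strand zero-error reads so read positions map to allele positions
  set <- list(reads = character(0), truth = NULL, maps = list())
  for (i in 1:10) {
    s <- simulateSpanningRead(al, strand = "+", seed = 800L + i)
    id <- paste0("c", i)
    names(s$reads) <- id; s$truth$read_id <- id; names(s$maps) <- id
    set$reads <- c(set$reads, s$reads)
    set$truth <- rbind(set$truth, s$truth)
    set$maps <- c(set$maps, s$maps)
  }
  meth <- simulateMethylation(set, list(al), methModel(), seed = 8L)
  ## probabilities are near-binary with jitter, never outside [0, 1]
  expect_true(all(meth$calls$prob_5mC >= 0 & meth$calls$prob_5mC <= 1))
  expect_true(all(meth$calls$prob_5mC < 0.25 | meth$calls$prob_5mC > 0.75))
  ## per-site truth rates emitted for every allele
  expect_true("c" %in% names(meth$site_rates))
  ## pooled call rate over array sites close to the contracted truth of 0.08
  f <- al$truth$features
  arr <- f[f$label %in% c("unit", "distal_partial"), ]
  start_of <- stats::setNames(set$truth$start, set$truth$read_id)
  apos <- meth$calls$read_pos + start_of[meth$calls$read_id]
  in_arr <- apos >= min(arr$start) & apos <= max(arr$end)
  rate <- naive_pooled_rate(meth$calls[in_arr, ])
  n_arr <- sum(in_arr)
  expect_lt(abs(rate - 0.08), 3 * sqrt(0.08 * 0.92 / n_arr) + 0.005)
})
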