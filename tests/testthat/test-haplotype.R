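# Chromosome / A-B / subtype calls, allele grouping, mosaic fractions,
# reporting.

test_that("concordant evidence yields clean chromosome and A/B calls", {
  b <- tb()
  ## 4qA: pLAM + per-unit XapI + 4q downstream flank
  al4 <- buildAlleleSequence(alleleSpec("a", "4q", "A", "AS", structure = 3L), b)
  hc4 <- callHaplotype(annotateRead(simulateSpanningRead(al4)$reads[[1]], b), b)
  expect_equal(hc4@chrom, "4q")
  expect_equal(hc4@ab, "A")
  expect_false(hc4@conflict)
  expect_equal(hc4@evidence$xapi_blni, "4q")
  ## 10qB-like: qB distal + BlnI units + 10q flanks, all concordant
  al10 <- buildAlleleSequence(alleleSpec("b", "10q", "B", structure = 5L), b)
  hc10 <- callHaplotype(annotateRead(al10$seq, b), b)
  expect_equal(hc10@chrom, "10q")
  expect_equal(hc10@ab, "B")
  expect_false(hc10@conflict)
  expect_equal(haplotypeLabel(hc10), "10qB")
})

test_that("translocation configuration: flank evidence wins, conflict flagged", {
  b <- tb()
  ## 10q flanks and qB distal over XapI-carrying (4q-type) units; the read
  ## extends beyond the upstream homology so the flank decides
  al <- buildAlleleSequence(alleleSpec("tr", "10q", "B", structure = 8L,
                                       translocation = TRUE), b)
  hc <- callHaplotype(annotateRead(al$seq, b), b)
  expect_equal(hc@chrom, "10q")
  expect_equal(hc@ab, "B")
  expect_true(hc@conflict)
  expect_equal(hc@evidence$xapi_blni, "4q")
  expect_equal(hc@evidence$flank_up, "10q")
})

test_that("haplotype calls are invariant to read orientation", {
  b <- tb()
  al <- buildAlleleSequence(alleleSpec("o", "4q", "A", "AL", structure = 4L), b)
  fw <- simulateSpanningRead(al, strand = "+")$reads[[1]]
  rv <- simulateSpanningRead(al, strand = "-")$reads[[1]]
  hf <- callHaplotype(annotateRead(fw, b), b)
  hr <- callHaplotype(annotateRead(rv, b), b)
  expect_equal(haplotypeLabel(hf), haplotypeLabel(hr))
  expect_equal(haplotypeLabel(hf), "4qAL")
})

test_that("distal subtype bins reproduce the S/M/L distal-unit lengths", {
  ## ~0.3 kb -> S, ~0.6 kb -> M, ~1.9 kb -> L
  expect_equal(callSubtype(300L, "A"), "AS")
  expect_equal(callSubtype(600L, "A"), "AM")
  expect_equal(callSubtype(1900L, "A"), "AL")
  expect_equal(callSubtype(1200L, "A"), "unknown")  # between bins
  expect_equal(callSubtype(600L, "B"), "none")
  expect_equal(callSubtype(0L, "A"), "unknown")
})

test_that("spanning reads bucket into one group per simulated allele", {
  b <- tb()
  ## the three 4q alleles of a mosaic carrier: 1, 15 and 40 RU, all 4qAL
  specs <- list(alleleSpec("ru1", "4q", "A", "AL", structure = 1L),
                alleleSpec("ru15", "4q", "A", "AL", structure = 15L),
                alleleSpec("ru40", "4q", "A", "AL", structure = 40L))
  reads <- character(0)
  for (s in specs) {
    al <- buildAlleleSequence(s, b)
    set <- spanning_set(al, 2L, seed = sum(s@structure), prefix = s@name)
    reads <- c(reads, set$reads)
  }
  anns <- annotateReads(reads, b)
  groups <- groupAlleles(anns, b)
  expect_length(groups, 3L)
  expect_equal(sort(vapply(groups, ruTotal, numeric(1))), c(1, 15, 40))
  expect_true(all(vapply(groups, function(g) g@subtype == "AL", logical(1))))
  ## groups sorted by RU within chromosome
  expect_equal(vapply(groups, ruTotal, numeric(1)), c(1, 15, 40))
  ## report table renders one row per group
  tab <- reportTable(groups)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$haplotype, rep("4qAL", 3))
})

test_that("mosaic fraction estimates the simulated read share with a Wilson interval", {
  b <- tb_small()
  a2 <- buildAlleleSequence(alleleSpec("m2", "4q", "A", "AS", structure = 2L,
                                       mosaic_fraction = 0.25), b)
  a3 <- buildAlleleSequence(alleleSpec("m3", "4q", "A", "AS", structure = 3L,
                                       mosaic_fraction = 0.75), b)
  sim <- simulateReads(list(a2, a3), 60L,
                       error_rates = c(sub = 0, ins = 0, del = 0),
                       length_bias = FALSE, seed = 9L)
  anns <- annotateReads(sim$reads, b)
  groups <- groupAlleles(anns, b)
  expect_length(groups, 2L)
  g2 <- groups[[which(vapply(groups, ruTotal, numeric(1)) == 2)]]
  expect_true(g2@mosaic_ci[1] <= 0.25 && 0.25 <= g2@mosaic_ci[2])
  frac_truth <- mean(sim$truth$allele == "m2")
  expect_equal(g2@mosaic_fraction, frac_truth, tolerance = 1e-9)
})

test_that("mosaic fraction is consistent over seeded replicates", {
  ## scaled-down replicate study: mean of the estimator over whole-molecule
  ## simulations stays within 3 percentage points of the simulated fraction
  b <- tb_small()
  a2 <- buildAlleleSequence(alleleSpec("m2", "4q", "A", "AS", structure = 1L,
                                       mosaic_fraction = 0.25), b)
  a3 <- buildAlleleSequence(alleleSpec("m3", "4q", "A", "AS", structure = 3L,
                                       mosaic_fraction = 0.75), b)
  est <- vapply(1:25, function(rep) {
    sim <- simulateReads(list(a2, a3), 24L,
                         error_rates = c(sub = 0, ins = 0, del = 0),
                         length_bias = FALSE, seed = 100L + rep)
    anns <- annotateReads(sim$reads, b)
    groups <- groupAlleles(anns, b)
    rus <- vapply(groups, ruTotal, numeric(1))
    if (!1 %in% rus) return(0)
    groups[[which(rus == 1)]]@mosaic_fraction
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.25), 0.03)
})

test_that("nonspanning reads attach only to a uniquely compatible group", {
  b <- tb_small()
  a5 <- buildAlleleSequence(alleleSpec("g5", "4q", "A", "AS", structure = 5L), b)
  a9 <- buildAlleleSequence(alleleSpec("g9", "10q", "A", "AS", structure = 9L), b)
  reads <- c(spanning_set(a5, 2L, seed = 5, prefix = "s5")$reads,
             spanning_set(a9, 2L, seed = 9, prefix = "s9")$reads)
  ## a distal-anchored nonspanning 10q read (no p13E-11): unique chrom match
  f <- a9$truth$features
  tail9 <- substr(a9$seq, f$start[f$label == "unit" & f$index == 6][1],
                  nchar(a9$seq))
  reads <- c(reads, ns1 = tail9)
  anns <- annotateReads(reads, b)
  groups <- groupAlleles(anns, b)
  expect_length(groups, 2L)
  g10 <- groups[[which(vapply(groups, function(g) g@chrom, character(1)) == "10q")]]
  expect_true("ns1" %in% g10@nonspanning_ids)
})

test_that("grouping without spanning reads warns and returns empty", {
  b <- tb_small()
  al <- buildAlleleSequence(alleleSpec("n", "4q", "A", "AS", structure = 3L), b)
  ## interior fragment: units only, no flanking features
  f <- al$truth$features
  frag <- substr(al$seq, f$start[f$label == "unit" & f$index == 1][1],
                 f$end[f$label == "unit" & f$index == 3][1])
  anns <- annotateReads(c(x = frag), b)
  expect_warning(groups <- groupAlleles(anns, b), "no spanning reads")
  expect_length(groups, 0L)
})

test_that("report table renders duplication structures and empty input", {
  b <- tb()
  al <- buildAlleleSequence(alleleSpec("t", "10q", "A", "AS",
                                       structure = c(15L, 2L, 5L),
                                       spacer_len = c(20000L, 20000L)), b)
  anns <- annotateReads(spanning_set(al, 1L, seed = 3)$reads, b)
  tab <- reportTable(groupAlleles(anns, b))
  expect_equal(tab$ru, "15 + 2 + 5")
  expect_equal(tab$ru_total, 22L)
  ## empty grouping gives a header-only table
  empty <- reportTable(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("chrom", "haplotype", "ru", "n_spanning") %in%
                    names(empty)))
})
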