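# Allele consensus building, unit extraction, unit variant matrices.

test_that("consensus from ten 3%-error spanning reads recovers the allele at >= 99.9% identity", {
  b <- tb()
  p <- pipelineParams()
  al <- buildAlleleSequence(alleleSpec("c5", "4q", "A", "AS", structure = 5L), b)
  set <- spanning_set(al, 10L,
                      error = c(sub = 0.015, ins = 0.0075, del = 0.0075),
                      seed = 100L)
  anns <- annotateReads(set$reads, b, p)
  groups <- groupAlleles(anns, b, p)
  expect_length(groups, 1L)
  cons <- buildConsensus(groups[[1]], set$reads, b, p)
  f <- al$truth$features
  truth_span <- substr(al$seq, f$start[f$label == "p13E-11"][1] - 300L,
                       max(f$end[f$label == "pLAM"]) + 300L)
  d <- as.numeric(utils::adist(consensusSeq(cons), truth_span))
  expect_lte(d / nchar(truth_span), 0.001)
  ## error-correction monotonicity: consensus closer to truth than the
  ## median member read
  read_d <- vapply(set$reads, function(r)
    min(as.numeric(utils::adist(r, truth_span)),
        as.numeric(utils::adist(dazzle:::revcomp(r), truth_span))),
    numeric(1))
  expect_lt(d, stats::median(read_d))
  ## structure preservation invariant, checked through assembly annotation
  ann_c <- annotateAssembly(c(cons = consensusSeq(cons)), b, p)$cons
  expect_equal(ruStructure(ann_c), 5L)
  expect_equal(callSubtype(distalPartialLength(ann_c), "A", p), "AS")
})

test_that("a single-read group passes through unpolished and flagged", {
  b <- tb()
  al <- buildAlleleSequence(alleleSpec("s1", "4q", "A", "AL", structure = 2L), b)
  set <- spanning_set(al, 1L, seed = 4L)
  anns <- annotateReads(set$reads, b)
  groups <- groupAlleles(anns, b)
  cons <- buildConsensus(groups[[1]], set$reads, b)
  expect_equal(cons@rounds, 0L)
  expect_true("unpolished" %in% cons@flags)
  expect_identical(consensusSeq(cons), unname(set$reads[[1]]))
})

test_that("a mixed-allele group aborts instead of emitting a chimera", {
  b <- tb()
  a3 <- buildAlleleSequence(alleleSpec("x3", "4q", "A", "AS", structure = 3L), b)
  a6 <- buildAlleleSequence(alleleSpec("x6", "4q", "A", "AS", structure = 6L), b)
  reads <- c(spanning_set(a3, 2L, seed = 1, prefix = "a")$reads,
             spanning_set(a6, 3L, seed = 2, prefix = "b")$reads)
  anns <- annotateReads(reads, b)
  groups <- groupAlleles(anns, b)
  ## adversarial fixture: force both alleles' reads into one group
  bad <- groups[[1]]
  bad@spanning_ids <- names(reads)
  expect_error(buildConsensus(bad, reads, b), "structure")
})

test_that("unit extraction returns KpnI-anchored units proximal to distal", {
  b <- tb()
  p <- pipelineParams()
  u <- bundleSeq(b, "unit")
  ## perfect 3RU allele: 3 full units plus the distal partial
  al <- buildAlleleSequence(alleleSpec("u3", "4q", "A", "AM", structure = 3L), b)
  f <- al$truth$features
  span <- substr(al$seq, f$start[f$label == "p13E-11"][1] - 200L,
                 max(f$end[f$label == "pLAM"]) + 200L)
  units <- extractUnits(span, b, p)
  expect_equal(sum(units$completeness == "full"), 3L)
  expect_identical(units$seq[units$completeness == "full"], rep(u, 3))
  ## AM allele: distal partial ~0.6 kb
  dp <- units[units$completeness == "partial_distal", ]
  expect_equal(nrow(dp), 1L)
  expect_lt(abs(dp$length - 600L), 50L)
  ## a truncated internal unit is extracted with its deletion intact
  al2 <- buildAlleleSequence(alleleSpec("u5", "4q", "A", "AS", structure = 5L,
                                        truncated_unit = c(3L, 1200L)), b)
  units2 <- extractUnits(al2$seq, b, p)
  tu <- units2[units2$completeness == "truncated_internal", ]
  expect_equal(nrow(tu), 1L)
  expect_lt(abs(tu$length - 2100L), 60L)
})

test_that("unit variant calling records diagnostic SNVs and reconstructs units exactly", {
  b <- tb()
  p <- pipelineParams()
  u4 <- bundleSeq(b, "unit")
  u10 <- dazzle:::.unit_for_chrom(b, "10q")
  ## BlnI-creating SNV shows up in the matrix and in the genotype column
  uvm <- callUnitVariants(c(u4, u10, u10), b, p)
  expect_equal(unname(uvm$genotypes[, "BlnI"]), c(FALSE, TRUE, TRUE))
  expect_equal(unname(uvm$genotypes[, "XapI"]), c(TRUE, FALSE, FALSE))
  ## canonical unit gives an all-ref row
  expect_true(all(uvm$matrix[1, ] %in% c("ref", "missing")))
  expect_equal(nrow(uvm$events[[1]]), 0L)
  ## a proximal unit with its own variant set gets a distinct row pattern
  u_prox <- u4
  substr(u_prox, 800, 800) <- setdiff(c("A", "C", "G", "T"),
                                      substr(u4, 800, 800))[1]
  uvm2 <- callUnitVariants(c(u_prox, u4, u4), b, p)
  expect_false(identical(uvm2$matrix[1, ], uvm2$matrix[2, ]))
  ## involution: applying recorded events reconstructs every unit byte-exactly
  mixed <- c(u4, u10, u_prox, substr(u4, 1, 600),
             paste0(substr(u4, 1, 1000), substr(u4, 2201, 3300)))
  uvm3 <- callUnitVariants(mixed, b, p)
  for (i in seq_along(mixed)) {
    rec <- applyUnitVariants(u4, uvm3$events[[i]], uvm3$coverage[[i]])
    expect_identical(rec, mixed[i], label = paste("unit", i))
  }
})

test_that("the display filter hides only small private indels, at render time", {
  b <- tb()
  u <- bundleSeq(b, "unit")
  ## one unit with a private 2 nt insertion, one with a shared 6 nt deletion
  u_ins <- paste0(substr(u, 1, 500), "AC", substr(u, 501, 3300))
  u_del <- paste0(substr(u, 1, 900), substr(u, 907, 3300))
  uvm <- callUnitVariants(c(u_ins, u_del, u_del), b)
  rendered <- renderVariantMatrix(uvm)
  ## the private small insertion disappears from the rendering only
  ins_key <- uvm$site_info$key[uvm$site_info$type == "ins"]
  del_key <- uvm$site_info$key[uvm$site_info$type == "del"]
  expect_false(ins_key %in% colnames(rendered))
  expect_true(del_key %in% colnames(rendered))
  expect_true(ins_key %in% colnames(uvm$matrix))  # storage untouched
})

test_that("allele comparison separates identical, related and distinct matrices", {
  b <- tb()
  u4 <- bundleSeq(b, "unit")
  u10 <- dazzle:::.unit_for_chrom(b, "10q")
  m4 <- callUnitVariants(rep(u4, 4), b)
  ## a matrix equals itself
  expect_equal(compareAlleles(m4, m4)$verdict, "identical")
  ## one SNV in one unit: related, one mismatch reported
  u_var <- u4
  substr(u_var, 1200, 1200) <- setdiff(c("A", "C", "G", "T"),
                                       substr(u4, 1200, 1200))[1]
  m_rel <- callUnitVariants(c(u4, u4, u_var, u4), b)
  cmp <- compareAlleles(m4, m_rel)
  expect_equal(cmp$verdict, "related")
  expect_equal(cmp$n_mismatch, 1L)
  ## 4q vs 10q: chromosome-diagnostic columns disagree -> distinct
  m10 <- callUnitVariants(rep(u10, 4), b)
  cmp2 <- compareAlleles(m4, m10)
  expect_equal(cmp2$verdict, "distinct")
  expect_true(cmp2$diagnostic_conflict)
  ## different canonical references are an error
  b2 <- syntheticBundle(seed = 7L)
  m_other <- callUnitVariants(rep(bundleSeq(b2, "unit"), 2), b2)
  expect_error(compareAlleles(m4, m_other), "different canonical")
})

test_that("variant matrices export to TSV and minimal VCF", {
  b <- tb()
  u10 <- dazzle:::.unit_for_chrom(b, "10q")
  uvm <- callUnitVariants(c(u10, u10), b)
  tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  writeVariantMatrix(uvm, b, "10qA_2", tsv = tsv, vcf = vcf)
  tab <- utils::read.delim(tsv)
  expect_equal(nrow(tab), 2L)
  lines <- readLines(vcf)
  expect_true(any(grepl("^##fileformat=VCF", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 4L)  # 2 diagnostic SNVs x 2 units
})
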