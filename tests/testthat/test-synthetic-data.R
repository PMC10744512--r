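test_that("diplotype sampling follows the prevalence weights", {
  cat <- testCatalog()
  expect_identical(
    renderDiplotype(sampleDiplotype("CYP2D6",
      data.frame(diplotype = "*4/*4", count = 1))), "*4/*4")
  expect_error(sampleDiplotype("CYP2D6",
    data.frame(diplotype = character(), count = numeric())), "empty")

  # deletion spread: empirical frequency of *1/*5 within 3 sigma of 25/55
  sp <- readFixture("cyp2d6_spread.tsv")
  del <- sp[sp$category == "deletion", ]
  withr::with_seed(1, {
    draws <- sampleDiplotype("CYP2D6", del, n = 10000)
  })
  p <- 25 / 55
  f <- mean(vapply(draws, renderDiplotype, "") == "*1/*5")
  expect_lt(abs(f - p), 3 * sqrt(p * (1 - p) / 10000))

  n5 <- readFixture("nat2_spread.tsv")
  nonamb <- n5[n5$type == "non-ambiguous", ]
  withr::with_seed(2, {
    draws <- sampleDiplotype("NAT2", nonamb, n = 10000)
  })
  p <- 70 / 282
  f <- mean(vapply(draws, renderDiplotype, "") ==
    "*5,*11,*12/*5,*11,*12")
  expect_lt(abs(f - p), 3 * sqrt(p * (1 - p) / 10000))
})

test_that("haplotype materialization applies star definitions faithfully", {
  cat <- testCatalog()
  gm <- geneModel(cat, "NAT2")
  m <- materializeHaplotypes(parseDiplotype("NAT2", "*4/*4"), cat)
  expect_identical(m$haps$A$seq, gm$reference_sequence)
  expect_identical(m$haps$B$seq, gm$reference_sequence)
  expect_identical(nrow(m$truth), 0L)

  m <- materializeHaplotypes(parseDiplotype("NAT2", "*4/*5,*11,*12"), cat)
  expect_identical(m$truth$coord, c(341L, 481L, 803L))
  expect_identical(m$truth$A, c(0L, 0L, 0L))
  expect_identical(m$truth$B, c(1L, 1L, 1L))
  v <- cat@variants
  for (cd in m$truth$coord) {
    pos <- cd + gm$cds_offset
    expect_identical(substr(m$haps$B$seq, pos, pos),
      v$alt[v$gene == "NAT2" & v$coord == cd])
    expect_identical(substr(m$haps$A$seq, pos, pos),
      v$ref[v$gene == "NAT2" & v$coord == cd])
  }
})

test_that("the seven-TA-repeat allele materializes seven units", {
  cat <- testCatalog()
  gm <- geneModel(cat, "UGT1A1")
  rl <- gm$repeat_locus
  m <- materializeHaplotypes(parseDiplotype("UGT1A1", "*1/*28"), cat)
  expect_identical(m$haps$B$ta_units, 7L)
  expect_identical(m$haps$A$ta_units, 6L)
  pat <- paste0(rl$anchor_left, strrep("TA", 7), rl$anchor_right)
  expect_true(grepl(pat, m$haps$B$seq, fixed = TRUE))
  expect_false(grepl(pat, m$haps$A$seq, fixed = TRUE))
})

test_that("structural haplotypes carry copy, hybrid and deletion structure", {
  cat <- testCatalog()
  m <- materializeHaplotypes(parseDiplotype("CYP2D6", "*1 x 2/*4,*68"), cat)
  expect_identical(m$cn$gene_copies, 3L)
  expect_identical(m$cn$hybrid_copies, 1L)
  expect_false(m$cn$deletion)
  hyb <- m$haps$B$junctions
  expect_identical(hyb$type, "hybrid")
  m2 <- materializeHaplotypes(parseDiplotype("CYP2D6", "*2 x 2/*5"), cat)
  expect_identical(m2$cn$gene_copies, 2L)
  expect_true(m2$cn$deletion)
})

test_that("error-free reads are exact substrings of their haplotype", {
  cat <- testCatalog()
  m <- materializeHaplotypes(parseDiplotype("NAT2", "*4/*5,*11,*12"), cat)
  rs <- simulateReads(m, lrsRegime(errorRate = 0), seed = 42)
  ok <- mapply(function(s, h, a, b) s == substr(m$haps[[h]]$seq, a, b),
    rs@reads$seq, rs@reads$hap, rs@reads$start, rs@reads$end)
  expect_true(all(ok))
  expect_true(all(rs@reads$end <= nchar(m$haps$A$seq)))
})

test_that("the realized error rate matches the nominal 1 percent", {
  cat <- testCatalog()
  m <- materializeHaplotypes(parseDiplotype("NAT2", "*4/*4"), cat)
  rs <- simulateReads(m, lrsRegime(errorRate = 0.01), seed = 7)
  tot <- sum(nchar(rs@reads$seq))
  expect_gte(tot, 1e5)
  rate <- sum(rs@reads$n_errors) / tot
  expect_gte(rate, 0.008)
  expect_lte(rate, 0.012)
})

test_that("realized mean depth is within 10 percent of nominal", {
  cat <- testCatalog()
  m <- materializeHaplotypes(parseDiplotype("NAT2", "*4/*4"), cat)
  for (rg in list(lrsRegime(), srsRegime())) {
    rs <- simulateReads(m, rg, seed = 3)
    L <- nchar(m$haps$A$seq)
    depth <- sum(rs@reads$end - rs@reads$start + 1) / L
    expect_lt(abs(depth - rg@depth) / rg@depth, 0.10)
  }
})

test_that("simulation is deterministic given the seed", {
  cat <- testCatalog()
  m <- materializeHaplotypes(parseDiplotype("UGT1A1", "*1/*28"), cat)
  r1 <- simulateReads(m, lrsRegime(), seed = 99)
  r2 <- simulateReads(m, lrsRegime(), seed = 99)
  expect_identical(r1@reads, r2@reads)
  r3 <- simulateReads(m, lrsRegime(), seed = 100)
  expect_false(identical(r1@reads, r3@reads))
})

test_that("long reads jointly span the distant NAT2 sites", {
  cat <- testCatalog()
  gm <- geneModel(cat, "NAT2")
  m <- materializeHaplotypes(parseDiplotype("NAT2", "*4/*5,*11,*12"), cat)
  rs <- simulateReads(m, lrsRegime(depth = 30), seed = 11)
  p1 <- 341 + gm$cds_offset; p2 <- 803 + gm$cds_offset
  covers <- function(p) rs@reads$start <= p & rs@reads$end >= p
  joint <- sum(covers(p1) & covers(p2)) / sum(covers(p1) | covers(p2))
  expect_gt(joint, 0.5)
})

test_that("paired fragments have two mates with the configured span", {
  cat <- testCatalog()
  m <- materializeHaplotypes(parseDiplotype("NAT2", "*4/*4"), cat)
  rg <- srsRegime()
  rs <- simulateReads(m, rg, seed = 5)
  frag <- split(rs@reads, rs@reads$fragment)
  full <- Filter(function(f) nrow(f) == 2L, frag)
  expect_gt(length(full), 0)
  spans <- vapply(full, function(f) max(f$end) - min(f$start) + 1L, 1L)
  expect_true(all(spans <= rg@fragmentLength))
  expect_true(mean(spans == rg@fragmentLength) > 0.9)
})

test_that("depth profiles reproduce the expected copy-number ratios", {
  cat <- testCatalog()
  rg <- defaultRegime("CYP2D6", "LRS")
  p <- simulateDepthProfile(c(2, 2, 0), rg, cat, cv = 0)
  expect_identical(p$ratio, 1)
  expect_identical(p$junction_reads, 0)
  expect_identical(simulateDepthProfile(c(1, 2, 0), rg, cat, cv = 0)$ratio,
    0.5)
  p3 <- simulateDepthProfile(c(3, 2, 1), rg, cat, cv = 0, seed = 1)
  expect_identical(p3$ratio, 1.5)
  expect_gt(p3$junction_reads, 0)
  expect_error(simulateDepthProfile(c(2, 0, 0), rg, cat), "paralog")
})

test_that("a read length exceeding the haplotype is rejected", {
  cat <- testCatalog()
  m <- materializeHaplotypes(parseDiplotype("UGT1A1", "*1/*1"), cat)
  expect_error(simulateReads(m, lrsRegime(readLength = 7000L)),
    "exceeds haplotype length")
})
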