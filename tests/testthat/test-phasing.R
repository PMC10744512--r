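test_that("observation extraction projects reads onto het sites", {
  cat <- testCatalog()
  m <- materializeHaplotypes(parseDiplotype("NAT2", "*4/*5,*11,*12"), cat)
  rs <- simulateReads(m, lrsRegime(errorRate = 0), seed = 21)
  sites <- c(341L, 481L, 803L)
  ob <- extractObservations(rs, sites, cat)
  expect_identical(colnames(ob$obs), as.character(sites))
  # hap B rows are all-alt wherever observed, hap A rows all-ref
  hapOf <- rs@reads$hap[match(rownames(ob$obs), rs@reads$fragment)]
  for (i in seq_len(nrow(ob$obs))) {
    vals <- ob$obs[i, !is.na(ob$obs[i, ])]
    expect_true(all(vals == if (hapOf[i] == "B") 1L else 0L))
  }
  expect_error(extractObservations(rs, c(803L, 341L), cat), "sorted")
})

test_that("short fragments can observe close sites but never distant ones", {
  cat <- testCatalog()
  m <- materializeHaplotypes(parseDiplotype("NAT2",
    "*5,*11,*12/*5,*11,*12"), cat)
  rs <- simulateReads(m, srsRegime(errorRate = 0), seed = 8)
  ob <- extractObservations(rs, c(341L, 481L, 803L), cat)
  both_close <- sum(!is.na(ob$obs[, "341"]) & !is.na(ob$obs[, "481"]))
  both_far <- sum(!is.na(ob$obs[, "341"]) & !is.na(ob$obs[, "803"]))
  expect_gt(both_close, 0)   # 140 bp apart: within one 350 bp fragment
  expect_identical(both_far, 0L)  # 462 bp apart: beyond any fragment
})

test_that("error-free full-span reads recover the truth with MEC zero", {
  cat <- testCatalog()
  m <- materializeHaplotypes(parseDiplotype("NAT2", "*12/*5,*11"), cat)
  rs <- simulateReads(m, lrsRegime(readLength = 9000L, errorRate = 0),
    seed = 2)
  ob <- extractObservations(rs, m$truth$coord, cat)
  ph <- phaseDirect(ob, sites = m$truth$coord)
  expect_identical(length(ph@blocks), 1L)
  expect_identical(mecScore(ph), 0L)
  err <- phaseErrors(ph, m$truth)
  expect_identical(err$switch_errors, 0L)
  expect_identical(err$hamming, 0L)
})

test_that("exact and greedy MEC solvers match the brute-force oracle", {
  withr::with_seed(123, {
    for (rep in 1:200) {
      obs <- randomMecInstance(6L, 20L)
      exact <- phaseDirect(obs, sites = 1:6)
      # oracle over each connected block, summed
      blocks <- phaseBlocks(exact)
      oracle <- sum(vapply(blocks, function(b) {
        sub <- obs[, b, drop = FALSE]
        sub <- sub[rowSums(!is.na(sub)) > 0, , drop = FALSE]
        if (length(b) == 1L || nrow(sub) == 0L) 0L else
          as.integer(oracleMec(sub))
      }, 1L))
      expect_identical(mecScore(exact), oracle)
      greedy <- phaseDirect(obs, sites = 1:6, maxExact = 1L)
      expect_identical(mecScore(greedy), oracle)
    }
  })
})

test_that("the reported MEC score is self-consistent with the assignment", {
  withr::with_seed(77, {
    for (rep in 1:25) {
      obs <- randomMecInstance(8L, 30L)
      ph <- phaseDirect(obs, sites = 1:8)
      recount <- sum(vapply(phaseBlocks(ph), function(b) {
        sub <- obs[, b, drop = FALSE]
        sub <- sub[rowSums(!is.na(sub)) > 0, , drop = FALSE]
        if (length(b) == 1L || nrow(sub) == 0L) 0L else
          as.integer(pgxphase:::mecCost(sub, hapAlleles(ph)[b]))
      }, 1L))
      expect_identical(mecScore(ph), recount)
    }
  })
})

test_that("read-length block model cuts between distant het sites", {
  expect_identical(computePhaseBlocks(c(341, 481, 803), 10000),
    list(1:3))
  expect_identical(computePhaseBlocks(c(341, 481, 803), 200),
    list(1:2, 3L))
  expect_identical(computePhaseBlocks(c(341, 481, 803), 4985),
    list(1:3))
  expect_identical(computePhaseBlocks(numeric(), 100), list())
  # monotonicity: block count non-increasing in read length
  withr::with_seed(5, {
    for (rep in 1:20) {
      pos <- sort(sample.int(10000, 8))
      nb <- vapply(c(50, 200, 500, 2000, 5000),
        function(rl) length(computePhaseBlocks(pos, rl)), 1L)
      expect_true(all(diff(nb) <= 0))
    }
  })
})

test_that("switch and Hamming errors match hand-enumerated cases", {
  mk <- function(hapA, blocks) new("PhaseResult",
    sites = seq_along(hapA), hapA = as.integer(hapA), blocks = blocks,
    mec = 0L, method = "direct", metadata = list())
  truth <- c(0L, 1L, 0L, 1L)
  expect_identical(phaseErrors(mk(truth, list(1:4)), truth),
    list(switch_errors = 0L, hamming = 0L))
  # global flip of the single block: equivalent labeling
  expect_identical(phaseErrors(mk(1L - truth, list(1:4)), truth),
    list(switch_errors = 0L, hamming = 0L))
  # relative phase flips once after site 2: one switch, hamming min(2,2)
  pred <- c(0L, 1L, 1L, 0L)
  expect_identical(phaseErrors(mk(pred, list(1:4)), truth),
    list(switch_errors = 1L, hamming = 2L))
  expect_error(phaseErrors(mk(truth, list(1:4)), c(0L, 1L)), "differ")
})

test_that("direct long-read phasing recovers cis/trans configurations", {
  cat <- testCatalog()
  # the published correction: statistical *6/*13 vs direct *4/*6,*13
  r <- runPipeline("NAT2", "*4/*6,*13", cat, seed = 33)
  expect_identical(r$called, "*4/*6,*13")
})

test_that("statistical joining is frequency-driven and flags exact ties", {
  cat <- testCatalog()
  # single block: returned unchanged
  ph <- new("PhaseResult", sites = c(282L, 590L), hapA = c(1L, 1L),
    blocks = list(1:2), mec = 0L, method = "blockmodel",
    metadata = list())
  out <- phaseStatistical(ph, cat, "NAT2")
  expect_identical(hapAlleles(out), c(1L, 1L))
  expect_identical(out@method, "statistical")

  two <- new("PhaseResult", sites = c(282L, 590L), hapA = c(0L, 0L),
    blocks = list(1L, 2L), mec = 0L, method = "blockmodel",
    metadata = list())
  # uniform table: every join scores equally -> ambiguous, canonical order
  unif <- data.frame(gene = "NAT2",
    haplotype = c("*4", "*6", "*13", "*6,*13"), freq = 0.1)
  outU <- phaseStatistical(two, cat, "NAT2", freq = unif)
  expect_true(outU@metadata$ambiguous_join)
  # shipped table: trans *6/*13 beats *4 + *6,*13
  outS <- phaseStatistical(two, cat, "NAT2")
  expect_false(outS@metadata$ambiguous_join)
  expect_identical(sum(hapAlleles(outS)), 1L)  # alleles split trans
})

test_that("statistical short-read emulation reproduces the published mis-assignments", {
  cat <- testCatalog()
  # truth *4/*6,*13 (Samples 3/11 genotype): statistical splits *6 / *13
  r3 <- runPipeline("NAT2", "*4/*6,*13", cat, method = "statistical",
    seed = 41)
  expect_identical(r3$called, "*6/*13")
  # truth *12/*5,*11 (Samples 9/10): statistical joins *5,*11,*12 vs *4
  r10 <- runPipeline("NAT2", "*12/*5,*11", cat, method = "statistical",
    seed = 42)
  expect_identical(r10$called, "*4/*5,*11,*12")
  expect_false(r10$concordant)
  # truth *12/*6,*13,*12 (Sample 11): trans split of *6 and *13 on a
  # homozygous *12 background
  r11 <- runPipeline("NAT2", "*12/*6,*13,*12", cat,
    method = "statistical", seed = 43)
  expect_identical(r11$called, "*6,*12/*12,*13")
  # a concordant profile stays concordant under statistical phasing
  r6 <- runPipeline("NAT2", "*4/*5,*11,*12", cat, method = "statistical",
    seed = 44)
  expect_true(r6$concordant)
})

test_that("phasing with no informative reads leaves sites unphased", {
  obs <- matrix(NA_integer_, 0, 3, dimnames = list(NULL, c("1", "2", "3")))
  expect_warning(ph <- phaseDirect(obs, sites = 1:3), "no informative")
  expect_identical(length(phaseBlocks(ph)), 3L)
})
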