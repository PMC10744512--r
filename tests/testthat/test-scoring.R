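test_that("every published CYP2D6 scoring row is reproduced exactly", {
  cat <- testCatalog()
  t3 <- readFixture("cyp2d6_calls.tsv")
  for (i in seq_len(nrow(t3))) {
    res <- activityScore(t3$diplotype[i], cat, "CYP2D6")
    expect_equal(res$activity_score, t3$activity_score[i],
      info = t3$diplotype[i])
    expect_identical(res$phenotype, t3$phenotype[i], info = t3$diplotype[i])
  }
  # the non-additive rows must resolve through the override table
  expect_identical(activityScore("*2 x 2/*5", cat, "CYP2D6")$source,
    "override")
  expect_identical(activityScore("*4/*41,*68", cat, "CYP2D6")$source,
    "override")
  expect_identical(activityScore("*5/*17", cat, "CYP2D6")$source,
    "additive")
})

test_that("every published UGT1A1 scoring row is reproduced exactly", {
  cat <- testCatalog()
  t4 <- readFixture("ugt1a1_calls.tsv")
  for (i in seq_len(nrow(t4))) {
    res <- activityScore(t4$diplotype[i], cat, "UGT1A1")
    expect_equal(res$activity_score, t4$activity_score[i],
      info = t4$diplotype[i])
    expect_identical(res$phenotype, t4$phenotype[i], info = t4$diplotype[i])
  }
  expect_identical(activityScore("*36/*60", cat, "UGT1A1")$source,
    "override")
})

test_that("phenotype bands map scores to metabolizer classes", {
  cat <- testCatalog()
  expect_identical(phenotypeFromScore("CYP2D6", 0, cat), "PM")
  expect_identical(phenotypeFromScore("CYP2D6", 0.5, cat), "PM")
  expect_identical(phenotypeFromScore("CYP2D6", 1.0, cat), "IM")
  expect_identical(phenotypeFromScore("CYP2D6", 1.25, cat), "NM")
  expect_identical(phenotypeFromScore("CYP2D6", 2.25, cat), "NM")
  expect_identical(phenotypeFromScore("CYP2D6", 3.0, cat), "UM")
  expect_identical(phenotypeFromScore("UGT1A1", 0.6, cat), "PM")
  expect_identical(phenotypeFromScore("UGT1A1", 1.3, cat), "IM")
  expect_identical(phenotypeFromScore("UGT1A1", 2.125, cat), "NM")
})

test_that("unknown activity without an override is indeterminate", {
  cat <- testCatalog()
  res <- activityScore("*1/*28", cat, "CYP2D6")
  expect_identical(res$phenotype, "indeterminate")
  expect_true(is.na(res$activity_score))
})

test_that("acetylator status follows the slow-haplotype count", {
  cat <- testCatalog()
  expect_identical(acetylatorStatus("*4/*4", cat), "RA")
  expect_identical(acetylatorStatus("*4/*12", cat), "RA")
  expect_identical(acetylatorStatus("*4/*6,*13", cat), "IA")
  expect_identical(acetylatorStatus("*6,*13/*6,*13", cat), "SA")
  # *11 and *13 never count as slow
  expect_identical(acetylatorStatus("*4/*11", cat), "RA")
  expect_identical(acetylatorStatus("*11/*13", cat), "RA")
})

test_that("the published acetylator columns are reproduced, with two printed exceptions", {
  cat <- testCatalog()
  t6 <- readFixture("nat2_calls.tsv")
  exceptions <- c("Sample 4", "Sample 9")
  for (i in seq_len(nrow(t6))) {
    gotS <- acetylatorStatus(t6$diplotype_srs[i], cat)
    gotL <- acetylatorStatus(t6$diplotype_lrs[i], cat)
    if (t6$sample[i] %in% exceptions) next
    expect_identical(gotS, t6$status_srs[i], info = t6$sample[i])
    expect_identical(gotL, t6$status_lrs[i], info = t6$sample[i])
  }
  # Sample 9 prints SA for a single-slow-haplotype diplotype (the same
  # diplotype is printed IA for Sample 10); Sample 4 prints IA although
  # both haplotypes carry a slow star. The count rule gives:
  expect_identical(acetylatorStatus("*12/*5,*11", cat), "IA")
  expect_identical(acetylatorStatus("*6,*13,*12/*5,*11", cat), "SA")
})

test_that("ambiguity classification follows the slow-SNV distance rule", {
  cat <- testCatalog()
  expect_false(classifyAmbiguity("*5,*12/*14", cat)$ambiguous)      # 150 bp
  expect_true(classifyAmbiguity("*5,*11,*12/*6,*13", cat)$ambiguous) # 249 bp
  expect_false(
    classifyAmbiguity("*5,*11,*12/*5,*11,*12", cat)$ambiguous)  # hom
  expect_false(classifyAmbiguity("*4/*5,*11,*12", cat)$ambiguous)   # 1 slow
  expect_true(classifyAmbiguity("*5/*6", cat)$ambiguous)            # 249 bp
  # invariant to haplotype order and component order
  a <- classifyAmbiguity("*5,*11,*12/*6,*13", cat)$ambiguous
  b <- classifyAmbiguity("*6,*13/*5,*11,*12", cat)$ambiguous
  c <- classifyAmbiguity("*13,*6/*12,*11,*5", cat)$ambiguous
  expect_identical(a, b)
  expect_identical(a, c)
})

test_that("acetylator status depends only on the slow-carrier count", {
  cat <- testCatalog()
  slowSet <- c("*5", "*6", "*7", "*14")  # independent restatement
  n5 <- readFixture("nat2_spread.tsv")
  for (s in n5$diplotype) {
    d <- parseDiplotype("NAT2", s)
    carriers <- sum(vapply(haplotypes(d),
      function(h) any(starComponents(h) %in% slowSet), TRUE))
    expect_identical(acetylatorStatus(d, cat),
      c("RA", "IA", "SA")[carriers + 1L], info = s)
  }
})
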