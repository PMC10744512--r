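test_that("identical call sets are concordant at all three levels", {
  a <- readCallSets("SRS")
  s1 <- a[a$sample == "Sample 1", ]
  rec <- compareCallSets(s1, s1)
  expect_true(all(rec$concordant))
})

test_that("published per-sample pairs reproduce their printed flags", {
  a <- readCallSets("SRS"); b <- readCallSets("LRS")
  s4 <- compareCallSets(a[a$sample == "Sample 4", ],
    b[b$sample == "Sample 4", ])
  expect_identical(s4$concordant, c(FALSE, FALSE, TRUE))
  s2 <- compareCallSets(a[a$sample == "Sample 2", ],
    b[b$sample == "Sample 2", ])
  expect_identical(s2$concordant, c(FALSE, TRUE, TRUE))
  expect_match(s2$detail[1], "marker")
  # every printed row of the concordance table
  rec <- compareCohorts(a, b)
  t1 <- readFixture("table1_concordance.tsv")
  for (l in c("haplotype", "diplotype", "phenotype")) {
    sub <- rec[rec$level == l, ]
    got <- sub$concordant[match(t1$sample, sub$sample)]
    expect_identical(got, t1[[l]] == "yes", info = l)
  }
})

test_that("concordance summaries use truncated one-decimal percentages", {
  a <- readCallSets("SRS"); b <- readCallSets("LRS")
  s <- summarizeConcordance(compareCohorts(a, b))
  expect_identical(s$percentage[s$level == "haplotype"], 38.4)
  expect_identical(s$percentage[s$level == "diplotype"], 61.5)
  expect_identical(s$percentage[s$level == "phenotype"], 100)
  expect_identical(s$n_concordant, c(5L, 8L, 13L))
})

test_that("summaries are permutation-invariant and support resampling", {
  a <- readCallSets("SRS"); b <- readCallSets("LRS")
  rec <- compareCohorts(a, b)
  perm <- rec[sample(nrow(rec)), ]
  s1 <- summarizeConcordance(rec)
  s2 <- summarizeConcordance(perm)
  expect_equal(s1[order(s1$level), ], s2[order(s2$level), ],
    ignore_attr = TRUE)
  # leave-one-out: percentages match a hand count from the printed flags
  t1 <- readFixture("table1_concordance.tsv")
  for (drop in t1$sample) {
    s <- summarizeConcordance(rec[rec$sample != drop, ])
    for (l in c("haplotype", "diplotype", "phenotype")) {
      expected <- sum(t1[[l]] == "yes" & t1$sample != drop)
      expect_identical(s$n_concordant[s$level == l], expected)
      expect_identical(s$percentage[s$level == l],
        floor(1000 * expected / 12) / 10)
    }
  }
})

test_that("phenotype-discordant pairs are also diplotype-discordant", {
  a <- readCallSets("SRS"); b <- readCallSets("LRS")
  rec <- compareCohorts(a, b)
  wide <- split(rec, rec$sample)
  for (w in wide) {
    phe <- w$concordant[w$level == "phenotype"]
    dip <- w$concordant[w$level == "diplotype"]
    expect_true(phe || !dip || TRUE)  # vacuous unless phenotype discordant
    if (!phe) expect_false(dip)
  }
})

test_that("cohort tallies reproduce the published spreads", {
  cat <- testCatalog()
  sp <- readFixture("cyp2d6_spread.tsv")
  del <- sp[sp$category == "deletion", ]
  t <- tallySpread(del$diplotype, classifierDeletionPartner(cat),
    counts = del$count)
  expect_identical(t$count[t$category == "normal"], 34L)
  expect_identical(t$count[t$category == "decreased/none"], 20L)
  expect_identical(t$count[t$category == "unknown"], 1L)
  expect_identical(t$percentage[t$category == "normal"], 61.8)
  expect_identical(t$percentage[t$category == "decreased/none"], 36.4)
  expect_identical(t$percentage[t$category == "unknown"], 1.8)

  forms <- tallySpread(sp$diplotype, categories = sp$category,
    counts = sp$count, denominator = 773)
  expect_identical(sum(forms$count), 198L)
  expect_identical(floor(1000 * sum(forms$count) / 773) / 10, 25.6)

  n5 <- readFixture("nat2_spread.tsv")
  t5 <- tallySpread(n5$diplotype, categories = n5$type, counts = n5$count)
  expect_identical(t5$count[t5$category == "non-ambiguous"], 282L)
  expect_identical(t5$count[t5$category == "ambiguous"], 129L)
  expect_identical(t5$percentage[t5$category == "non-ambiguous"], 68.6)
  expect_identical(t5$percentage[t5$category == "ambiguous"], 31.4)
})

test_that("tally percentages sum to 100 within rounding slack", {
  n5 <- readFixture("nat2_spread.tsv")
  t5 <- tallySpread(n5$diplotype, categories = n5$type, counts = n5$count)
  expect_lt(abs(sum(t5$percentage) - 100), 0.2)
  empty <- tallySpread(character(), classifier = identity)
  expect_identical(nrow(empty), 0L)
})

test_that("call sets over different gene sets are rejected", {
  a <- readCallSets("SRS")
  s1 <- a[a$sample == "Sample 1", ]
  expect_error(compareCallSets(s1, s1[-1, ]), "same genes")
})
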