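test_that("base composition counts bases and short windows correctly", {
  comp <- baseComposition("ACGT")
  expect_equal(unname(baseProportions(comp)), rep(0.25, 4))
  expect_equal(totalBases(comp), 4)
  comp2 <- baseComposition("AAAA")
  expect_equal(unname(baseProportions(comp2)), c(1, 0, 0, 0))
  comp3 <- baseComposition("AAAT")
  tri <- trinucleotideCounts(comp3)
  expect_equal(unname(tri[c("AAA", "AAT")]), c(1, 1))
  expect_equal(sum(tri), 2)  # number of 3-windows
  expect_error(baseComposition("NNNN"), "unambiguous")
})

test_that("zero-order expectation follows the mononucleotide product formula", {
  # exactly uniform base proportions, N = 1e6
  comp <- baseComposition(strrep("ACGT", 250000))
  expect_equal(expectedCountOrder0("GAAGAAGA", comp), 1e6 / 4^8)
  expect_equal(expectedCountOrder0("CCCCCCCC", comp), 1e6 / 4^8)
  compA <- baseComposition(strrep("A", 1000))
  expect_equal(expectedCountOrder0("AAAAAAAA", compA), 1000)
  compAT <- baseComposition(strrep("AT", 128))
  expect_equal(expectedCountOrder0("ATATATAT", compAT), 1)
  # a base with zero proportion gives expectation 0 (degenerate)
  expect_equal(expectedCountOrder0("ACGTACGT", compA), 0)
})

test_that("zero-order expectations are multinomially complete", {
  set.seed(3)
  comp <- baseComposition(randomSeq(20000))
  allWords <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 8)
  expect_equal(sum(expectedCountOrder0(allWords, comp)),
               totalBases(comp), tolerance = 1e-9)
})

test_that("chi-squared is the one-cell Pearson statistic", {
  expect_equal(chiSquared(15, 15), 0)
  expect_equal(chiSquared(30, 15), 15)
  e <- 1e6 / 4^8
  expect_equal(chiSquared(100, e), (100 - e)^2 / e)
  expect_error(chiSquared(10, 0), "positive")
  # exchangeable in words: depends only on (observed, expected)
  expect_identical(chiSquared(c(20, 20), c(5, 5)),
                   rep(chiSquared(20, 5), 2))
})

test_that("order-2 expectation reduces to observed counts for trinucleotides", {
  set.seed(11)
  for (i in 1:5) {
    s <- randomSeq(500, pN = ifelse(i == 3, 0.02, 0))
    comp <- baseComposition(s)
    tri <- trinucleotideCounts(comp)
    present <- names(tri)[tri > 0]
    expect_equal(expectedCountOrder2(present, comp),
                 unname(tri[present]))
  }
})

test_that("order-2 expectation is the tri/di plug-in ratio", {
  comp <- baseComposition(strrep("A", 10))
  # N3(AAA) = 8, N2(AA) = 9 -> 8 * 8 / 9
  expect_equal(expectedCountOrder2("AAAA", comp), 64 / 9)
  # a zero internal dinucleotide makes the word degenerate
  expect_equal(expectedCountOrder2("ACGT", comp), 0)
})

test_that("Gaussian z is centred and standardised on i.i.d. sequences", {
  set.seed(99)
  words <- unique(replicate(300, randomWord(8)))[1:256]
  zAll <- list()
  for (s in 1:3) {
    r <- generateRandomGenome(1e6, 0.5, seed = s)
    comp <- baseComposition(r)
    obs <- wordCounts(countWords(r, 8))[words]
    obs[is.na(obs)] <- 0L
    z <- gaussianZ(words, as.numeric(obs), comp)
    expect_gt(sd(z), 0.7)
    expect_lt(sd(z), 1.3)
    zp <- gaussianZ(words, as.numeric(obs), comp, variance = "poisson")
    expect_gt(sd(zp), 0.7)
    expect_lt(sd(zp), 1.3)
    zAll[[s]] <- z
  }
  expect_lt(abs(mean(unlist(zAll))), 0.15)
})

test_that("Gaussian z flags planted enrichment and degeneracy", {
  rec <- makeAnnotatedChromosome(1e6, seed = 21, word = "GAAGAAGA",
                                 ratePerMb = 60)
  comp <- baseComposition(rec)
  obs <- wordCounts(countWords(rec, 8))[["GAAGAAGA"]]
  expect_gt(gaussianZ("GAAGAAGA", obs, comp), 3)
  # observed == expected gives z = 0
  e <- expectedCountOrder2("GAAGAAGA", comp)
  expect_equal(gaussianZ("GAAGAAGA", e, comp), 0)
  compA <- baseComposition(strrep("A", 100))
  expect_warning(z <- gaussianZ("ACGTACGT", 5, compA), "degenerate")
  expect_true(is.na(z))
})

test_that("representation calls follow the thresholds for both models", {
  # order 0: over/under need chi2 >= 100 and the right direction
  expect_identical(classifyCalls(60, 15, chiSquared(60, 15), 0), "over")
  expect_identical(classifyCalls(0, 104, chiSquared(0, 104), 0), "under")
  expect_identical(classifyCalls(20, 15, chiSquared(20, 15), 0), "neutral")
  expect_identical(classifyCalls(200, 100, 100, 0), "over")
  expect_identical(classifyCalls(50, 100, 100, 0), "under")
  # order 2: symmetric z rule
  expect_identical(classifyCalls(NA, NA, c(2.5, -2.5, 0, 1.9), 2),
                   c("over", "under", "neutral", "neutral"))
  expect_identical(classifyCalls(NA, NA, NA_real_, 2), "neutral")
  expect_error(classifyCalls(1, 1, 1, 1), "modelOrder")
})

test_that("scoreWords produces a consistent tidy score table", {
  rec <- makeAnnotatedChromosome(2e5, seed = 33, word = "GAAGAAGA",
                                 ratePerMb = 200)
  comp <- baseComposition(rec)
  wt <- countWords(rec, 8)
  tab0 <- scoreWords(c("GAAGAAGA", "ACACACAC"), wt, comp, modelOrder = 0)
  expect_identical(tab0$call[tab0$oligomer == "GAAGAAGA"], "over")
  expect_true(all(tab0$statistic[!tab0$degenerate] >= 0))
  tab2 <- scoreWords(c("GAAGAAGA", "ACACACAC"), wt, comp, modelOrder = 2)
  expect_identical(tab2$call[tab2$oligomer == "GAAGAAGA"], "over")
  expect_identical(tab2$model_order, c(2, 2))
})
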