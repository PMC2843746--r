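test_that("random genomes hit the requested G+C and are reproducible", {
  r <- generateRandomGenome(1e6, 0.5, seed = 1)
  f <- Biostrings::letterFrequency(chromosomeSeq(r), c("G", "C"))
  expect_equal(sum(f) / 1e6, 0.5, tolerance = 0.004)
  r70 <- generateRandomGenome(2e5, 0.7, seed = 2)
  f70 <- Biostrings::letterFrequency(chromosomeSeq(r70), c("G", "C"))
  expect_equal(sum(f70) / 2e5, 0.7, tolerance = 0.01)
  # determinism
  a <- generateRandomGenome(5e4, 0.4, seed = 9)
  b <- generateRandomGenome(5e4, 0.4, seed = 9)
  expect_identical(as.character(chromosomeSeq(a)),
                   as.character(chromosomeSeq(b)))
  expect_error(generateRandomGenome(1e4, 0, 1), "between 0 and 1")
  expect_error(generateRandomGenome(1e4, 1, 1), "between 0 and 1")
})

test_that("planting writes non-overlapping copies at a Poisson rate", {
  r <- generateRandomGenome(1e6, 0.5, seed = 31)
  r0 <- plantWords(r, "GAAGAAGA", 0, seed = 32)
  expect_identical(as.character(chromosomeSeq(r0)),
                   as.character(chromosomeSeq(r)))
  r100 <- plantWords(r, "GAAGAAGA", 100, seed = 32)
  planted <- r100@metadata$planted[["GAAGAAGA"]]
  # Poisson(100) central band
  expect_gte(length(planted), 70)
  expect_lte(length(planted), 130)
  expect_true(all(diff(planted) >= 8))
  # every planted position is a real occurrence
  pos <- wordPositions(r100, "GAAGAAGA")
  expect_true(all(planted %in% pos))
  # background + planted clears the retention threshold at rate 60
  r60 <- plantWords(r, "GAAGAAGA", 60, seed = 33)
  n <- length(wordPositions(r60, "GAAGAAGA"))
  expect_gt(copiesPerMb(n, seqLength(r60)), 31)
})

test_that("synthetic annotation meets the coverage contract", {
  r <- generateRandomGenome(1e6, 0.5, seed = 41)
  cds <- generateAnnotation(r, 86, 900, seed = 42)
  rec <- chromosomeRecord(chromosomeId(r), chromosomeSeq(r), cds = cds)
  expect_gte(codingFraction(rec), 84)
  expect_lte(codingFraction(rec), 88)
  expect_true(all(GenomicRanges::width(cds) %% 3 == 0))
  # non-overlapping, alternating strands
  expect_true(all(GenomicRanges::start(cds)[-1] >
                    GenomicRanges::end(cds)[-length(cds)]))
  str <- as.character(GenomicRanges::strand(cds))
  expect_true(all(str[c(TRUE, FALSE)] == "+"))
  expect_true(all(str[c(FALSE, TRUE)] == "-"))
  expect_length(generateAnnotation(r, 0, seed = 1), 0L)
  expect_error(generateAnnotation(r, 100, seed = 1), "below 100")
})

test_that("a spec regenerates its chromosome bit-exactly", {
  sp <- syntheticSpec(1e5, 0.45,
                      data.frame(word = c("GAAGAAGA", "TCTTCTTC"),
                                 ratePerMb = c(60, 40)),
                      seed = 77)
  a <- generateSyntheticChromosome(sp)
  b <- generateSyntheticChromosome(sp)
  expect_identical(as.character(chromosomeSeq(a)),
                   as.character(chromosomeSeq(b)))
  expect_identical(GenomicRanges::start(cdsRanges(a)),
                   GenomicRanges::start(cdsRanges(b)))
  expect_identical(a@metadata$planted, b@metadata$planted)
  expect_identical(sort(names(a@metadata$planted)),
                   c("GAAGAAGA", "TCTTCTTC"))
})

test_that("planting budget above 5% of the chromosome is rejected", {
  expect_error(syntheticSpec(1e5, 0.5,
                             data.frame(word = "GAAGAAGA",
                                        ratePerMb = 10000)),
               "5%")
})

test_that("frame-constrained planting honours the requested frame", {
  sp <- syntheticSpec(2e5, 0.5, seed = 91)
  rec <- generateSyntheticChromosome(sp)
  rec2 <- plantWords(rec, "GATTACAG", 150, seed = 92, frame = 2L)
  planted <- rec2@metadata$planted[["GATTACAG"]]
  cds <- cdsRanges(rec2)
  hit <- IRanges::findOverlaps(IRanges::IRanges(planted, width = 8),
                               IRanges::IRanges(GenomicRanges::start(cds),
                                                GenomicRanges::end(cds)),
                               type = "within", select = "first")
  expect_false(anyNA(hit))
  frames <- vapply(seq_along(planted), function(i)
    frameOf(planted[i], cds[hit[i]], 8), numeric(1))
  expect_true(all(frames == 2))
})

test_that("fixture writing emits FASTA + GFF3 + provenance that round-trip", {
  sp <- syntheticSpec(5e4, 0.5,
                      data.frame(word = "GAAGAAGA", ratePerMb = 60),
                      seed = 13)
  rec <- generateSyntheticChromosome(sp)
  dir <- withr::local_tempdir()
  paths <- writeSyntheticFixture(rec, dir, prefix = "fix")
  expect_true(all(file.exists(paths)))
  prov <- readLines(file.path(dir, "fix.provenance.txt"))
  expect_true(any(grepl("seed=13", prov)))
  expect_true(any(grepl("planted=GAAGAAGA:60", prov)))
  back <- readChromosomes(file.path(dir, "fix.fasta"),
                          file.path(dir, "fix.gff3"))[[1]]
  expect_identical(as.character(chromosomeSeq(back)),
                   as.character(chromosomeSeq(rec)))
  expect_identical(length(cdsRanges(back)), length(cdsRanges(rec)))
})
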