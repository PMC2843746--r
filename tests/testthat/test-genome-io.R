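test_that("FASTA reading preserves entries, order, and normalises case/U", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x some description", "ACGT",
               ">y", "acgu", "NNRY"), fa)
  recs <- readChromosomes(fa)
  expect_length(recs, 2L)
  expect_identical(names(recs), c("x", "y"))
  expect_identical(as.character(chromosomeSeq(recs[["x"]])), "ACGT")
  expect_identical(seqLength(recs[["x"]]), 4L)
  # lowercase folded, U mapped to T, ambiguity codes retained
  expect_identical(as.character(chromosomeSeq(recs[["y"]])), "ACGTNNRY")
})

test_that("FASTA reading rejects empty and non-nucleotide input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(), fa)
  expect_error(readChromosomes(fa), "no sequences")
  writeLines(c(">p", "MKVLLITTT", ">q", "EEQQWWFFY"), fa)
  expect_error(readChromosomes(fa), "not nucleotide")
})

test_that("GFF3 CDS rows are selected by seqid with strand checking", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tCDS\t1\t9\t.\t+\t0",
               "chr1\t.\tCDS\t10\t12\t.\t-\t0",
               "chr1\t.\tgene\t1\t12\t.\t+\t.",
               "chr2\t.\tCDS\t5\t40\t.\t+\t0"), gff)
  cds <- readCdsAnnotation(gff, "chr1")
  expect_length(cds, 2L)
  expect_identical(GenomicRanges::start(cds), c(1L, 10L))
  expect_identical(GenomicRanges::end(cds), c(9L, 12L))
  expect_identical(as.character(GenomicRanges::strand(cds)), c("+", "-"))
  # rows for other chromosomes excluded
  expect_length(readCdsAnnotation(gff, "chr2"), 1L)
  writeLines(c("##gff-version 3",
               "chr1\t.\tCDS\t1\t9\t.\t.\t0"), gff)
  expect_error(readCdsAnnotation(gff, "chr1"), "strand")
})

test_that("GenBank CDS locations parse, decomposing join/complement", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TEST                 100 bp    DNA",
    "FEATURES             Location/Qualifiers",
    "     source          1..100",
    "     CDS             3..11",
    "                     /product=\"p1\"",
    "     CDS             complement(20..40)",
    "     CDS             join(50..60,70..90)",
    "ORIGIN",
    "//"), gb)
  cds <- readCdsGenbank(gb)
  expect_length(cds, 4L)
  expect_identical(GenomicRanges::start(cds), c(3L, 20L, 50L, 70L))
  expect_identical(GenomicRanges::end(cds), c(11L, 40L, 60L, 90L))
  expect_identical(as.character(GenomicRanges::strand(cds)),
                   c("+", "-", "+", "+"))
})

test_that("coding fraction is a union coverage percentage", {
  gr <- function(...) GenomicRanges::GRanges("x", IRanges::IRanges(...), "+")
  r <- suppressWarnings(
    chromosomeRecord("x", strrep("A", 1000), cds = gr(1, 860)))
  expect_equal(codingFraction(r), 86)
  r2 <- suppressWarnings(chromosomeRecord("x", strrep("A", 1000),
                         cds = gr(c(1, 401), c(500, 600))))
  expect_equal(codingFraction(r2), 60)
  expect_equal(codingFraction(chromosomeRecord("x", strrep("A", 1000))), 0)
})

test_that("coding fraction is invariant to CDS order and splitting", {
  set.seed(5)
  starts <- sort(sample.int(900, 10))
  ends <- pmin(starts + sample(30:90, 10, TRUE), 1000)
  gr <- GenomicRanges::GRanges("x", IRanges::IRanges(starts, ends), "+")
  r <- suppressWarnings(
    chromosomeRecord("x", strrep("A", 1000), cds = gr))
  shuffled <- suppressWarnings(chromosomeRecord("x", strrep("A", 1000),
                               cds = gr[sample(length(gr))]))
  expect_equal(codingFraction(shuffled), codingFraction(r))
  # split the first interval into two adjacent pieces
  g1 <- gr[1]
  mid <- GenomicRanges::start(g1) + 10L
  split2 <- c(GenomicRanges::GRanges("x",
                IRanges::IRanges(GenomicRanges::start(g1), mid), "+"),
              GenomicRanges::GRanges("x",
                IRanges::IRanges(mid + 1L, GenomicRanges::end(g1)), "+"),
              gr[-1])
  rSplit <- suppressWarnings(
    chromosomeRecord("x", strrep("A", 1000), cds = split2))
  expect_equal(codingFraction(rSplit), codingFraction(r))
})

test_that("FASTA/GFF3 write -> read round-trip preserves everything", {
  rec <- makeAnnotatedChromosome(5e4, seed = 9)
  dir <- withr::local_tempdir()
  writeChromosomeFasta(rec, file.path(dir, "r.fa"))
  writeCdsGff(rec, file.path(dir, "r.gff3"))
  back <- readChromosomes(file.path(dir, "r.fa"),
                          file.path(dir, "r.gff3"))[[1]]
  expect_identical(as.character(chromosomeSeq(back)),
                   as.character(chromosomeSeq(rec)))
  expect_identical(GenomicRanges::start(cdsRanges(back)),
                   GenomicRanges::start(cdsRanges(rec)))
  expect_identical(GenomicRanges::end(cdsRanges(back)),
                   GenomicRanges::end(cdsRanges(rec)))
  expect_identical(as.character(GenomicRanges::strand(cdsRanges(back))),
                   as.character(GenomicRanges::strand(cdsRanges(rec))))
})

test_that("CDS intervals outside the sequence are rejected, odd lengths flagged", {
  gr <- GenomicRanges::GRanges("x", IRanges::IRanges(5, 2000), "+")
  expect_error(suppressWarnings(
    chromosomeRecord("x", strrep("A", 1000), cds = gr)), "within")
  grOdd <- GenomicRanges::GRanges("x", IRanges::IRanges(1, 10), "+")
  expect_warning(r <- chromosomeRecord("x", strrep("A", 100), cds = grOdd),
                 "divisible by 3")
  expect_true(S4Vectors::mcols(cdsRanges(r))$lengthWarning)
})
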