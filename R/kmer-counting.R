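#' Strand-specific k-mer counting (k = 8-14)
#'
#' Tallies every overlapping window of length \code{k} consisting only of
#' A/C/G/T; windows containing any other symbol (N, IUPAC ambiguity codes)
#' are skipped and excluded from \code{usablePositions}. Counting is on the
#' given strand only: occurrences of a word's reverse complement are not
#' added (both members of a complement pair are separate words). Overlapping
#' occurrences count individually. The conservation identity
#' \code{sum(wordCounts(x)) == usablePositions(x)} holds for every input.
#'
#' Only observed words are stored, so the full \code{4^k} table is never
#' materialised (relevant at k = 13, 14). The counting core is compiled code
#' (rolling 2-bit encoding).
#'
#' @param x a character string, \code{DNAString} or
#'   [ChromosomeRecord-class].
#' @param k word length, between 8 and 14.
#' @return a [WordCountTable-class].
#' @examples
#' wt <- countWords(strrep("A", 10), 8)
#' wordCounts(wt)        # AAAAAAAA = 3
#' usablePositions(wt)   # 3
#' @export
#' @rdname countWords
setMethod("countWords", "character", function(x, k) {
  stopifnot(length(x) == 1L)
  .countWordsString(x, k, id = "unnamed")
})

#' @rdname countWords
#' @export
setMethod("countWords", "DNAString", function(x, k) {
  .countWordsString(as.character(x), k, id = "unnamed")
})

#' @rdname countWords
#' @export
setMethod("countWords", "ChromosomeRecord", function(x, k) {
  .countWordsString(as.character(chromosomeSeq(x)), k, id = chromosomeId(x))
})

.countWordsString <- function(seq, k, id) {
  k <- as.integer(k)
  if (k < 8L || k > 14L)
    stop("k must be between 8 and 14")
  if (nchar(seq) < k)
    stop("sequence too short: ", nchar(seq), " bp for k = ", k)
  res <- .kmer_count_cpp(toupper(seq), k)
  counts <- setNames(res$count, res$word)
  counts <- counts[order(names(counts))]
  new("WordCountTable", chromosomeId = id, k = k,
      counts = counts, usablePositions = res$usable)
}

#' Start positions of every overlapping exact occurrence of a word
#'
#' 1-based start positions, ascending. Overlapping matches are all reported.
#' A word longer than the sequence yields an empty vector (not an error).
#'
#' @param x a character string, \code{DNAString} or
#'   [ChromosomeRecord-class].
#' @param word the oligomer to locate (A/C/G/T only).
#' @return integer vector of start positions.
#' @examples
#' wordPositions("GAAGAAGAAGA", "GAAGAAGA")  # 1 4
#' @export
wordPositions <- function(x, word) {
  if (inherits(x, "ChromosomeRecord"))
    x <- chromosomeSeq(x)
  if (is.character(x))
    x <- DNAString(toupper(x))
  .checkAcgt(word)
  if (nchar(word) > length(x))
    return(integer(0))
  sort(start(matchPattern(DNAString(word), x)))
}

#' Normalise a count to copies per megabase
#'
#' \code{count * 1e6 / lengthBp}. The denominator is the full chromosome
#' length (not the number of usable windows), matching the survey's
#' "per Mb" convention; both are reported in score tables.
#'
#' @param count non-negative count(s).
#' @param lengthBp chromosome length in bp.
#' @return numeric copies per Mb.
#' @examples
#' copiesPerMb(31, 1e6)  # 31
#' @export
copiesPerMb <- function(count, lengthBp) {
  if (any(lengthBp <= 0))
    stop("lengthBp must be positive")
  count * 1e6 / lengthBp
}

.checkAcgt <- function(word) {
  if (grepl("[^ACGT]", word))
    stop("word contains non-ACGT characters: ", word)
  invisible(word)
}

#' Reverse complement of a plain-character oligomer
#'
#' Strict Watson-Crick reverse complement for words over A/C/G/T; any other
#' character is an error. (For \code{DNAString} inputs the \pkg{Biostrings}
#' method applies unchanged.)
#'
#' @param x a single character string over A/C/G/T.
#' @return the reverse complement, as character.
#' @examples
#' reverseComplement("GAAGAAGA")  # "TCTTCTTC"
#' @export
#' @rdname reverseComplement-character
setMethod("reverseComplement", "character", function(x, ...) {
  vapply(x, function(w) {
    .checkAcgt(w)
    paste(rev(strsplit(chartr("ACGT", "TGCA", w), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
})

#' Serialise a WordCountTable as TSV
#'
#' Columns: chromosome_id, k, oligomer, count, copies_per_mb. The
#' copies-per-Mb column uses \code{lengthBp} as denominator.
#'
#' @param x a [WordCountTable-class].
#' @param path output path.
#' @param lengthBp chromosome length used for normalisation.
#' @return the path, invisibly.
#' @export
writeWordCounts <- function(x, path, lengthBp) {
  df <- data.frame(
    chromosome_id = x@chromosomeId,
    k = x@k,
    oligomer = names(x@counts),
    count = as.integer(x@counts),
    copies_per_mb = copiesPerMb(as.numeric(x@counts), lengthBp)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
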