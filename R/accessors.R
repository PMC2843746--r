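#' Construct a ChromosomeRecord
#'
#' @param id character(1) identifier.
#' @param sequence a \code{DNAString} or single character string (uppercased,
#'   U mapped to T).
#' @param cds a \code{GRanges} of CDS intervals (1-based, closed) or NULL.
#' @param taxonLabel optional taxon label.
#' @param metadata optional list of provenance items.
#' @return a [ChromosomeRecord-class] object.
#' @examples
#' chromosomeRecord("x", "ACGTACGT")
#' @export
chromosomeRecord <- function(id, sequence, cds = NULL, taxonLabel = NA_character_,
                             metadata = list()) {
  if (is.character(sequence))
    sequence <- DNAString(chartr("u", "t", toupper(sequence)))
  if (is.null(cds))
    cds <- GRanges()
  if (length(cds) > 0L) {
    w <- width(cds)
    mcols(cds)$lengthWarning <- (w %% 3L) != 0L
    if (any(mcols(cds)$lengthWarning))
      warning(sum(mcols(cds)$lengthWarning),
              " CDS interval(s) have length not divisible by 3")
  }
  new("ChromosomeRecord", id = as.character(id), sequence = sequence,
      cds = cds, taxonLabel = as.character(taxonLabel), metadata = metadata)
}

#' @describeIn chromosomeRecord chromosome identifier
#' @param x a ChromosomeRecord.
#' @export
setMethod("chromosomeId", "ChromosomeRecord", function(x) x@id)

#' @describeIn chromosomeRecord the sequence as a \code{DNAString}
#' @export
setMethod("chromosomeSeq", "ChromosomeRecord", function(x) x@sequence)

#' @describeIn chromosomeRecord CDS annotation as a \code{GRanges}
#' @export
setMethod("cdsRanges", "ChromosomeRecord", function(x) x@cds)

#' @describeIn chromosomeRecord taxon label (may be NA)
#' @export
setMethod("taxonLabel", "ChromosomeRecord", function(x) x@taxonLabel)

#' @describeIn chromosomeRecord sequence length in bp
#' @export
setMethod("seqLength", "ChromosomeRecord", function(x) length(x@sequence))

setMethod("show", "ChromosomeRecord", function(object) {
  cat("ChromosomeRecord:", object@id, "\n")
  cat("  length:", length(object@sequence), "bp\n")
  cat("  CDS intervals:", length(object@cds), "\n")
  if (!is.na(object@taxonLabel))
    cat("  taxon:", object@taxonLabel, "\n")
})

#' @rdname countWords
#' @export
setMethod("wordCounts", "WordCountTable", function(x) x@counts)

#' @rdname countWords
#' @export
setMethod("usablePositions", "WordCountTable", function(x) x@usablePositions)

#' @rdname countWords
#' @export
setMethod("kmerSize", "WordCountTable", function(x) x@k)

setMethod("show", "WordCountTable", function(object) {
  cat("WordCountTable (", object@chromosomeId, "): k=", object@k,
      ", ", length(object@counts), " distinct words, ",
      object@usablePositions, " usable windows\n", sep = "")
})

#' @rdname baseComposition
#' @export
setMethod("baseProportions", "BaseComposition", function(x) x@proportions)

#' @rdname baseComposition
#' @export
setMethod("dinucleotideCounts", "BaseComposition",
          function(x) x@dinucleotideCounts)

#' @rdname baseComposition
#' @export
setMethod("trinucleotideCounts", "BaseComposition",
          function(x) x@trinucleotideCounts)

setMethod("show", "BaseComposition", function(object) {
  cat("BaseComposition over", object@totalBases, "unambiguous bases\n")
  print(round(object@proportions, 4))
})

#' @rdname locateInCoding
#' @param x a CodingLocalization.
#' @export
setMethod("frameCounts", "CodingLocalization", function(x) x@frameCounts)

setMethod("show", "CodingLocalization", function(object) {
  cat("CodingLocalization:", object@oligomer, "on", object@chromosomeId, "\n")
  cat("  occurrences:", object@nTotal, "(", object@nCoding, "coding,",
      round(object@pctCoding, 1), "% )\n")
  cat("  frames 1/2/3:", paste(object@frameCounts, collapse = "/"), "\n")
})

#' @rdname windowProfile
#' @param x a WindowProfile.
#' @export
setMethod("windowCounts", "WindowProfile", function(x) x@counts)

#' @rdname windowProfile
#' @export
setMethod("dispersion", "WindowProfile", function(x) x@dispersion)

setMethod("show", "WindowProfile", function(object) {
  cat("WindowProfile:", object@oligomer, "on", object@chromosomeId,
      "(", object@windowBp, "bp windows )\n")
  cat("  windows:", length(object@counts), " total occurrences:",
      sum(object@counts), " dispersion:", round(object@dispersion, 3), "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@lengthBp, "bp, G+C",
      round(100 * object@gc, 1), "%, coding target",
      object@codingFractionTarget, "%, seed", object@seed, "\n")
  if (nrow(object@planted)) {
    cat("  planted words:\n")
    print(object@planted)
  }
})

setMethod("show", "SurveyConfig", function(object) {
  cat("SurveyConfig\n")
  cat("  k:", paste(range(object@kRange), collapse = "-"),
      " minCpm:", object@minCpm, " chi2Min:", object@chi2Min,
      " zMin:", object@zMin, "\n")
  cat("  indexMode:", object@indexMode, " bothStrands:", object@bothStrands,
      " windowBp:", object@windowBp, " seed:", object@seed, "\n")
})
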