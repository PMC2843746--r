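#' @export
setGeneric("chromosomeId", function(x) standardGeneric("chromosomeId"))

#' @export
setGeneric("chromosomeSeq", function(x) standardGeneric("chromosomeSeq"))

#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))

#' @export
setGeneric("taxonLabel", function(x) standardGeneric("taxonLabel"))

#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' @export
setGeneric("wordCounts", function(x) standardGeneric("wordCounts"))

#' @export
setGeneric("usablePositions", function(x) standardGeneric("usablePositions"))

#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @export
setGeneric("baseProportions", function(x) standardGeneric("baseProportions"))

#' @export
setGeneric("dinucleotideCounts",
           function(x) standardGeneric("dinucleotideCounts"))

#' @export
setGeneric("trinucleotideCounts",
           function(x) standardGeneric("trinucleotideCounts"))

#' @export
setGeneric("frameCounts", function(x) standardGeneric("frameCounts"))

#' @export
setGeneric("windowCounts", function(x) standardGeneric("windowCounts"))

#' @export
setGeneric("dispersion", function(x) standardGeneric("dispersion"))

#' @export
setGeneric("codingFraction", function(x) standardGeneric("codingFraction"))

#' @export
setGeneric("countWords", function(x, k) standardGeneric("countWords"))
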