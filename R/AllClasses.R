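#' ChromosomeRecord: one replicon's sequence plus CDS annotation
#'
#' The unit of analysis for the survey. Holds a single chromosome (or plasmid)
#' sequence, its CDS annotation as a \link[GenomicRanges]{GRanges} (1-based,
#' closed intervals, the Bioconductor convention), an optional taxon label and
#' free-form metadata (e.g. planted-word provenance for synthetic records).
#'
#' CDS intervals whose width is not a multiple of 3 are retained (real
#' annotations contain such exceptions) but flagged in
#' \code{mcols(cdsRanges(x))$lengthWarning}.
#'
#' @slot id character(1) identifier (FASTA header word / GFF3 seqid).
#' @slot sequence a \link[Biostrings]{DNAString}; IUPAC ambiguity codes are
#'   retained, downstream counting skips windows containing them.
#' @slot cds a \code{GRanges} of CDS intervals on strand \code{+}/\code{-},
#'   all within \code{[1, length(sequence)]}.
#' @slot taxonLabel character(1) or \code{NA}.
#' @slot metadata list of provenance items.
#'
#' @seealso [chromosomeRecord()], [readChromosomes()], [codingFraction()]
#' @exportClass ChromosomeRecord
setClass("ChromosomeRecord",
  slots = c(
    id = "character",
    sequence = "DNAString",
    cds = "GRanges",
    taxonLabel = "character",
    metadata = "list"
  )
)

setValidity("ChromosomeRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  len <- length(object@sequence)
  if (length(object@cds) > 0L) {
    if (any(GenomicRanges::start(object@cds) < 1L) ||
        any(GenomicRanges::end(object@cds) > len))
      msg <- c(msg, "CDS intervals must lie within [1, sequence length]")
    str <- as.character(GenomicRanges::strand(object@cds))
    if (any(!str %in% c("+", "-")))
      msg <- c(msg, "CDS strand must be '+' or '-'")
  }
  if (length(msg)) msg else TRUE
})

#' BaseComposition: mono-, di- and trinucleotide content of a sequence
#'
#' Sufficient statistics for the zero-order and second-order Markov null
#' models: base proportions over unambiguous positions, and di-/trinucleotide
#' counts over ambiguity-free windows.
#'
#' @slot totalBases numeric(1), number of unambiguous (A/C/G/T) positions.
#' @slot proportions named numeric(4), base proportions (sum to 1).
#' @slot dinucleotideCounts named numeric(16).
#' @slot trinucleotideCounts named numeric(64).
#'
#' @seealso [baseComposition()], [expectedCountOrder0()],
#'   [expectedCountOrder2()]
#' @exportClass BaseComposition
setClass("BaseComposition",
  slots = c(
    totalBases = "numeric",
    proportions = "numeric",
    dinucleotideCounts = "numeric",
    trinucleotideCounts = "numeric"
  )
)

setValidity("BaseComposition", function(object) {
  msg <- character()
  if (!identical(names(object@proportions), c("A", "C", "G", "T")))
    msg <- c(msg, "'proportions' must be named A, C, G, T")
  else if (abs(sum(object@proportions) - 1) > 1e-12)
    msg <- c(msg, "'proportions' must sum to 1")
  if (length(object@dinucleotideCounts) != 16L)
    msg <- c(msg, "'dinucleotideCounts' must have 16 entries")
  if (length(object@trinucleotideCounts) != 64L)
    msg <- c(msg, "'trinucleotideCounts' must have 64 entries")
  if (length(msg)) msg else TRUE
})

#' WordCountTable: strand-specific k-mer counts of one chromosome
#'
#' Observed counts of every k-mer (k in 8-14) present on the given strand,
#' counted over all overlapping ambiguity-free windows. The conservation
#' identity \code{sum(wordCounts(x)) == usablePositions(x)} always holds.
#'
#' @slot chromosomeId character(1).
#' @slot k integer(1) word length.
#' @slot counts named integer vector over observed words only.
#' @slot usablePositions numeric(1), number of length-k windows free of
#'   ambiguity codes.
#'
#' @seealso [countWords()], [copiesPerMb()]
#' @exportClass WordCountTable
setClass("WordCountTable",
  slots = c(
    chromosomeId = "character",
    k = "integer",
    counts = "integer",
    usablePositions = "numeric"
  )
)

setValidity("WordCountTable", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "'k' must be a single positive integer")
  if (length(object@counts) &&
      (is.null(names(object@counts)) ||
       any(nchar(names(object@counts)) != object@k)))
    msg <- c(msg, "count names must all have length k")
  if (sum(as.numeric(object@counts)) != object@usablePositions)
    msg <- c(msg, "sum of counts must equal usablePositions")
  if (length(msg)) msg else TRUE
})

#' CodingLocalization: where a word's occurrences fall relative to CDS
#'
#' Per-word, per-chromosome localization: how many occurrences are fully
#' contained in annotated CDS, and their reading-frame distribution in coding
#' orientation (frame 1 = in frame with the reading frame of the CDS).
#'
#' @slot oligomer character(1).
#' @slot chromosomeId character(1).
#' @slot nTotal integer(1) total occurrences examined.
#' @slot nCoding integer(1) occurrences fully inside a CDS.
#' @slot pctCoding numeric(1), 100 * nCoding / nTotal (NA when nTotal = 0).
#' @slot frameCounts named integer(3), occurrences per frame 1/2/3;
#'   sums to nCoding.
#'
#' @seealso [locateInCoding()], [frameBiasTest()]
#' @exportClass CodingLocalization
setClass("CodingLocalization",
  slots = c(
    oligomer = "character",
    chromosomeId = "character",
    nTotal = "integer",
    nCoding = "integer",
    pctCoding = "numeric",
    frameCounts = "integer"
  )
)

setValidity("CodingLocalization", function(object) {
  msg <- character()
  if (object@nCoding > object@nTotal)
    msg <- c(msg, "nCoding cannot exceed nTotal")
  if (length(object@frameCounts) != 3L ||
      sum(object@frameCounts) != object@nCoding)
    msg <- c(msg, "frameCounts must have 3 entries summing to nCoding")
  if (length(msg)) msg else TRUE
})

#' WindowProfile: occurrence counts of a word in fixed genomic windows
#'
#' Positional distribution of one word along a chromosome at a fixed window
#' size (default 50 kb), plus a variance/mean dispersion statistic over full
#' windows used as a simple clustering detector (Poisson-like spread gives
#' dispersion near 1; a single dense cluster inflates it).
#'
#' @slot chromosomeId character(1).
#' @slot oligomer character(1).
#' @slot windowBp integer(1).
#' @slot counts integer vector, one entry per window (last window may be
#'   partial).
#' @slot dispersion numeric(1) variance/mean over full windows (NA when
#'   undefined).
#'
#' @seealso [windowProfile()]
#' @exportClass WindowProfile
setClass("WindowProfile",
  slots = c(
    chromosomeId = "character",
    oligomer = "character",
    windowBp = "integer",
    counts = "integer",
    dispersion = "numeric"
  )
)

#' SyntheticSpec: full recipe for one synthetic chromosome
#'
#' Captures everything needed to regenerate a synthetic chromosome bit-exactly:
#' length, G+C content, planted words and rates, target coding fraction, mean
#' gene length and the master seed. All randomness in generation flows from
#' \code{seed} through documented substream offsets.
#'
#' @slot lengthBp numeric(1) chromosome length in bp.
#' @slot gc numeric(1) G+C fraction in (0, 1).
#' @slot planted data.frame with columns \code{word}, \code{ratePerMb},
#'   \code{frame} (NA = unconstrained placement).
#' @slot codingFractionTarget numeric(1) percent of the chromosome to cover
#'   with synthetic CDS (default 86).
#' @slot meanGeneBp numeric(1) mean synthetic gene length (default 900).
#' @slot seed integer(1) master seed.
#'
#' @seealso [syntheticSpec()], [generateSyntheticChromosome()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  slots = c(
    lengthBp = "numeric",
    gc = "numeric",
    planted = "data.frame",
    codingFractionTarget = "numeric",
    meanGeneBp = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@lengthBp < 100)
    msg <- c(msg, "'lengthBp' must be at least 100")
  if (object@gc <= 0 || object@gc >= 1)
    msg <- c(msg, "'gc' must lie strictly between 0 and 1")
  if (nrow(object@planted)) {
    if (!all(c("word", "ratePerMb", "frame") %in% names(object@planted)))
      msg <- c(msg, "'planted' needs columns word, ratePerMb, frame")
    else {
      if (any(object@planted$ratePerMb < 0))
        msg <- c(msg, "planted rates must be non-negative")
      plantedBp <- sum(nchar(object@planted$word) *
                         object@planted$ratePerMb) * object@lengthBp / 1e6
      if (plantedBp > 0.05 * object@lengthBp)
        msg <- c(msg, "total planted bases exceed 5% of the chromosome")
    }
  }
  if (object@codingFractionTarget < 0 || object@codingFractionTarget >= 100)
    msg <- c(msg, "'codingFractionTarget' must be in [0, 100)")
  if (length(msg)) msg else TRUE
})

#' SurveyConfig: thresholds, inputs and seed of a full survey run
#'
#' Bundles every knob of the pipeline. Defaults are the survey's canonical
#' thresholds: retain words with at least 31 copies per Mb and a one-cell
#' chi-squared of at least 100 under the zero-order model; call second-order
#' over/underrepresentation at |z| >= 1.96.
#'
#' @slot kRange integer vector of word lengths, within 8-14.
#' @slot minCpm numeric(1) copies-per-Mb retention threshold.
#' @slot chi2Min numeric(1) chi-squared retention threshold.
#' @slot zMin numeric(1) two-sided z threshold for order-2 calls.
#' @slot indexMode \code{"subtract"} (n_over - n_under) or \code{"exclude"}
#'   (n_over alone) for the order-2 ranking index.
#' @slot bothStrands logical(1), add reverse-complement counts when counting.
#' @slot windowBp integer(1) window size for positional profiles.
#' @slot varianceMode \code{"conditional"} or \code{"poisson"} for the
#'   order-2 Gaussian z denominator.
#' @slot seed integer(1).
#' @slot fastaPath,gffPath,outDir character(1) paths ("" when unset).
#'
#' @seealso [surveyConfig()], [runSurvey()]
#' @exportClass SurveyConfig
setClass("SurveyConfig",
  slots = c(
    kRange = "integer",
    minCpm = "numeric",
    chi2Min = "numeric",
    zMin = "numeric",
    indexMode = "character",
    bothStrands = "logical",
    windowBp = "integer",
    varianceMode = "character",
    seed = "integer",
    fastaPath = "character",
    gffPath = "character",
    outDir = "character"
  )
)

setValidity("SurveyConfig", function(object) {
  msg <- character()
  if (any(object@kRange < 8L) || any(object@kRange > 14L))
    msg <- c(msg, "'kRange' must lie within [8, 14]")
  if (object@minCpm <= 0 || object@chi2Min <= 0 || object@zMin <= 0)
    msg <- c(msg, "all thresholds must be positive")
  if (!object@indexMode %in% c("subtract", "exclude"))
    msg <- c(msg, "'indexMode' must be 'subtract' or 'exclude'")
  if (!object@varianceMode %in% c("conditional", "poisson"))
    msg <- c(msg, "'varianceMode' must be 'conditional' or 'poisson'")
  if (object@windowBp <= 0L)
    msg <- c(msg, "'windowBp' must be positive")
  if (length(msg)) msg else TRUE
})
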