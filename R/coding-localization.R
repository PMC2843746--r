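#' Reading frame of a word occurrence within a CDS
#'
#' Frame of the word's 5' end in the coding orientation of its containing
#' CDS, in \{1, 2, 3\}; frame 1 is "in frame" with the reading frame of the
#' CDS. With 1-based closed coordinates: on the \code{+} strand
#' \code{((start - cdsStart) mod 3) + 1}; on the \code{-} strand the word's
#' 5' end in coding orientation is its last base, giving
#' \code{((cdsEnd - (start + wordLength - 1)) mod 3) + 1}.
#'
#' @param occurrenceStart 1-based start position(s) of the occurrence.
#' @param cds a length-1 \code{GRanges} (or one recycled per occurrence).
#' @param wordLength word length in bp.
#' @return integer frame(s) in \{1, 2, 3\}.
#' @examples
#' cds <- GenomicRanges::GRanges("x", IRanges::IRanges(101, 200), "+")
#' frameOf(101, cds, 8)  # 1
#' frameOf(102, cds, 8)  # 2
#' @export
frameOf <- function(occurrenceStart, cds, wordLength) {
  cdsStart <- start(cds)
  cdsEnd <- end(cds)
  str <- as.character(strand(cds))
  if (any(occurrenceStart < cdsStart |
          occurrenceStart + wordLength - 1L > cdsEnd))
    stop("occurrence not contained in the CDS")
  framePlus <- ((occurrenceStart - cdsStart) %% 3L) + 1L
  frameMinus <- ((cdsEnd - (occurrenceStart + wordLength - 1L)) %% 3L) + 1L
  ifelse(rep_len(str == "+", length(framePlus)), framePlus, frameMinus)
}

#' Localize word occurrences relative to CDS annotation
#'
#' An occurrence is coding iff its full extent
#' \code{[start, start + wordLength - 1]} lies inside at least one CDS
#' interval (a straddling occurrence has no well-defined frame and counts
#' as non-coding). Occurrences inside overlapping CDS are assigned once, to
#' the first containing CDS in annotation order, so totals are conserved.
#'
#' @param positions 1-based start positions of the word's occurrences.
#' @param wordLength word length in bp.
#' @param cds a \code{GRanges} of CDS intervals.
#' @param oligomer,chromosomeId labels recorded in the result.
#' @return a [CodingLocalization-class].
#' @export
locateInCoding <- function(positions, wordLength, cds,
                           oligomer = NA_character_,
                           chromosomeId = NA_character_) {
  nTotal <- length(positions)
  frames <- integer(0)
  if (nTotal > 0L && length(cds) > 0L) {
    occ <- IRanges(positions, width = wordLength)
    hit <- findOverlaps(occ, IRanges(start(cds), end(cds)),
                        type = "within", select = "first")
    inCds <- !is.na(hit)
    if (any(inCds))
      frames <- frameOf(positions[inCds], cds[hit[inCds]], wordLength)
  }
  fc <- tabulate(frames, nbins = 3L)
  nCoding <- length(frames)
  new("CodingLocalization",
      oligomer = oligomer, chromosomeId = chromosomeId,
      nTotal = as.integer(nTotal), nCoding = as.integer(nCoding),
      pctCoding = if (nTotal > 0) 100 * nCoding / nTotal else NA_real_,
      frameCounts = setNames(as.integer(fc), c("frame1", "frame2", "frame3")))
}

#' @rdname locateInCoding
#' @export
pctCoding <- function(x) x@pctCoding

#' Chi-squared test of reading-frame uniformity
#'
#' Pearson chi-squared of the frame-1/2/3 counts against the uniform
#' (1/3, 1/3, 1/3) distribution, 2 degrees of freedom. Used to check that a
#' word shows no preference for any reading frame.
#'
#' @param frameCounts integer(3) of frame counts, or a
#'   [CodingLocalization-class].
#' @return list with \code{statistic}, \code{df}, \code{p.value}; all NA
#'   (with a warning) when there are no coding occurrences.
#' @examples
#' frameBiasTest(c(10, 10, 10))$statistic  # 0
#' @export
frameBiasTest <- function(frameCounts) {
  if (inherits(frameCounts, "CodingLocalization"))
    frameCounts <- frameCounts@frameCounts
  if (sum(frameCounts) == 0) {
    warning("no coding occurrences; frame bias undefined")
    return(list(statistic = NA_real_, df = 2L, p.value = NA_real_))
  }
  ht <- suppressWarnings(chisq.test(frameCounts, p = rep(1 / 3, 3)))
  list(statistic = unname(ht$statistic), df = 2L,
       p.value = unname(ht$p.value))
}
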