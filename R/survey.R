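#' Copies-per-Mb retention threshold for a random word
#'
#' A random k-mer is expected \code{1e6 / 4^k} times per Mb under
#' equiprobable bases (15.26 for an octamer, printed as 15.2). The retention
#' threshold is twice that expectation, rounded up to the next integer: 31
#' copies per Mb for octamers.
#'
#' @param k word length.
#' @return list with \code{expectedPerMb} and \code{threshold}.
#' @examples
#' retentionThreshold(8)$threshold  # 31
#' @export
retentionThreshold <- function(k = 8) {
  expectedPerMb <- 1e6 / 4^k
  list(expectedPerMb = expectedPerMb,
       threshold = ceiling(2 * expectedPerMb))
}

#' Scan one chromosome for overrepresented words
#'
#' For every word length in \code{kRange}, retains words with at least
#' \code{minCpm} copies per Mb whose observed count exceeds the zero-order
#' Markov expectation with a one-cell chi-squared of at least \code{chi2Min}.
#'
#' @param record a [ChromosomeRecord-class].
#' @param kRange integer vector of word lengths within 8-14.
#' @param minCpm copies-per-Mb threshold (default 31).
#' @param chi2Min chi-squared threshold (default 100).
#' @param bothStrands if TRUE, a word's count is pooled with its reverse
#'   complement's before thresholding.
#' @return data.frame with columns chromosome_id, k, oligomer, count,
#'   copies_per_mb, expected, chi2 (zero rows when nothing qualifies).
#' @export
scanChromosome <- function(record, kRange = 8:14, minCpm = 31,
                           chi2Min = 100, bothStrands = FALSE) {
  len <- seqLength(record)
  if (len < max(kRange))
    stop("chromosome shorter than the largest word length requested")
  comp <- baseComposition(record)
  out <- list()
  for (k in sort(unique(as.integer(kRange)))) {
    wt <- countWords(record, k)
    counts <- as.numeric(wordCounts(wt))
    words <- names(wordCounts(wt))
    if (bothStrands) {
      rc <- as.character(reverseComplement(DNAStringSet(words)))
      rcCounts <- setNames(counts, words)[rc]
      rcCounts[is.na(rcCounts)] <- 0
      counts <- counts + as.numeric(rcCounts)
    }
    minCount <- minCpm * len / 1e6
    keep <- counts >= minCount
    if (!any(keep)) next
    words <- words[keep]; counts <- counts[keep]
    ex <- expectedCountOrder0(words, comp)
    chi2 <- ifelse(ex > 0, (counts - ex)^2 / ex, NA_real_)
    hit <- !is.na(chi2) & chi2 >= chi2Min & counts > ex
    if (!any(hit)) next
    out[[as.character(k)]] <- data.frame(
      chromosome_id = chromosomeId(record),
      k = k,
      oligomer = words[hit],
      count = counts[hit],
      copies_per_mb = copiesPerMb(counts[hit], len),
      expected = ex[hit],
      chi2 = chi2[hit]
    )
  }
  if (!length(out))
    return(data.frame(chromosome_id = character(), k = integer(),
                      oligomer = character(), count = numeric(),
                      copies_per_mb = numeric(), expected = numeric(),
                      chi2 = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$k, res$oligomer), , drop = FALSE]
}

#' Intersect per-genome overrepresented-word sets
#'
#' Words common to every set in the list (the cross-phylum selection step:
#' words overrepresented in all five genomes of a selection set).
#'
#' @param perGenomeSets non-empty list of character vectors.
#' @return character vector of words present in every set.
#' @examples
#' selectCommonOligomers(list(c("A", "B", "C"), c("B", "C"), c("C", "B")))
#' @export
selectCommonOligomers <- function(perGenomeSets) {
  if (!length(perGenomeSets))
    stop("empty list of sets")
  sort(Reduce(intersect, perGenomeSets))
}

#' All 512 homopurine and homopyrimidine octamers
#'
#' Every 8-mer over \{A, G\} plus every 8-mer over \{C, T\} (2^8 + 2^8 =
#' 512), in lexicographic order. These are the candidate abundant oligomers:
#' purine tracts with interspersed guanines and their pyrimidine
#' complements.
#'
#' @return character vector of 512 octamers.
#' @examples
#' length(enumerateHomoOctamers())  # 512
#' @export
enumerateHomoOctamers <- function() {
  expand8 <- function(alphabet) {
    g <- do.call(expand.grid,
                 c(rep(list(alphabet), 8), stringsAsFactors = FALSE))
    do.call(paste0, g)
  }
  sort(c(expand8(c("A", "G")), expand8(c("C", "T"))))
}

#' Cohort-level overrepresentation summary of candidate words
#'
#' For each candidate word, tallies across the cohort: the number of
#' chromosomes where it passes the zero-order thresholds (copies/Mb >=
#' \code{minCpm}, observed > expected, chi-squared >= \code{chi2Min}); the
#' numbers of chromosomes where the second-order Gaussian z calls it over-
#' or underrepresented; the overrepresentation index (\code{"subtract"}
#' mode: n_over_2 - n_under_2; \code{"exclude"} mode: n_over_2 alone); ranks
#' under both models (descending tallies, ties broken lexicographically);
#' and the median and quartiles (linear interpolation, \code{quantile} type
#' 7) of copies per Mb over the chromosomes where the zero-order thresholds
#' were met.
#'
#' @param cohort non-empty list of [ChromosomeRecord-class] objects.
#' @param candidates character vector of candidate words (any mix of
#'   lengths 8-14).
#' @param minCpm,chi2Min,zMin thresholds.
#' @param indexMode \code{"subtract"} or \code{"exclude"}.
#' @param variance variance mode for the order-2 z (see [gaussianZ()]).
#' @param bothStrands pool reverse-complement counts before thresholding.
#' @return data.frame, one row per candidate: oligomer, n_over_0, n_over_2,
#'   n_under_2, index, rank_0, rank_2, median_cpm, q1_cpm, q3_cpm.
#' @export
summariseCohort <- function(cohort, candidates, minCpm = 31, chi2Min = 100,
                            zMin = 1.96, indexMode = c("subtract", "exclude"),
                            variance = "conditional", bothStrands = FALSE) {
  indexMode <- match.arg(indexMode)
  if (!length(cohort))
    stop("empty cohort")
  candidates <- sort(unique(candidates))
  nC <- length(candidates)
  qual0 <- matrix(FALSE, nC, length(cohort))
  over2 <- matrix(FALSE, nC, length(cohort))
  under2 <- matrix(FALSE, nC, length(cohort))
  cpm <- matrix(NA_real_, nC, length(cohort))
  kGroups <- split(seq_len(nC), nchar(candidates))
  for (j in seq_along(cohort)) {
    rec <- cohort[[j]]
    len <- seqLength(rec)
    comp <- baseComposition(rec)
    for (idx in kGroups) {
      words <- candidates[idx]
      k <- nchar(words[1])
      wt <- countWords(rec, k)
      obs <- wordCounts(wt)[words]
      obs[is.na(obs)] <- 0L
      obs <- as.numeric(obs)
      if (bothStrands) {
        rc <- as.character(reverseComplement(DNAStringSet(words)))
        rcObs <- wordCounts(wt)[rc]
        rcObs[is.na(rcObs)] <- 0L
        obs <- obs + as.numeric(rcObs)
      }
      cpm[idx, j] <- copiesPerMb(obs, len)
      ex0 <- expectedCountOrder0(words, comp)
      chi2 <- ifelse(ex0 > 0, (obs - ex0)^2 / ex0, NA_real_)
      qual0[idx, j] <- cpm[idx, j] >= minCpm & !is.na(chi2) &
        chi2 >= chi2Min & obs > ex0
      z <- suppressWarnings(gaussianZ(words, obs, comp, variance = variance))
      over2[idx, j] <- !is.na(z) & z >= zMin
      under2[idx, j] <- !is.na(z) & z <= -zMin
    }
  }
  nOver0 <- rowSums(qual0)
  nOver2 <- rowSums(over2)
  nUnder2 <- rowSums(under2)
  index <- if (indexMode == "subtract") nOver2 - nUnder2 else nOver2
  rank0 <- rank2 <- integer(nC)
  rank0[order(-nOver0, candidates)] <- seq_len(nC)
  rank2[order(-index, candidates)] <- seq_len(nC)
  qs <- t(vapply(seq_len(nC), function(i) {
    v <- cpm[i, qual0[i, ]]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
    unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  }, numeric(3)))
  data.frame(
    oligomer = candidates,
    n_over_0 = nOver0,
    n_over_2 = nOver2,
    n_under_2 = nUnder2,
    index = index,
    rank_0 = rank0,
    rank_2 = rank2,
    median_cpm = qs[, 2],
    q1_cpm = qs[, 1],
    q3_cpm = qs[, 3]
  )
}
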