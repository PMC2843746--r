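#' Mono-, di- and trinucleotide composition of a sequence
#'
#' Computes the sufficient statistics of the two null models: base
#' proportions over unambiguous (A/C/G/T) positions for the zero-order
#' model, and di-/trinucleotide counts over ambiguity-free windows for the
#' second-order model.
#'
#' @param x a character string, \code{DNAString} or
#'   [ChromosomeRecord-class].
#' @return a [BaseComposition-class].
#' @examples
#' comp <- baseComposition("ACGT")
#' baseProportions(comp)  # 0.25 each
#' @export
baseComposition <- function(x) {
  if (inherits(x, "ChromosomeRecord"))
    x <- chromosomeSeq(x)
  if (is.character(x))
    x <- DNAString(toupper(x))
  mono <- oligonucleotideFrequency(x, 1)[c("A", "C", "G", "T")]
  n <- sum(mono)
  if (n == 0)
    stop("sequence contains no unambiguous bases")
  di <- oligonucleotideFrequency(x, 2)
  tri <- oligonucleotideFrequency(x, 3)
  new("BaseComposition",
      totalBases = as.numeric(n),
      proportions = mono / n,
      dinucleotideCounts = as.numeric(di) |> setNames(names(di)),
      trinucleotideCounts = as.numeric(tri) |> setNames(names(tri)))
}

#' @rdname baseComposition
#' @export
totalBases <- function(x) x@totalBases

.letterCounts <- function(words) {
  n <- nchar(words)
  vapply(c("A", "C", "G", "T"),
         function(b) n - nchar(gsub(b, "", words, fixed = TRUE)),
         numeric(length(words)))
}

#' Expected word count under the zero-order Markov model
#'
#' \code{N * A^a * C^c * G^g * T^t}, where \code{N} is the genome size in
#' unambiguous nucleotides, \code{A} the genomic proportion of adenine and
#' \code{a} the number of adenines in the word (and so on for the other
#' bases). \code{N} is deliberately the full genome size, not the window
#' count \code{N - k + 1}: at genome scale the difference is negligible and
#' the full-size form gives the canonical 10^6/4^8 = 15.26 expected copies
#' of a random octamer per Mb.
#'
#' A word using a base whose genomic proportion is 0 has expectation 0 and
#' is flagged degenerate by the scoring wrapper.
#'
#' @param word character vector of words (A/C/G/T).
#' @param comp a [BaseComposition-class].
#' @return numeric vector of expected counts.
#' @examples
#' comp <- baseComposition(strrep("ACGT", 100))
#' expectedCountOrder0("GAAGAAGA", comp)  # 400 / 4^8
#' @export
expectedCountOrder0 <- function(word, comp) {
  lc <- .letterCounts(word)
  if (length(word) == 1L) lc <- matrix(lc, nrow = 1)
  p <- baseProportions(comp)
  unname(totalBases(comp) * p["A"]^lc[, 1] * p["C"]^lc[, 2] *
           p["G"]^lc[, 3] * p["T"]^lc[, 4])
}

#' One-cell Pearson chi-squared overrepresentation statistic
#'
#' \code{(obs - exp)^2 / exp}. Used as a level of over/underrepresentation,
#' not as a significance test (no multiple-testing correction applies);
#' direction is recovered from \code{sign(obs - exp)}.
#'
#' @param observed observed count(s).
#' @param expected expected count(s), strictly positive.
#' @return numeric chi-squared value(s).
#' @examples
#' chiSquared(30, 15)  # 15
#' @export
chiSquared <- function(observed, expected) {
  if (any(expected <= 0))
    stop("expected count must be positive")
  (observed - expected)^2 / expected
}

.triWindows <- function(word) {
  k <- nchar(word)
  substring(word, seq_len(k - 2L), seq_len(k - 2L) + 2L)
}

.diInternal <- function(word) {
  k <- nchar(word)
  if (k < 4L) return(character(0))
  substring(word, 2:(k - 2L), 3:(k - 1L))
}

#' Expected word count under the second-order Markov model
#'
#' Plug-in maximal-order estimator built from the chromosome's observed
#' trinucleotide and dinucleotide counts:
#' \deqn{\hat E(w) = \frac{\prod_{i=1}^{k-2} N_3(w_i w_{i+1} w_{i+2})}
#'                        {\prod_{i=2}^{k-2} N_2(w_i w_{i+1})}}
#' This conditions each base on the two preceding bases and so factors out
#' the effect of embedded mono- and dinucleotides. For words of length 3 the
#' estimator reduces to the observed trinucleotide count itself. A word with
#' any internal dinucleotide count of 0 gets expectation 0 (degenerate).
#'
#' @inheritParams expectedCountOrder0
#' @return numeric vector of expected counts.
#' @export
expectedCountOrder2 <- function(word, comp) {
  tri <- trinucleotideCounts(comp)
  di <- dinucleotideCounts(comp)
  vapply(word, function(w) {
    if (nchar(w) < 3L)
      stop("word must have length >= 3")
    .checkAcgt(w)
    num <- tri[.triWindows(w)]
    den <- di[.diInternal(w)]
    if (any(den == 0))
      return(0)
    exp(sum(log(num)) - sum(log(den)))
  }, numeric(1), USE.NAMES = FALSE)
}

.wordPeriods <- function(word) {
  k <- nchar(word)
  d <- seq_len(k - 1L)
  d[substring(word, 1L, k - d) == substring(word, d + 1L, k)]
}

.transitionProb <- function(tri, context, base) {
  ctx <- tri[paste0(context, c("A", "C", "G", "T"))]
  tot <- sum(ctx)
  if (tot == 0) return(NA_real_)
  unname(tri[paste0(context, base)] / tot)
}

#' Gaussian z score for word counts under the second-order model
#'
#' \code{z = (obs - E) / sigma}, with \code{E} from
#' [expectedCountOrder2()]. The default denominator is an asymptotic
#' variance for the stationary order-2 chain that accounts for
#' self-overlapping occurrences (clumping):
#' \deqn{\hat\sigma^2 = \hat E\,[\,1 + 2\sum_{d \in P(w)} \hat\pi_d
#'       - (2k - 1)\,\hat\mu\,]}
#' where \eqn{P(w)} is the set of periods of \eqn{w} (lags at which the word
#' overlaps itself), \eqn{\hat\pi_d} the estimated conditional probability
#' that an occurrence is followed by another occurrence \eqn{d} positions
#' later (a product of \eqn{d} trinucleotide transition probabilities), and
#' \eqn{\hat\mu} the per-window occurrence probability. Indicator
#' covariances are truncated at lag \eqn{k} and the parameter-estimation
#' term is neglected; both simplifications are negligible when every
#' trinucleotide count greatly exceeds the word count, as holds for octamers
#' on chromosomes of 0.5 Mb and up. \code{variance = "poisson"} selects the
#' simpler \eqn{\hat\sigma^2 = \hat E}.
#'
#' @param word character vector of words.
#' @param observed observed count(s), same length as \code{word}.
#' @param comp a [BaseComposition-class].
#' @param variance \code{"conditional"} (default) or \code{"poisson"}.
#' @return numeric z score(s); NA (with a warning) for degenerate words.
#' @export
gaussianZ <- function(word, observed, comp,
                      variance = c("conditional", "poisson")) {
  variance <- match.arg(variance)
  tri <- trinucleotideCounts(comp)
  ex <- expectedCountOrder2(word, comp)
  nWindows <- sum(tri)   # ambiguity-free 3-windows; asymptotic window count
  z <- rep(NA_real_, length(word))
  for (i in seq_along(word)) {
    if (ex[i] <= 0) next
    if (variance == "poisson") {
      s2 <- ex[i]
    } else {
      w <- word[i]
      k <- nchar(w)
      piD <- vapply(.wordPeriods(w), function(d) {
        ext <- paste0(w, substring(w, k - d + 1L, k))
        p <- 1
        for (t in (k + 1L):(k + d)) {
          pt <- .transitionProb(tri, substr(ext, t - 2L, t - 1L),
                                substr(ext, t, t))
          p <- p * pt
        }
        p
      }, numeric(1))
      mu <- ex[i] / nWindows
      s2 <- ex[i] * (1 + 2 * sum(piD) - (2 * k - 1) * mu)
      s2 <- max(s2, 0.05 * ex[i])
    }
    z[i] <- (observed[i] - ex[i]) / sqrt(s2)
  }
  if (anyNA(z))
    warning(sum(is.na(z)), " word(s) with degenerate expectation; z = NA")
  z
}

#' Classify over/under/neutral representation calls
#'
#' Zero-order model: \code{over} iff \code{obs > exp} and chi-squared >=
#' \code{chi2Min}; \code{under} iff \code{obs < exp} and chi-squared >=
#' \code{chi2Min}; otherwise \code{neutral}. Second-order model: \code{over}
#' iff \code{z >= zMin}, \code{under} iff \code{z <= -zMin}, else
#' \code{neutral}. Degenerate scores (NA statistic) are \code{neutral}.
#'
#' @param observed,expected counts (order 0; ignored for order 2 except for
#'   the direction of ties).
#' @param statistic chi-squared (order 0) or z (order 2).
#' @param modelOrder 0 or 2.
#' @param chi2Min chi-squared threshold (default 100).
#' @param zMin z threshold (default 1.96).
#' @return character vector of calls.
#' @export
classifyCalls <- function(observed, expected, statistic, modelOrder,
                          chi2Min = 100, zMin = 1.96) {
  n <- length(statistic)
  call <- rep("neutral", n)
  ok <- !is.na(statistic)
  if (modelOrder == 0) {
    call[ok & statistic >= chi2Min & observed > expected] <- "over"
    call[ok & statistic >= chi2Min & observed < expected] <- "under"
  } else if (modelOrder == 2) {
    call[ok & statistic >= zMin] <- "over"
    call[ok & statistic <= -zMin] <- "under"
  } else stop("modelOrder must be 0 or 2")
  call
}

#' Score a set of words on one chromosome under a Markov null model
#'
#' Convenience wrapper producing a tidy score table (one row per word):
#' observed count, expected count under the requested model, the statistic
#' (chi-squared for order 0, Gaussian z for order 2), the representation
#' call and a degeneracy flag.
#'
#' @param words character vector of words (equal length k).
#' @param counts a [WordCountTable-class] for that k, or a named count
#'   vector (absent words count 0).
#' @param comp a [BaseComposition-class].
#' @param modelOrder 0 or 2.
#' @param chi2Min,zMin classification thresholds.
#' @param variance variance mode for order 2 (see [gaussianZ()]).
#' @param chromosomeId id recorded in the table.
#' @return data.frame with columns chromosome_id, oligomer, model_order,
#'   observed, expected, statistic, call, degenerate.
#' @export
scoreWords <- function(words, counts, comp, modelOrder = 0,
                       chi2Min = 100, zMin = 1.96,
                       variance = "conditional",
                       chromosomeId = NA_character_) {
  if (inherits(counts, "WordCountTable")) {
    if (is.na(chromosomeId)) chromosomeId <- counts@chromosomeId
    counts <- wordCounts(counts)
  }
  obs <- counts[words]
  obs[is.na(obs)] <- 0L
  obs <- unname(as.numeric(obs))
  if (modelOrder == 0) {
    ex <- expectedCountOrder0(words, comp)
    stat <- ifelse(ex > 0, (obs - ex)^2 / ex, NA_real_)
  } else {
    ex <- expectedCountOrder2(words, comp)
    stat <- suppressWarnings(gaussianZ(words, obs, comp, variance = variance))
  }
  data.frame(
    chromosome_id = chromosomeId,
    oligomer = words,
    model_order = modelOrder,
    observed = obs,
    expected = ex,
    statistic = stat,
    call = classifyCalls(obs, ex, stat, modelOrder, chi2Min, zMin),
    degenerate = ex <= 0 | is.na(stat)
  )
}
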