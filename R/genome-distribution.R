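#' Occurrence counts of a word in fixed windows along a chromosome
#'
#' Assigns each occurrence to window \code{floor((start - 1) / windowBp)};
#' the final partial window is retained in the counts. The dispersion
#' statistic (variance/mean of counts over \emph{full} windows only) is a
#' simple clustering detector: Poisson-like uniform spread gives values near
#' 1, a dense cluster inflates it well beyond the flagging threshold of 2.
#'
#' @param positions 1-based start positions of occurrences.
#' @param lengthBp chromosome length in bp.
#' @param windowBp window size in bp (default 50000).
#' @param oligomer,chromosomeId labels recorded in the profile.
#' @return a [WindowProfile-class]; dispersion is NA (flagged by a warning)
#'   when undefined (no occurrences in full windows, or fewer than two full
#'   windows).
#' @examples
#' p <- windowProfile(c(1, 10, 49999), 100000, 50000)
#' windowCounts(p)  # 3 0
#' @export
windowProfile <- function(positions, lengthBp, windowBp = 50000,
                          oligomer = NA_character_,
                          chromosomeId = NA_character_) {
  windowBp <- as.integer(windowBp)
  if (windowBp <= 0L)
    stop("windowBp must be positive")
  nWin <- as.integer(ceiling(lengthBp / windowBp))
  idx <- floor((positions - 1) / windowBp) + 1
  counts <- tabulate(idx, nbins = nWin)
  nFull <- lengthBp %/% windowBp
  disp <- NA_real_
  if (nFull >= 2L) {
    full <- counts[seq_len(nFull)]
    if (mean(full) > 0)
      disp <- var(full) / mean(full)
  }
  if (is.na(disp))
    warning("dispersion undefined (too few full windows or no occurrences)")
  new("WindowProfile", chromosomeId = chromosomeId, oligomer = oligomer,
      windowBp = windowBp, counts = as.integer(counts), dispersion = disp)
}

#' Flag a window profile as clustered
#'
#' TRUE when the dispersion statistic exceeds the documented threshold of 2,
#' i.e. the word's occurrences are substantially more aggregated than a
#' uniform (Poisson-like) spread.
#'
#' @param profile a [WindowProfile-class].
#' @param threshold dispersion threshold (default 2).
#' @return logical(1); NA when dispersion is undefined.
#' @export
isClustered <- function(profile, threshold = 2) {
  dispersion(profile) > threshold
}
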