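#' Construct a SyntheticSpec
#'
#' Full recipe for one synthetic chromosome: i.i.d. background of the given
#' G+C content, optional planted word enrichment, and synthetic CDS
#' annotation covering a target fraction of the sequence. Defaults mirror
#' typical prokaryotic chromosomes: 86\% coding, mean gene length 900 bp.
#'
#' All randomness flows from the single \code{seed} through fixed substream
#' offsets (background: \code{seed}; annotation: \code{seed + 1}; planted
#' word i: \code{seed + 1 + i}), so a spec regenerates its chromosome
#' bit-exactly.
#'
#' @param lengthBp chromosome length in bp (0.5-6 Mb is the intended range).
#' @param gc G+C fraction in (0, 1).
#' @param planted data.frame with columns \code{word}, \code{ratePerMb} and
#'   optionally \code{frame} (1-3 to force a reading frame inside CDS; NA =
#'   unconstrained), or NULL.
#' @param codingFractionTarget percent of the chromosome to cover with CDS.
#' @param meanGeneBp mean synthetic gene length in bp.
#' @param seed master seed (integer).
#' @return a [SyntheticSpec-class].
#' @examples
#' syntheticSpec(1e6, 0.5, data.frame(word = "GAAGAAGA", ratePerMb = 60))
#' @export
syntheticSpec <- function(lengthBp, gc = 0.5, planted = NULL,
                          codingFractionTarget = 86, meanGeneBp = 900,
                          seed = 1L) {
  if (is.null(planted))
    planted <- data.frame(word = character(), ratePerMb = numeric(),
                          frame = integer())
  if (!"frame" %in% names(planted))
    planted$frame <- NA_integer_
  new("SyntheticSpec", lengthBp = as.numeric(lengthBp), gc = as.numeric(gc),
      planted = planted, codingFractionTarget = codingFractionTarget,
      meanGeneBp = meanGeneBp, seed = as.integer(seed))
}

#' Generate an i.i.d. random chromosome
#'
#' Bases drawn independently with \code{P(G) = P(C) = gc/2} and
#' \code{P(A) = P(T) = (1 - gc)/2}; reproducible for a fixed seed.
#'
#' @param lengthBp chromosome length in bp.
#' @param gc G+C fraction in (0, 1).
#' @param seed integer seed.
#' @param id record identifier (default derived from the parameters).
#' @return a [ChromosomeRecord-class] without annotation.
#' @examples
#' r <- generateRandomGenome(1e4, 0.5, seed = 7)
#' @export
generateRandomGenome <- function(lengthBp, gc, seed,
                                 id = sprintf("synth_s%d", seed)) {
  if (gc <= 0 || gc >= 1)
    stop("gc must lie strictly between 0 and 1")
  set.seed(seed)
  at <- (1 - gc) / 2
  # utf8 codes of A, C, G, T; intToUtf8 assembles the string in one pass
  codes <- c(65L, 67L, 71L, 84L)
  draw <- sample.int(4L, lengthBp, replace = TRUE,
                     prob = c(at, gc / 2, gc / 2, at))
  rec <- chromosomeRecord(id, intToUtf8(codes[draw]))
  rec@metadata$gc <- gc
  rec@metadata$seed <- seed
  rec
}

#' Plant copies of a word into a chromosome at a target rate
#'
#' Writes \code{Poisson(ratePerMb * length / 1e6)} copies of \code{word} at
#' uniformly drawn, non-overlapping positions, \emph{replacing} the
#' background bases (length and all downstream coordinates stay fixed).
#' Positions never overlap previously planted copies. With \code{frame} set
#' (and CDS annotation present), placements are restricted to positions
#' inside a CDS whose coding-orientation frame equals \code{frame}. The
#' background still contributes its own chance occurrences of the word, so
#' total counts slightly exceed the planted number.
#'
#' Planted positions are logged in
#' \code{x@metadata$planted[[word]]}.
#'
#' @param x a [ChromosomeRecord-class].
#' @param word the word to plant (A/C/G/T).
#' @param ratePerMb target planting rate per Mb.
#' @param seed integer seed.
#' @param frame optional reading frame (1-3) to force.
#' @return the modified [ChromosomeRecord-class].
#' @export
plantWords <- function(x, word, ratePerMb, seed, frame = NA_integer_) {
  .checkAcgt(word)
  len <- seqLength(x)
  k <- nchar(word)
  set.seed(seed)
  n <- rpois(1, ratePerMb * len / 1e6)
  if (n == 0)
    return(x)
  occupied <- x@metadata$plantedRanges
  if (is.null(occupied))
    occupied <- IRanges()
  starts <- integer(0)
  candidates <- NULL
  if (!is.na(frame)) {
    cds <- cdsRanges(x)
    if (length(cds) == 0L)
      stop("frame-constrained planting requires CDS annotation")
    candidates <- unlist(lapply(seq_along(cds), function(i) {
      s <- start(cds)[i]; e <- end(cds)[i]
      pos <- s:(e - k + 1L)
      pos[frameOf(pos, cds[i], k) == frame]
    }))
    if (!length(candidates))
      stop("no positions available at the requested frame")
  }
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      s <- if (is.null(candidates)) sample.int(len - k + 1L, 1L) else
        candidates[sample.int(length(candidates), 1L)]
      cand <- IRanges(s, width = k)
      if (!any(IRanges::overlapsAny(cand, occupied)) &&
          !s %in% starts &&
          (!length(starts) || all(abs(starts - s) >= k))) {
        starts <- c(starts, s)
        occupied <- c(occupied, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place word copy without overlap after 200 retries")
  }
  starts <- sort(starts)
  newSeq <- replaceAt(chromosomeSeq(x), IRanges(starts, width = k),
                      as(rep(word, length(starts)), "DNAStringSet"))
  x@sequence <- newSeq
  planted <- x@metadata$planted
  if (is.null(planted)) planted <- list()
  planted[[word]] <- sort(c(planted[[word]], starts))
  x@metadata$planted <- planted
  x@metadata$plantedRanges <- occupied
  validObject(x)
  x
}

#' Generate synthetic CDS annotation at a target coding fraction
#'
#' Lays down non-overlapping gene intervals with exponential-like lengths
#' (mean \code{meanGeneBp}, rounded to multiples of 3, minimum 30 bp) on
#' alternating strands, separated by gaps sized so the union covers
#' \code{codingFractionTarget} percent of the chromosome to within 2
#' points.
#'
#' @param x a [ChromosomeRecord-class].
#' @param codingFractionTarget target coverage, percent (must be < 100).
#' @param meanGeneBp mean gene length in bp.
#' @param seed integer seed.
#' @return a \code{GRanges} of CDS intervals.
#' @export
generateAnnotation <- function(x, codingFractionTarget = 86,
                               meanGeneBp = 900, seed = 1L) {
  if (codingFractionTarget >= 100)
    stop("codingFractionTarget must be below 100")
  len <- seqLength(x)
  if (codingFractionTarget <= 0)
    return(GRanges())
  set.seed(seed)
  targetBp <- codingFractionTarget / 100 * len
  nEst <- ceiling(targetBp / meanGeneBp * 1.6) + 10L
  lens <- 3L * pmax(10L, round(rexp(nEst, 1 / meanGeneBp) / 3))
  cum <- cumsum(lens)
  nGenes <- which(cum >= targetBp)[1]
  if (is.na(nGenes)) nGenes <- nEst
  lens <- lens[seq_len(nGenes)]
  # trim the last gene (multiple of 3, >= 30 bp) so ungapped total ~ target
  excess <- sum(lens) - targetBp
  lens[nGenes] <- max(30L, lens[nGenes] - 3L * floor(excess / 3))
  totalGap <- len - sum(lens)
  if (totalGap < 0) {
    lens <- lens[cumsum(lens) <= len]
    nGenes <- length(lens)
    totalGap <- len - sum(lens)
  }
  gapDraw <- rexp(nGenes + 1L)
  gaps <- floor(gapDraw / sum(gapDraw) * totalGap)
  gaps[nGenes + 1L] <- gaps[nGenes + 1L] + (totalGap - sum(gaps))
  starts <- cumsum(gaps[seq_len(nGenes)]) +
    c(0, cumsum(lens[-nGenes])) + 1L
  gr <- GRanges(seqnames = chromosomeId(x),
                ranges = IRanges(starts, width = lens),
                strand = rep(c("+", "-"), length.out = nGenes))
  gr
}

#' Generate a complete synthetic chromosome from a SyntheticSpec
#'
#' Background (substream \code{seed}), then annotation (substream
#' \code{seed + 1}), then each planted word i (substream
#' \code{seed + 1 + i}). The returned record carries the spec and the
#' planted positions in its metadata.
#'
#' @param spec a [SyntheticSpec-class].
#' @param id record identifier (default derived from the seed).
#' @return a [ChromosomeRecord-class].
#' @examples
#' sp <- syntheticSpec(5e4, 0.5, seed = 3)
#' rec <- generateSyntheticChromosome(sp)
#' @export
generateSyntheticChromosome <- function(spec,
                                        id = sprintf("synth_s%d", spec@seed)) {
  rec <- generateRandomGenome(spec@lengthBp, spec@gc, spec@seed, id = id)
  if (spec@codingFractionTarget > 0) {
    cds <- generateAnnotation(rec, spec@codingFractionTarget,
                              spec@meanGeneBp, seed = spec@seed + 1L)
    rec <- chromosomeRecord(id, chromosomeSeq(rec), cds = cds,
                            metadata = rec@metadata)
  }
  pl <- spec@planted
  for (i in seq_len(nrow(pl)))
    rec <- plantWords(rec, pl$word[i], pl$ratePerMb[i],
                      seed = spec@seed + 1L + i, frame = pl$frame[i])
  rec@metadata$spec <- spec
  rec
}

#' Write a synthetic chromosome as FASTA + GFF3 + provenance sidecar
#'
#' Emits \code{<prefix>.fasta}, \code{<prefix>.gff3} and a plain-text
#' key=value sidecar \code{<prefix>.provenance.txt} recording the full
#' generation recipe, so any fixture can be regenerated bit-exactly.
#'
#' @param record a [ChromosomeRecord-class] from
#'   [generateSyntheticChromosome()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix (default the record id).
#' @return character vector of the paths written, invisibly.
#' @export
writeSyntheticFixture <- function(record, dir,
                                  prefix = chromosomeId(record)) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  prov <- file.path(dir, paste0(prefix, ".provenance.txt"))
  writeChromosomeFasta(record, fa)
  writeCdsGff(record, gff)
  spec <- record@metadata$spec
  lines <- c(
    paste0("id=", chromosomeId(record)),
    paste0("length_bp=", seqLength(record))
  )
  if (!is.null(spec)) {
    lines <- c(lines,
      paste0("gc=", spec@gc),
      paste0("coding_fraction_target=", spec@codingFractionTarget),
      paste0("mean_gene_bp=", spec@meanGeneBp),
      paste0("seed=", spec@seed))
    for (i in seq_len(nrow(spec@planted)))
      lines <- c(lines, sprintf("planted=%s:%g:%s",
                                spec@planted$word[i],
                                spec@planted$ratePerMb[i],
                                spec@planted$frame[i]))
  }
  writeLines(lines, prov)
  invisible(c(fa, gff, prov))
}
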