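#' Construct a SurveyConfig
#'
#' Defaults are the survey's canonical thresholds (31 copies/Mb,
#' chi-squared >= 100, |z| >= 1.96, 50-kb windows, words of 8-14 bp).
#'
#' @param kRange integer vector of word lengths within 8-14.
#' @param minCpm,chi2Min,zMin thresholds.
#' @param indexMode \code{"subtract"} or \code{"exclude"}.
#' @param bothStrands pool reverse-complement counts.
#' @param windowBp positional-profile window size.
#' @param varianceMode \code{"conditional"} or \code{"poisson"}.
#' @param seed integer seed for any stochastic step.
#' @param fastaPath,gffPath,outDir input/output paths.
#' @return a [SurveyConfig-class].
#' @export
surveyConfig <- function(kRange = 8:14, minCpm = 31, chi2Min = 100,
                         zMin = 1.96, indexMode = "subtract",
                         bothStrands = FALSE, windowBp = 50000L,
                         varianceMode = "conditional", seed = 1L,
                         fastaPath = "", gffPath = "", outDir = "") {
  new("SurveyConfig", kRange = as.integer(kRange), minCpm = minCpm,
      chi2Min = chi2Min, zMin = zMin, indexMode = indexMode,
      bothStrands = bothStrands, windowBp = as.integer(windowBp),
      varianceMode = varianceMode, seed = as.integer(seed),
      fastaPath = fastaPath, gffPath = gffPath, outDir = outDir)
}

#' Read a SurveyConfig from a plain-text key=value file
#'
#' Keys mirror [surveyConfig()] arguments (snake_case also accepted);
#' \code{kRange} accepts \code{"8:14"} or comma-separated values. Lines
#' starting with \code{#} are ignored.
#'
#' @param path path to the config file.
#' @return a [SurveyConfig-class].
#' @export
readConfigFile <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  # snake_case -> camelCase
  keys <- gsub("_(\\w)", "\\U\\1", keys, perl = TRUE)
  args <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    args[[keys[i]]] <- switch(keys[i],
      kRange = if (grepl(":", v))
        do.call(seq, as.list(as.integer(strsplit(v, ":")[[1]])))
      else as.integer(strsplit(v, ",")[[1]]),
      minCpm = , chi2Min = , zMin = as.numeric(v),
      windowBp = , seed = as.integer(v),
      bothStrands = as.logical(v),
      v)
  }
  do.call(surveyConfig, args)
}

# rolling polynomial hash of the canonicalised config text; a provenance
# label for report headers, not cryptography. outDir is excluded: where the
# reports land cannot affect their content.
.configHash <- function(config) {
  slots <- setdiff(slotNames(config), "outDir")
  txt <- paste(vapply(sort(slots), function(s)
    paste0(s, "=", paste(format(slot(config, s)), collapse = ",")),
    character(1)), collapse = ";")
  h <- 0
  for (b in utf8ToInt(txt))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.writeReport <- function(df, path, config) {
  header <- c(
    paste0("# oligosurvey version: ",
           as.character(utils::packageVersion("oligosurvey"))),
    paste0("# config_hash: ", .configHash(config)),
    paste0("# seed: ", config@seed),
    sprintf("# thresholds: min_cpm=%g chi2_min=%g z_min=%g index_mode=%s",
            config@minCpm, config@chi2Min, config@zMin, config@indexMode))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full survey pipeline and write report files
#'
#' Executes scan, candidate scoring (512 homopurine/homopyrimidine
#' octamers under both null models), cohort summary, coding localization
#' and positional profiles, writing a TSV per stage into
#' \code{config@outDir}:
#' \code{scan.tsv}, \code{scores.tsv}, \code{summary.tsv},
#' \code{coding.tsv}, \code{windows.tsv}, plus \code{run.log}. Every TSV
#' carries a header with the package version, a config hash and the seed;
#' identical config + inputs reproduce byte-identical TSVs. Localization
#' and profiles are computed for candidates that qualified (zero-order) in
#' at least one chromosome. If any stage fails, a \code{FAILED} sentinel
#' file is written before the error propagates.
#'
#' @param config a [SurveyConfig-class].
#' @param cohort optional list of [ChromosomeRecord-class] objects; when
#'   NULL, \code{config@fastaPath} (and optional \code{gffPath}) are read.
#' @param candidates candidate word set (default
#'   [enumerateHomoOctamers()]).
#' @return the cohort summary data.frame, invisibly.
#' @export
runSurvey <- function(config, cohort = NULL,
                      candidates = enumerateHomoOctamers()) {
  if (is.null(cohort)) {
    if (!nzchar(config@fastaPath) || !file.exists(config@fastaPath))
      stop("input FASTA missing: ", config@fastaPath)
    if (nzchar(config@gffPath) && !file.exists(config@gffPath))
      stop("input GFF missing: ", config@gffPath)
    cohort <- readChromosomes(config@fastaPath,
                              if (nzchar(config@gffPath)) config@gffPath)
  }
  outDir <- config@outDir
  if (!nzchar(outDir))
    stop("config@outDir is not set")
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  logLines <- character()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    logLines <<- c(logLines, sprintf("%s: %.2f s", name,
                                     proc.time()[["elapsed"]] - t0))
    res
  }
  tryCatch({
    scanTab <- stage("scan", do.call(rbind, lapply(cohort, function(rec)
      scanChromosome(rec, config@kRange, config@minCpm, config@chi2Min,
                     config@bothStrands))))
    rownames(scanTab) <- NULL
    .writeReport(scanTab, file.path(outDir, "scan.tsv"), config)
    logLines <- c(logLines, sprintf("scan hits: %d", nrow(scanTab)))

    scores <- stage("score-candidates", do.call(rbind, lapply(cohort,
      function(rec) {
        comp <- baseComposition(rec)
        do.call(rbind, lapply(split(candidates, nchar(candidates)),
          function(words) {
            wt <- countWords(rec, nchar(words[1]))
            rbind(
              scoreWords(words, wt, comp, modelOrder = 0,
                         chi2Min = config@chi2Min),
              scoreWords(words, wt, comp, modelOrder = 2,
                         zMin = config@zMin, variance = config@varianceMode))
          }))
      })))
    rownames(scores) <- NULL
    .writeReport(scores, file.path(outDir, "scores.tsv"), config)

    summary <- stage("summarise",
      summariseCohort(cohort, candidates, config@minCpm, config@chi2Min,
                      config@zMin, config@indexMode, config@varianceMode,
                      config@bothStrands))
    .writeReport(summary, file.path(outDir, "summary.tsv"), config)

    hits <- summary$oligomer[summary$n_over_0 > 0]
    coding <- list(); windows <- list()
    stage("localize+profile", for (rec in cohort) {
      for (w in hits) {
        pos <- wordPositions(rec, w)
        loc <- locateInCoding(pos, nchar(w), cdsRanges(rec),
                              oligomer = w,
                              chromosomeId = chromosomeId(rec))
        fb <- if (loc@nCoding > 0) frameBiasTest(loc)$statistic else NA_real_
        coding[[length(coding) + 1L]] <- data.frame(
          chromosome_id = chromosomeId(rec), oligomer = w,
          n_total = loc@nTotal, n_coding = loc@nCoding,
          pct_coding = loc@pctCoding,
          frame1 = loc@frameCounts[1], frame2 = loc@frameCounts[2],
          frame3 = loc@frameCounts[3], frame_chi2 = fb)
        prof <- suppressWarnings(
          windowProfile(pos, seqLength(rec), config@windowBp,
                        oligomer = w, chromosomeId = chromosomeId(rec)))
        windows[[length(windows) + 1L]] <- data.frame(
          chromosome_id = chromosomeId(rec), oligomer = w,
          n_windows = length(windowCounts(prof)),
          total = sum(windowCounts(prof)),
          dispersion = dispersion(prof),
          clustered = isClustered(prof))
      }
    })
    codingTab <- if (length(coding)) do.call(rbind, coding) else
      data.frame(chromosome_id = character(), oligomer = character(),
                 n_total = integer(), n_coding = integer(),
                 pct_coding = numeric(), frame1 = integer(),
                 frame2 = integer(), frame3 = integer(),
                 frame_chi2 = numeric())
    rownames(codingTab) <- NULL
    .writeReport(codingTab, file.path(outDir, "coding.tsv"), config)
    windowTab <- if (length(windows)) do.call(rbind, windows) else
      data.frame(chromosome_id = character(), oligomer = character(),
                 n_windows = integer(), total = integer(),
                 dispersion = numeric(), clustered = logical())
    rownames(windowTab) <- NULL
    .writeReport(windowTab, file.path(outDir, "windows.tsv"), config)

    writeLines(c(sprintf("chromosomes: %d", length(cohort)), logLines),
               file.path(outDir, "run.log"))
    invisible(summary)
  }, error = function(e) {
    writeLines(conditionMessage(e), file.path(outDir, "FAILED"))
    stop(e)
  })
}
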