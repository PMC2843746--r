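IUPAC_DNA <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "-")

#' Read chromosome sequences (and optionally CDS annotation) from FASTA/GFF3
#'
#' Reads a (multi-)FASTA file into a list of [ChromosomeRecord-class] objects,
#' in file order. Sequences are uppercased and U is mapped to T. When a GFF3
#' path is given, CDS features are attached to the record whose id matches
#' their seqid. Letters outside the IUPAC nucleotide alphabet are replaced by
#' N; if they exceed 10\% of the residues the file is rejected as
#' non-nucleotide.
#'
#' @param fastaPath path to a FASTA file.
#' @param gffPath optional path to a GFF3 file with CDS features.
#' @return named list of \code{ChromosomeRecord} objects, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgtACGT"), fa)
#' readChromosomes(fa)[["x"]]
#' @export
readChromosomes <- function(fastaPath, gffPath = NULL) {
  raw <- Biostrings::readBStringSet(fastaPath)
  if (length(raw) == 0L)
    stop("no sequences in ", fastaPath)
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  letters <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  badFrac <- mean(!letters %in% IUPAC_DNA)
  if (badFrac > 0.10)
    stop("not nucleotide FASTA: ", round(100 * badFrac, 1),
         "% of residues outside the IUPAC alphabet")
  # residual oddities (<= 10%) are masked as N
  seqs <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[!ch %in% IUPAC_DNA] <- "N"
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
  records <- lapply(seq_along(ids), function(i) {
    cds <- if (!is.null(gffPath)) readCdsAnnotation(gffPath, ids[i]) else NULL
    chromosomeRecord(ids[i], seqs[i], cds = cds)
  })
  names(records) <- ids
  records
}

#' Read CDS intervals for one chromosome from a GFF3 file
#'
#' Imports the file through \pkg{rtracklayer} and keeps rows of type
#' \code{CDS} whose seqid matches \code{chromosomeId}. Coordinates stay in
#' GFF3's native 1-based closed convention, which is also the package's
#' internal convention.
#'
#' @param path path to a GFF3 file.
#' @param chromosomeId seqid to select.
#' @return a \code{GRanges} of CDS intervals (strand \code{+}/\code{-}).
#' @export
readCdsAnnotation <- function(path, chromosomeId) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(mcols(gr)$type) == "CDS" &
             as.character(seqnames(gr)) == chromosomeId]
  str <- as.character(strand(gr))
  if (any(!str %in% c("+", "-")))
    stop("unknown strand symbol in CDS rows: ",
         paste(unique(str[!str %in% c("+", "-")]), collapse = ", "))
  gr <- GRanges(seqnames = as.character(seqnames(gr)),
                ranges = IRanges(start(gr), end(gr)),
                strand = str)
  unname(gr)
}

#' Read CDS intervals from a GenBank flat file's feature table
#'
#' Minimal extraction of CDS locations from a GenBank record: handles plain
#' \code{a..b} spans, \code{complement(...)} and compound
#' \code{join(...)}/\code{order(...)} locations. Compound locations are
#' decomposed into their parts, each returned as an independent interval;
#' partial markers (\code{<}, \code{>}) are ignored.
#'
#' @param path path to a GenBank flat file.
#' @return a \code{GRanges} of CDS intervals.
#' @export
readCdsGenbank <- function(path) {
  lines <- readLines(path)
  featStart <- grep("^FEATURES", lines)
  if (!length(featStart))
    stop("no FEATURES table in ", path)
  featEnd <- grep("^(ORIGIN|CONTIG|//)", lines)
  featEnd <- if (length(featEnd)) min(featEnd[featEnd > featStart[1]]) else
    length(lines) + 1L
  feat <- lines[(featStart[1] + 1L):(featEnd - 1L)]
  # a feature key sits at column 6; continuation lines are deeper-indented
  keyRows <- grep("^ {5}\\S", feat)
  cdsRows <- keyRows[grepl("^ {5}CDS\\s", feat[keyRows])]
  starts <- integer(); ends <- integer(); strands <- character()
  for (row in cdsRows) {
    loc <- sub("^ {5}CDS\\s+", "", feat[row])
    nxt <- row + 1L
    # location strings may wrap until the first qualifier line ("/xxx")
    while (nxt <= length(feat) && !grepl("^ {5}\\S", feat[nxt]) &&
           !grepl("^\\s+/", feat[nxt])) {
      loc <- paste0(loc, trimws(feat[nxt]))
      nxt <- nxt + 1L
    }
    loc <- gsub("[<>[:space:]]", "", loc)
    strandHere <- if (grepl("complement\\(", loc)) "-" else "+"
    loc <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
    for (part in strsplit(loc, ",")[[1]]) {
      ab <- as.integer(strsplit(part, "\\.\\.")[[1]])
      if (any(is.na(ab)))
        stop("unparseable CDS location part: ", part)
      if (length(ab) == 1L) ab <- c(ab, ab)
      if (ab[2] < ab[1])
        stop("CDS end precedes start: ", part)
      starts <- c(starts, ab[1]); ends <- c(ends, ab[2])
      strands <- c(strands, strandHere)
    }
  }
  GRanges(seqnames = "genbank",
          ranges = IRanges(starts, ends), strand = strands)
}

#' Fraction of a chromosome covered by CDS
#'
#' Percentage of positions covered by the union of the record's CDS intervals
#' (overlaps counted once), in \code{[0, 100]}.
#'
#' @param x a [ChromosomeRecord-class].
#' @return numeric(1) percent coverage.
#' @examples
#' r <- chromosomeRecord("x", strrep("A", 1000),
#'        cds = GenomicRanges::GRanges("x", IRanges::IRanges(1, 860), "+"))
#' codingFraction(r)  # 86
#' @export
setMethod("codingFraction", "ChromosomeRecord", function(x) {
  len <- seqLength(x)
  if (len == 0L)
    stop("zero-length chromosome")
  if (length(cdsRanges(x)) == 0L)
    return(0)
  100 * sum(width(reduce(cdsRanges(x), ignore.strand = TRUE))) / len
})

#' Write ChromosomeRecords to FASTA / their CDS annotation to GFF3
#'
#' \code{writeChromosomeFasta} writes the sequences of a list of records as a
#' multi-FASTA file. \code{writeCdsGff} writes one record's CDS intervals as
#' GFF3 \code{CDS} rows (via \pkg{rtracklayer}); the export's timestamp
#' comment is removed so identical inputs produce byte-identical files.
#'
#' @param records list of [ChromosomeRecord-class] objects.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeChromosomeFasta <- function(records, path) {
  if (inherits(records, "ChromosomeRecord"))
    records <- list(records)
  set <- DNAStringSet(lapply(records, chromosomeSeq))
  names(set) <- vapply(records, chromosomeId, character(1))
  writeXStringSet(set, path)
  invisible(path)
}

#' @rdname writeChromosomeFasta
#' @param record a single [ChromosomeRecord-class].
#' @export
writeCdsGff <- function(record, path) {
  gr <- cdsRanges(record)
  out <- GRanges(seqnames = chromosomeId(record),
                 ranges = IRanges(start(gr), end(gr)),
                 strand = strand(gr))
  mcols(out)$source <- "oligosurvey"
  mcols(out)$type <- "CDS"
  mcols(out)$phase <- 0L
  rtracklayer::export(out, path, format = "gff3")
  lines <- readLines(path)
  writeLines(lines[!grepl("^##date", lines)], path)
  invisible(path)
}
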