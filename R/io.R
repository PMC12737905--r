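## Plain-text readers and writers for the pipeline's tables. All files are
## 1-based TSV/CSV except the BED-like composition segments, which use
## 0-based half-open coordinates.

#' Write / read AB sites as TSV
#'
#' Columns: `chrom`, `pos` (1-based), `aAllele`, `bAllele`.
#'
#' @param x data.frame of AB sites (as from [selectABSites()]) or a
#'   [ParentalPair-class].
#' @param file path.
#' @return `readABSites` returns the data.frame.
#' @export
writeABSites <- function(x, file) {
  if (is(x, "ParentalPair")) {
    gr <- abSites(x)
    x <- data.frame(chrom = as.character(seqnames(gr)),
                    pos = GenomicRanges::start(gr),
                    aAllele = gr$aAllele, bAllele = gr$bAllele)
  }
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeABSites
#' @export
readABSites <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}

#' Write / read a composition map as BED-like TSV
#'
#' Columns: `chrom`, `start` (0-based), `end` (half-open), `aCopies`,
#' `bCopies` — the only 0-based file in the toolkit. A header line
#' `#chromLengths=` records the set lengths.
#'
#' @param map a [CompositionMap-class].
#' @param file path.
#' @return `readCompositionMap` returns a [CompositionMap-class].
#' @export
writeCompositionMap <- function(map, file) {
  gr <- segments(map)
  sl <- seqlengths(gr)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("#chromLengths=",
                    paste(names(sl), sl, sep = ":", collapse = ",")), con)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   aCopies = gr$aCopies, bCopies = gr$bCopies)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeCompositionMap
#' @export
readCompositionMap <- function(file) {
  hdr <- readLines(file, n = 1L)
  if (!startsWith(hdr, "#chromLengths="))
    stopf("missing #chromLengths= header in %s", file)
  parts <- strsplit(strsplit(sub("^#chromLengths=", "", hdr), ",")[[1]], ":")
  sl <- setNames(as.integer(vapply(parts, `[`, "", 2L)),
                 vapply(parts, `[`, "", 1L))
  df <- read.delim(file, skip = 1L, stringsAsFactors = FALSE)
  compositionMap(df$chrom, df$start + 1L, df$end, df$aCopies, df$bCopies, sl)
}

#' Read a per-sample allele-count track
#'
#' TSV with columns `chrom`, `pos`, `aCount`, `bCount` (optionally
#' `sample`).
#'
#' @param file path.
#' @return data.frame.
#' @export
readAlleleCounts <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}

#' Read a raw tetraploid-scale genotype-call table
#'
#' CSV in the layout of a raw call spreadsheet: a header of sample ids
#' (first columns `marker`, `chromB`, `posB`), a second row with marker id
#' `ROLE` carrying each sample's control role, then one row per marker with
#' integer calls 0-4 (empty = missing).
#'
#' @param file path.
#' @return a [DosageCalls-class].
#' @export
readRawCalls <- function(file) {
  raw <- read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  roleRow <- which(raw$marker == "ROLE")
  if (length(roleRow) != 1L) stopf("expected one ROLE row in %s", file)
  sampleCols <- setdiff(colnames(raw), c("marker", "chromB", "posB"))
  roles <- setNames(as.character(raw[roleRow, sampleCols]), sampleCols)
  dat <- raw[-roleRow, , drop = FALSE]
  m <- as.matrix(dat[, sampleCols, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- dat$marker
  dosageCalls(m, roles,
              chromB = if ("chromB" %in% colnames(dat)) dat$chromB else NA,
              posB = if ("posB" %in% colnames(dat))
                suppressWarnings(as.integer(dat$posB)) else NA)
}

#' Read a phenotype table
#'
#' CSV mirroring a greenhouse phenotype spreadsheet, with at least
#' `plantId`, `population`, `year`, `selectionClass` and `seedWeight`
#' columns; extra trait columns (pod metrics, SPAD, flower colour) pass
#' through.
#'
#' @param file path.
#' @return data.frame.
#' @export
readPhenotypes <- function(file) {
  read.csv(file, stringsAsFactors = FALSE)
}
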