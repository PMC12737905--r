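## Discovery of subgenome-diagnostic AB sites from parental fragment
## consensus and whole-genome read pileups.

#' Consensus allele of a pileup
#'
#' Returns the allele accounting for at least `minFrac` of the counts at one
#' position and source, or `NA` when no allele reaches that fraction (or the
#' pileup is empty).
#'
#' @param counts named numeric vector (allele -> count).
#' @param minFrac required consensus fraction, in (0.5, 1].
#' @return single allele character or `NA_character_`.
#' @examples
#' consensusAllele(c(T = 98, C = 2), 0.95)  # "T"
#' consensusAllele(c(T = 94, C = 6), 0.95)  # NA
#' @export
consensusAllele <- function(counts, minFrac = 0.95) {
  if (minFrac <= 0.5 || minFrac > 1)
    stopf("minFrac must be in (0.5, 1]")
  total <- sum(counts)
  if (length(counts) == 0L || total == 0) return(NA_character_)
  i <- which.max(counts)
  if (counts[[i]] / total >= minFrac) names(counts)[i] else NA_character_
}

## plain-majority consensus used for the low-depth fragment sources
majorityAllele <- function(counts) {
  total <- sum(counts)
  if (length(counts) == 0L || total == 0) return(NA_character_)
  i <- which.max(counts)
  if (counts[[i]] / total > 0.5) names(counts)[i] else NA_character_
}

PILEUP_SOURCES <- c("fragA", "fragB", "readsA", "readsB")

#' Select subgenome-diagnostic AB sites from pileups
#'
#' Filters candidate variant positions to those diagnostic for subgenome
#' origin, applying four conditions per position: (1) the genome-fragment
#' consensus and the read consensus agree within each subgenome; (2) a read
#' consensus at fraction >= `minFrac` exists for both subgenomes; (3) the
#' fragment pileup has depth >= `minFragDepth` for both subgenomes; and
#' (4) the A- and B-subgenome consensus alleles differ. Fragment consensus
#' is a plain majority.
#'
#' @param pileups data.frame with columns `chrom`, `pos` (1-based), `source`
#'   (one of `fragA`, `fragB`, `readsA`, `readsB`), `allele`, `count`,
#'   sorted by (`chrom`, `pos`).
#' @param minFrac read-consensus fraction (default 0.95, i.e. "at least 95%
#'   of mapped reads").
#' @param minFragDepth minimum fragment depth per subgenome (default 1).
#' @return data.frame of retained sites with columns `chrom`, `pos`,
#'   `aAllele`, `bAllele`, in input order.
#' @export
selectABSites <- function(pileups, minFrac = 0.95, minFragDepth = 1L) {
  need <- c("chrom", "pos", "source", "allele", "count")
  if (!all(need %in% colnames(pileups)))
    stopf("pileups needs columns: %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(pileups$source), PILEUP_SOURCES)
  if (length(bad)) stopf("unknown pileup source(s): %s", paste(bad, collapse = ", "))
  key <- paste(pileups$chrom, pileups$pos)
  uk <- unique(key)
  ord <- match(key, uk)
  if (is.unsorted(ord))
    stopf("ordering error: pileups must be sorted by (chrom, pos)")
  posOrd <- unname(tapply(pileups$pos, factor(pileups$chrom,
                                              levels = unique(pileups$chrom)),
                          function(p) is.unsorted(unique(p))))
  if (any(posOrd))
    stopf("ordering error: positions must be non-decreasing within each chromosome")

  keep <- logical(length(uk))
  aAll <- bAll <- character(length(uk))
  for (i in seq_along(uk)) {
    p <- pileups[ord == i, ]
    cnt <- function(src) {
      x <- p[p$source == src, ]
      setNames(x$count, x$allele)
    }
    fragA <- cnt("fragA"); fragB <- cnt("fragB")
    readsA <- cnt("readsA"); readsB <- cnt("readsB")
    consA <- consensusAllele(readsA, minFrac)        # condition 2
    consB <- consensusAllele(readsB, minFrac)
    if (is.na(consA) || is.na(consB)) next
    if (sum(fragA) < minFragDepth || sum(fragB) < minFragDepth) next  # condition 3
    fA <- majorityAllele(fragA); fB <- majorityAllele(fragB)
    if (is.na(fA) || is.na(fB) || fA != consA || fB != consB) next    # condition 1
    if (consA == consB) next                                          # condition 4
    keep[i] <- TRUE
    aAll[i] <- consA; bAll[i] <- consB
  }
  first <- !duplicated(key)
  out <- data.frame(chrom = pileups$chrom[first], pos = pileups$pos[first],
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out$aAllele <- aAll[keep]
  out$bAllele <- bAll[keep]
  rownames(out) <- NULL
  out
}

#' Noise-free pileups from a simulated parental pair
#'
#' Generates the ideal pileup evidence a [ParentalPair-class] would produce:
#' each AB site yields fragment and read pileups supporting only the true
#' parental alleles. Useful as the oracle input for which
#' [selectABSites()] must return exactly the simulated sites.
#'
#' @param parents a [ParentalPair-class].
#' @param fragDepth,readDepth depths for the fragment and read sources.
#' @return a pileup data.frame as accepted by [selectABSites()].
#' @export
idealPileups <- function(parents, fragDepth = 2L, readDepth = 50L) {
  gr <- abSites(parents)
  if (!length(gr))
    return(data.frame(chrom = character(), pos = integer(), source = character(),
                      allele = character(), count = integer()))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   pos = GenomicRanges::start(gr),
                   aAllele = gr$aAllele, bAllele = gr$bAllele,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), ]
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    data.frame(chrom = df$chrom[i], pos = df$pos[i],
               source = PILEUP_SOURCES,
               allele = c(df$aAllele[i], df$bAllele[i],
                          df$aAllele[i], df$bAllele[i]),
               count = c(fragDepth, fragDepth, readDepth, readDepth),
               stringsAsFactors = FALSE)
  }))
}
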