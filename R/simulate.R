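## Forward simulator of a selfing neoallotetraploid: parental diagnostic
## sites, homoeologous-exchange lineages under a tetrasomic-segregation
## Markov model, sequencing read counts, array signals and phenotypes.

#' Simulate a pair of diverged parental subgenomes
#'
#' Draws subgenome-diagnostic AB sites along each chromosome set: positions
#' where the two parental consensus alleles differ. Sites occur
#' independently per bp at rate `siteRate`; alleles are random distinct
#' bases.
#'
#' @param nChrom number of chromosome sets (named `B01`, `B02`, ...).
#' @param chromLen chromosome-set length in bp (scalar or per-set vector).
#' @param siteRate per-bp probability that a position is diagnostic.
#' @param seed integer seed; identical seeds give identical objects.
#' @return a [ParentalPair-class].
#' @examples
#' pp <- simulateParents(2, 1e5, 0.005, seed = 1)
#' pp
#' @export
simulateParents <- function(nChrom, chromLen, siteRate, seed) {
  if (nChrom < 1) stopf("invalid parameter: nChrom must be >= 1")
  if (any(chromLen <= 0)) stopf("invalid parameter: chromLen must be positive")
  if (siteRate < 0 || siteRate > 1)
    stopf("invalid parameter: siteRate must be in [0, 1]")
  lens <- as.integer(rep_len(chromLen, nChrom))
  names(lens) <- sprintf("B%02d", seq_len(nChrom))
  bases <- c("A", "C", "G", "T")
  withSeed(seed, {
    sites <- lapply(names(lens), function(chr) {
      n <- rbinom(1L, lens[[chr]], siteRate)
      if (n == 0L) return(NULL)
      pos <- sort(sample.int(lens[[chr]], n))
      ai <- sample.int(4L, n, replace = TRUE)
      bi <- ((ai - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
      data.frame(chrom = chr, pos = pos, aAllele = bases[ai], bAllele = bases[bi])
    })
    sites <- do.call(rbind, sites)
    gr <- if (is.null(sites)) {
      GRanges(seqlengths = lens, aAllele = character(), bAllele = character())
    } else {
      GRanges(sites$chrom, IRanges(sites$pos, width = 1L),
              aAllele = sites$aAllele, bAllele = sites$bAllele,
              seqlengths = lens)
    }
    new("ParentalPair", abSites = gr, seed = as.integer(seed))
  })
}

#' Gamete A-dosage of one tetraploid segment
#'
#' Draws the number of A-subgenome copies (0-2) transmitted through one
#' gamete by a segment with `aCopies` A copies among its four chromosomes.
#' Under disomic (bivalent, homologous) pairing, balanced and fixed segments
#' transmit exactly half their A copies; under tetrasomic (multivalent)
#' pairing the gamete receives 2 of the 4 copies drawn uniformly without
#' replacement, i.e. a hypergeometric draw.
#'
#' @param aCopies integer in 0..4 (the segment's B count is `4 - aCopies`).
#' @param mode `"disomic"` or `"tetrasomic"`.
#' @param n number of independent gametes to draw.
#' @return integer vector of length `n` with values in 0..2.
#' @examples
#' set.seed(1)
#' table(gameteSegmentDosage(3, "tetrasomic", n = 1000)) / 1000  # ~ 1/2, 1/2
#' @export
gameteSegmentDosage <- function(aCopies, mode = c("tetrasomic", "disomic"), n = 1L) {
  mode <- match.arg(mode)
  if (length(aCopies) != 1L || is.na(aCopies) || !aCopies %in% 0:4)
    stopf("aCopies must be a single integer in 0..4 (total copies = 4)")
  if (mode == "disomic") {
    if (aCopies %% 2L != 0L)
      stopf("invalid state: disomic segregation is undefined for odd dosage %d; unbalanced segments segregate tetrasomically", aCopies)
    return(rep(as.integer(aCopies / 2L), n))
  }
  as.integer(rhyper(n, m = aCopies, n = 4L - aCopies, k = 2L))
}

## One selfing step on the internal segment frame. Each of the two meioses
## decides multivalent pairing of balanced segments independently with
## probability pHE; dosage 1/3 always segregates tetrasomically; dosage 0/4
## and aneuploid (total != 4) segments are transmitted unchanged.
selfStep <- function(df, pHE, breakpointRate, chromLengths,
                     nondisjunctionProb = 0) {
  if (breakpointRate > 0) {
    for (chr in names(chromLengths)) {
      k <- rpois(1L, breakpointRate)
      if (k == 0L) next
      len <- chromLengths[[chr]]
      if (len < 2L) next
      for (p in sample.int(len - 1L, min(k, len - 1L))) {
        hit <- which(df$chrom == chr & df$start <= p & df$end > p)
        if (length(hit)) {
          seg <- df[hit, ]
          left <- seg; left$end <- p
          right <- seg; right$start <- p + 1L
          df <- rbind(df[-hit, ], left, right)
        }
      }
    }
    df <- df[order(df$chrom, df$start), ]
  }
  eu <- (df$a + df$b) == 4L
  if (any(eu)) {
    childA <- selfDosageKernel(df$a[eu], pHE)
    df$a[eu] <- childA
    df$b[eu] <- 4L - childA
  }
  if (nondisjunctionProb > 0) {
    for (chr in names(chromLengths)) {
      if (runif(1) < nondisjunctionProb) {
        i <- df$chrom == chr & (df$a + df$b) == 4L
        extraA <- runif(sum(i)) < df$a[i] / 4
        df$a[i] <- df$a[i] + as.integer(extraA)
        df$b[i] <- df$b[i] + as.integer(!extraA)
      }
    }
  }
  mergeFrameRuns(df)
}

## merge adjacent segments with identical state so frames stay small
mergeFrameRuns <- function(df) {
  if (nrow(df) < 2L) return(df)
  df <- df[order(df$chrom, df$start), ]
  same <- c(FALSE, df$chrom[-1] == df$chrom[-nrow(df)] &
                   df$a[-1] == df$a[-nrow(df)] & df$b[-1] == df$b[-nrow(df)])
  grp <- cumsum(!same)
  out <- df[!same, ]
  out$end <- df$end[c(which(diff(grp) != 0L), nrow(df))]
  rownames(out) <- NULL
  out
}

#' Simulate a selfing lineage under homoeologous exchange
#'
#' Advances one individual per generation by single-seed descent. Each
#' generation, new segment breakpoints arise at rate `breakpointRate` per
#' chromosome set at uniform positions; each segment then segregates through
#' two independent gametes: fixed states (dosage 0 or 4) are transmitted
#' unchanged (absorbing), unbalanced states (dosage 1 or 3) segregate
#' tetrasomically, and the balanced state (dosage 2) pairs multivalently
#' with probability `pHE` per meiosis (homoeologous exchange), otherwise
#' disomically. The offspring dosage is the sum of the two gamete draws.
#'
#' @param founder a [CompositionMap-class] tiling all chromosome sets.
#' @param nGenerations number of selfing generations to simulate.
#' @param pHE per-meiosis probability that a balanced segment pairs
#'   multivalently (the homoeologous-exchange rate knob).
#' @param breakpointRate expected new breakpoints per chromosome set per
#'   generation.
#' @param seed integer seed.
#' @param nondisjunctionProb per-set per-generation probability of gaining an
#'   extra chromosome copy (aneuploidy); default 0.
#' @return a [Lineage-class] with individuals `G0` (the founder) to
#'   `G<nGenerations>`.
#' @examples
#' founder <- balancedMap(c(B01 = 1e6, B02 = 1e6))
#' lin <- simulateLineage(founder, 5, pHE = 0.2, breakpointRate = 1, seed = 7)
#' lin
#' @export
simulateLineage <- function(founder, nGenerations, pHE, breakpointRate = 0,
                            seed = 1L, nondisjunctionProb = 0) {
  if (!is(founder, "CompositionMap"))
    stopf("invalid composition: founder must be a CompositionMap")
  v <- validObject(founder, test = TRUE)
  if (!isTRUE(v)) stopf("invalid composition: %s", paste(v, collapse = "; "))
  if (pHE < 0 || pHE > 1) stopf("invalid parameter: pHE must be in [0, 1]")
  chromLengths <- seqlengths(segments(founder))
  withSeed(seed, {
    df <- segFrame(founder)
    ids <- paste0("G", 0:nGenerations)
    maps <- vector("list", nGenerations + 1L)
    names(maps) <- ids
    maps[[1L]] <- founder
    for (g in seq_len(nGenerations)) {
      df <- selfStep(df, pHE, breakpointRate, chromLengths, nondisjunctionProb)
      maps[[g + 1L]] <- frameToMap(df, chromLengths)
    }
    ind <- data.frame(id = ids,
                      parentId = c(NA_character_, ids[-length(ids)]),
                      generation = 0:nGenerations,
                      selectionClass = NA_character_,
                      stringsAsFactors = FALSE)
    new("Lineage", individuals = ind, maps = maps, seed = as.integer(seed))
  })
}

#' Simulate WGS read counts at diagnostic sites
#'
#' Emulates whole-genome sequencing of one individual mapped to the B-genome
#' reference and genotyped at the AB sites: site depth is
#' Poisson(`meanCov` x totalCopies / 4) — aneuploid segments yield
#' proportionally more coverage — and the A-allele count is
#' Binomial(depth, aCopies / totalCopies).
#'
#' @param map a [CompositionMap-class].
#' @param sites a [ParentalPair-class] or a `GRanges` of AB sites.
#' @param meanCov mean per-site sequencing depth of a euploid genome.
#' @param seed integer seed.
#' @return data.frame with columns `chrom`, `pos`, `aCount`, `bCount` and
#'   `missing` (TRUE where the site received no reads).
#' @export
simulateReadCounts <- function(map, sites, meanCov, seed = 1L) {
  if (meanCov <= 0) stopf("invalid parameter: meanCov must be > 0")
  gr <- if (is(sites, "ParentalPair")) abSites(sites) else sites
  seg <- segments(map)
  hits <- GenomicRanges::findOverlaps(gr, seg, ignore.strand = TRUE)
  if (length(unique(S4Vectors::queryHits(hits))) < length(gr))
    stopf("invalid composition: %d site(s) fall outside any segment",
          length(gr) - length(unique(S4Vectors::queryHits(hits))))
  a <- seg$aCopies[S4Vectors::subjectHits(hits)]
  tot <- a + seg$bCopies[S4Vectors::subjectHits(hits)]
  withSeed(seed, {
    depth <- rpois(length(gr), meanCov * tot / 4)
    aCount <- rbinom(length(gr), depth, ifelse(tot > 0, a / tot, 0))
    data.frame(chrom = as.character(seqnames(gr)),
               pos = GenomicRanges::start(gr),
               aCount = aCount, bCount = depth - aCount,
               missing = depth == 0L, stringsAsFactors = FALSE)
  })
}

ARRAY_ROLES <- c("duranensis", "ipaensis", "mix11", "mix31", "mix13", "tetraploid")

#' Simulate array signal ratios for plants and controls
#'
#' Emulates summarized SNP-array intensities at a subset of AB-site markers:
#' the noise-free A-signal fraction is `aCopies / totalCopies` for tetraploid
#' plants, 1 and 0 for the pure *A. duranensis* / *A. ipaensis* diploid
#' controls, and 0.5 / 0.75 / 0.25 for the 1:1, 3:1 and 1:3 DNA-mixture
#' controls. Gaussian noise of s.d. `noiseSd` is added and the ratio clipped
#' to \[0, 1\].
#'
#' @param markers `GRanges` of marker positions (an AB-site subset) or a
#'   [ParentalPair-class].
#' @param roles named character vector: sample id -> role (one of
#'   `duranensis`, `ipaensis`, `mix11`, `mix31`, `mix13`, `tetraploid`).
#' @param maps named list of [CompositionMap-class] for the
#'   `tetraploid`-role samples.
#' @param noiseSd signal noise s.d. (>= 0).
#' @param seed integer seed.
#' @return a [MarkerSignals-class].
#' @export
simulateArraySignals <- function(markers, roles, maps = list(), noiseSd = 0.02,
                                 seed = 1L) {
  if (noiseSd < 0) stopf("invalid parameter: noiseSd must be >= 0")
  gr <- if (is(markers, "ParentalPair")) abSites(markers) else markers
  bad <- setdiff(unique(roles), ARRAY_ROLES)
  if (length(bad))
    stopf("invalid role: %s (known roles: %s)",
          paste(bad, collapse = ", "), paste(ARRAY_ROLES, collapse = ", "))
  fixed <- c(duranensis = 1, ipaensis = 0, mix11 = 0.5, mix31 = 0.75, mix13 = 0.25)
  nM <- length(gr)
  withSeed(seed, {
    ratio <- matrix(NA_real_, nM, length(roles),
                    dimnames = list(names(gr) %||% paste0("M", seq_len(nM)),
                                    names(roles)))
    for (j in seq_along(roles)) {
      role <- roles[[j]]
      base <- if (role == "tetraploid") {
        id <- names(roles)[j]
        if (is.null(maps[[id]]))
          stopf("tetraploid sample '%s' needs a CompositionMap in 'maps'", id)
        seg <- segments(maps[[id]])
        hits <- GenomicRanges::findOverlaps(gr, seg, ignore.strand = TRUE)
        a <- seg$aCopies[S4Vectors::subjectHits(hits)]
        a / (a + seg$bCopies[S4Vectors::subjectHits(hits)])
      } else rep(fixed[[role]], nM)
      ratio[, j] <- pmin(1, pmax(0, base + rnorm(nM, 0, noiseSd)))
    }
    se <- SummarizedExperiment(
      assays = list(ratio = ratio),
      rowData = S4Vectors::DataFrame(chromB = as.character(seqnames(gr)),
                                     posB = GenomicRanges::start(gr)),
      colData = S4Vectors::DataFrame(role = unname(as.character(roles)),
                                     row.names = names(roles)))
    new("MarkerSignals", se)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## B-copy / A-copy numbers at a locus: copy numbers of the segment(s)
## overlapping the locus, length-weighted rounded to the modal segment.
locusCopies <- function(map, locus) {
  seg <- segments(map)
  hits <- GenomicRanges::findOverlaps(locus, seg, ignore.strand = TRUE)
  if (!length(hits)) stopf("locus outside the simulated chromosome sets")
  sub <- seg[S4Vectors::subjectHits(hits)]
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    rep(locus, length(sub)), sub, ignore.strand = TRUE))
  i <- which.max(w)
  c(a = sub$aCopies[i], b = sub$bCopies[i])
}

#' Simulate dosage-linked phenotypes of a lineage
#'
#' Seed weight is `baseline + sum over seed loci of
#' perExtraBEffect x (bCopies - 2)` plus Gaussian noise. Flower colour
#' follows the dominance of the A-genome yellow allele: any A copy at the
#' flower locus gives yellow; a BBBB locus gives orange, or white with
#' probability `silencingProbBBBB` (dosage-imbalance silencing).
#'
#' @param lineage a [Lineage-class].
#' @param model a [TraitModel-class].
#' @param seed integer seed.
#' @return data.frame with columns `id`, `generation`, `selectionClass`,
#'   `seedWeight` (g/seed) and `flowerColor`.
#' @export
simulatePhenotypes <- function(lineage, model, seed = 1L) {
  ind <- individuals(lineage)
  maps <- compositionMaps(lineage)
  withSeed(seed, {
    res <- lapply(ind$id, function(id) {
      map <- maps[[id]]
      extraB <- sum(vapply(seq_along(model@seedLoci), function(i)
        locusCopies(map, model@seedLoci[i])[["b"]] - 2L, integer(1)))
      w <- model@baseline + model@perExtraBEffect * extraB +
        rnorm(1, 0, model@noiseSd)
      fc <- locusCopies(map, model@flowerLocus)
      color <- if (fc[["a"]] > 0L) "yellow"
               else if (runif(1) < model@silencingProbBBBB) "white" else "orange"
      data.frame(id = id, seedWeight = w, flowerColor = color,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$generation <- ind$generation
    out$selectionClass <- ind$selectionClass
    out[, c("id", "generation", "selectionClass", "seedWeight", "flowerColor")]
  })
}
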