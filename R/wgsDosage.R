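## Normalized subgenome allele counts at AB sites and windowed euploid /
## aneuploid dosage-state classification of chromosome segments.

#' Normalize subgenome allele counts against a 1:1 reference
#'
#' Computes the ratio-of-ratios normalization of per-site subgenome allele
#' counts: each sample count is scaled by the sample's mean coverage and
#' divided by the same quantity in a synthetic 1:1 A:B reference read set,
#' so that a balanced AABB segment has expected normalized counts (1, 1)
#' and, in general, expectation copies/2:
#' \deqn{normalizedA = \frac{sampleAcount / sampleMeanCov}{normrefAcount / normrefMeanCov}}
#' and likewise for B. Sites where the reference count is zero are flagged
#' missing, never divided.
#'
#' @param sample data.frame with columns `chrom`, `pos`, `aCount`, `bCount`.
#' @param normref data.frame with the same columns for the 1:1 reference.
#' @param sampleMeanCov,normrefMeanCov mean per-site coverages; when `NULL`
#'   they are computed as the mean total count over all AB sites.
#' @return data.frame with `chrom`, `pos`, `normalizedA`, `normalizedB` and
#'   `missing` (TRUE where a reference count was zero).
#' @examples
#' s <- data.frame(chrom = "B01", pos = 1, aCount = 30, bCount = 30)
#' r <- data.frame(chrom = "B01", pos = 1, aCount = 15, bCount = 15)
#' normalizeCounts(s, r, sampleMeanCov = 30, normrefMeanCov = 30)
#' @export
normalizeCounts <- function(sample, normref, sampleMeanCov = NULL,
                            normrefMeanCov = NULL) {
  if (is.null(sampleMeanCov)) sampleMeanCov <- mean(sample$aCount + sample$bCount)
  if (is.null(normrefMeanCov)) normrefMeanCov <- mean(normref$aCount + normref$bCount)
  if (!isTRUE(sampleMeanCov > 0) || !isTRUE(normrefMeanCov > 0))
    stopf("invalid input: mean coverages must be > 0")
  m <- match(paste(sample$chrom, sample$pos), paste(normref$chrom, normref$pos))
  if (anyNA(m)) stopf("invalid input: %d site(s) absent from the reference track",
                      sum(is.na(m)))
  refA <- normref$aCount[m]; refB <- normref$bCount[m]
  nA <- ifelse(refA > 0, (sample$aCount / sampleMeanCov) / (refA / normrefMeanCov), NA_real_)
  nB <- ifelse(refB > 0, (sample$bCount / sampleMeanCov) / (refB / normrefMeanCov), NA_real_)
  data.frame(chrom = sample$chrom, pos = sample$pos,
             normalizedA = nA, normalizedB = nB,
             missing = is.na(nA) | is.na(nB), stringsAsFactors = FALSE)
}

#' Expected normalized-count profile of a dosage state
#'
#' Relative to the 1:1 AABB reference, a segment with `(aCopies, bCopies)`
#' subgenome copies has expected normalized counts `(aCopies/2, bCopies/2)`
#' — e.g. (1, 1) for AABB, (1.5, 0.5) for AAAB, (2, 0.5) for the aneuploid
#' AAAAB.
#'
#' @param aCopies,bCopies segment copy numbers; the total must be 3..6.
#' @return numeric `c(expectedA, expectedB)`.
#' @export
expectedProfile <- function(aCopies, bCopies) {
  tot <- aCopies + bCopies
  if (any(!tot %in% 3:6))
    stopf("total copies must be in 3..6 (tetraploid +/- aneuploidy)")
  c(expectedA = aCopies / 2, expectedB = bCopies / 2)
}

#' Allowed dosage-state alphabets
#'
#' `euploidStates()` returns the five balanced-total states (sum 4);
#' `extendedStates()` adds the aneuploid configurations observed in
#' sequenced neoallotetraploid plants (AAAAA, AAAAB, AAAABB, AABBBB).
#'
#' @return integer matrix with columns `aCopies`, `bCopies`, rownames the
#'   state labels.
#' @export
euploidStates <- function() {
  m <- cbind(aCopies = 0:4, bCopies = 4:0)
  rownames(m) <- dosageLabel(m[, 1], m[, 2])
  m
}

#' @rdname euploidStates
#' @export
extendedStates <- function() {
  m <- rbind(euploidStates(),
             cbind(aCopies = c(5L, 4L, 4L, 2L), bCopies = c(0L, 1L, 2L, 4L)))
  rownames(m) <- dosageLabel(m[, 1], m[, 2])
  m
}

#' Classify windows of a normalized track into dosage states
#'
#' Splits each chromosome's AB sites into consecutive non-overlapping
#' windows of `windowN` sites (a shorter terminal window is kept and
#' flagged), takes the per-window median of the normalized A and B counts,
#' and assigns the allowed state whose expected profile
#' ([expectedProfile()]) is nearest in Euclidean distance. Ties are broken
#' toward euploid states (total 4), then toward the lower |A - B|
#' imbalance. Windows with more than 50% missing sites are called
#' `"missing"`.
#'
#' @param norm output of [normalizeCounts()] for one sample.
#' @param windowN sites per window (>= 20).
#' @param allowedStates state matrix as from [extendedStates()] (the
#'   default) or [euploidStates()].
#' @return data.frame with one row per window: `chrom`, `start`, `end` (bp
#'   of first/last site), `nSites`, `medianA`, `medianB`, `aCopies`,
#'   `bCopies`, `state`, `partial`.
#' @export
classifyWindows <- function(norm, windowN = 200L, allowedStates = extendedStates()) {
  if (windowN < 20L) stopf("windowN must be >= 20")
  norm <- norm[order(norm$chrom, norm$pos), ]
  out <- lapply(split(norm, norm$chrom), function(d) {
    n <- nrow(d)
    win <- ceiling(seq_len(n) / windowN)
    do.call(rbind, lapply(split(d, win), function(w) {
      miss <- mean(w$missing)
      if (miss > 0.5) {
        st <- c(NA_integer_, NA_integer_); lab <- "missing"
        mA <- mB <- NA_real_
      } else {
        mA <- median(w$normalizedA[!w$missing])
        mB <- median(w$normalizedB[!w$missing])
        dist <- sqrt((allowedStates[, 1] / 2 - mA)^2 +
                     (allowedStates[, 2] / 2 - mB)^2)
        best <- which(dist <= min(dist) + 1e-12)
        if (length(best) > 1L) {
          tot <- rowSums(allowedStates[best, , drop = FALSE])
          best <- best[order(tot != 4L,
                             abs(allowedStates[best, 1] - allowedStates[best, 2]))]
        }
        st <- allowedStates[best[1L], ]
        lab <- rownames(allowedStates)[best[1L]]
      }
      data.frame(chrom = w$chrom[1L], start = min(w$pos), end = max(w$pos),
                 nSites = nrow(w), medianA = mA, medianB = mB,
                 aCopies = st[[1L]], bCopies = st[[2L]], state = lab,
                 partial = nrow(w) < windowN, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Merge classified windows into segments
#'
#' Merges maximal runs of windows sharing a state into contiguous segment
#' calls. Runs shorter than `minRun` windows are absorbed into the flanking
#' state whose expected profile is nearer to the run's median profile, and
#' counted in the segment's `nFlagged`.
#'
#' @param windows output of [classifyWindows()] (one sample), ordered by
#'   position.
#' @param minRun minimum run length (windows) for a state to stand alone.
#' @return data.frame of segments: `chrom`, `start`, `end`, `aCopies`,
#'   `bCopies`, `state`, `nWindows`, `nSites`, `meanA`, `meanB`, `nFlagged`.
#' @export
mergeSegments <- function(windows, minRun = 2L) {
  segOne <- function(d) {
    r <- rle(d$state)
    repeat {
      if (length(r$lengths) <= 1L) break
      short <- which(r$lengths < minRun)
      if (!length(short)) break
      i <- short[1L]
      idx <- cumsum(r$lengths)
      lo <- if (i == 1L) NA else i - 1L
      hi <- if (i == length(r$lengths)) NA else i + 1L
      pick <- if (is.na(lo)) hi else if (is.na(hi)) lo else {
        first <- idx[i] - r$lengths[i] + 1L
        mA <- mean(d$medianA[first:idx[i]], na.rm = TRUE)
        mB <- mean(d$medianB[first:idx[i]], na.rm = TRUE)
        profDist <- function(j) {
          k <- idx[j]  # any window of run j carries its state copies
          if (is.na(d$aCopies[k]) || !is.finite(mA)) Inf
          else sqrt((d$aCopies[k] / 2 - mA)^2 + (d$bCopies[k] / 2 - mB)^2)
        }
        if (profDist(lo) <= profDist(hi)) lo else hi
      }
      # absorb: relabel the short run's windows to the picked state
      first <- idx[i] - r$lengths[i] + 1L
      src <- idx[pick]
      d$state[first:idx[i]] <- d$state[src]
      d$aCopies[first:idx[i]] <- d$aCopies[src]
      d$bCopies[first:idx[i]] <- d$bCopies[src]
      d$flagged[first:idx[i]] <- TRUE
      r <- rle(d$state)
    }
    grp <- rep(seq_along(r$lengths), r$lengths)
    do.call(rbind, lapply(split(d, grp), function(g) {
      data.frame(chrom = g$chrom[1L], start = min(g$start), end = max(g$end),
                 aCopies = g$aCopies[1L], bCopies = g$bCopies[1L],
                 state = g$state[1L], nWindows = nrow(g),
                 nSites = sum(g$nSites),
                 meanA = mean(g$medianA, na.rm = TRUE),
                 meanB = mean(g$medianB, na.rm = TRUE),
                 nFlagged = sum(g$flagged), stringsAsFactors = FALSE)
    }))
  }
  windows$flagged <- FALSE
  out <- do.call(rbind, lapply(split(windows, windows$chrom), segOne))
  rownames(out) <- NULL
  out
}

#' End-to-end WGS dosage profile of one individual
#'
#' Convenience wrapper: simulate or supply raw counts, normalize against the
#' reference track, classify windows and merge segments.
#'
#' @param sample,normref count tracks as for [normalizeCounts()].
#' @param windowN,allowedStates,minRun see [classifyWindows()] and
#'   [mergeSegments()].
#' @return list with elements `normalized`, `windows`, `segments`.
#' @export
wgsDosageProfile <- function(sample, normref, windowN = 200L,
                             allowedStates = extendedStates(), minRun = 2L) {
  norm <- normalizeCounts(sample, normref)
  win <- classifyWindows(norm, windowN, allowedStates)
  list(normalized = norm, windows = win, segments = mergeSegments(win, minRun))
}
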