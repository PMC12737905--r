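## Seeded simulation experiments that exercise whole pipeline paths.

#' Window-classification recovery across dosage states
#'
#' For every target dosage state, simulates one individual whose genome is
#' balanced AABB except for chromosome set `B01`, which carries the target
#' state — the configuration of sequenced neoallotetraploid plants, where
#' aberrant segments sit in a mostly-euploid background so the sample mean
#' coverage stays near the euploid baseline. WGS read counts at the
#' diagnostic sites are normalized against a simulated 1:1 AABB reference
#' and classified into windows; the experiment reports the fraction of
#' target-chromosome windows recovering the true state.
#'
#' @param states integer state matrix (see [extendedStates()]) of target
#'   states to simulate.
#' @param allowedStates state alphabet given to [classifyWindows()].
#' @param meanCov mean sequencing coverage of the simulated samples.
#' @param nChrom,chromLen,siteRate simulated genome dimensions.
#' @param windowN sites per classification window.
#' @param seed integer master seed.
#' @return data.frame with one row per target state: `state`, `aCopies`,
#'   `bCopies`, `nWindows`, `accuracy` (target chromosome), `modalCall`
#'   (most frequent call on the target chromosome) and `aabbAccuracy`
#'   (background chromosomes).
#' @export
dosageRecoveryExperiment <- function(states = extendedStates(),
                                     allowedStates = extendedStates(),
                                     meanCov = 30, nChrom = 4L,
                                     chromLen = 2e5L, siteRate = 0.005,
                                     windowN = 100L, seed = 1L) {
  seeds <- splitSeed(seed, 2L + nrow(states))
  parents <- simulateParents(nChrom, chromLen, siteRate, seed = seeds[1])
  chromLengths <- seqlengths(abSites(parents))
  refMap <- balancedMap(chromLengths)
  normref <- simulateReadCounts(refMap, parents, meanCov * 2, seed = seeds[2])
  out <- lapply(seq_len(nrow(states)), function(i) {
    a <- states[i, 1]; b <- states[i, 2]
    lab <- rownames(states)[i]
    seg <- segFrame(refMap)
    seg$a[seg$chrom == "B01"] <- a
    seg$b[seg$chrom == "B01"] <- b
    map <- frameToMap(seg, chromLengths)
    counts <- simulateReadCounts(map, parents, meanCov, seed = seeds[2 + i])
    win <- classifyWindows(normalizeCounts(counts, normref),
                           windowN = windowN, allowedStates = allowedStates)
    tgt <- win[win$chrom == "B01", ]
    bg <- win[win$chrom != "B01", ]
    calls <- table(tgt$state)
    data.frame(state = lab, aCopies = a, bCopies = b,
               nWindows = nrow(tgt),
               accuracy = mean(tgt$state == lab),
               modalCall = names(calls)[which.max(calls)],
               aabbAccuracy = mean(bg$state == "AABB"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
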