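## The tetrasomic-segregation Markov model of a selfed segment: offspring
## dosage law, transition matrix, absorption (fixation) probabilities and a
## vectorized chain simulator.

## One selfing of a vector of euploid segment dosages: each of the two
## meioses draws a gamete A-count — disomically for even dosage, with
## per-meiosis probability pHE of multivalent (hypergeometric) pairing for
## the balanced state, always hypergeometric for odd dosage. Shared by the
## lineage simulator and the chain simulator.
selfDosageKernel <- function(aCopies, pHE) {
  n <- length(aCopies)
  gam <- matrix(0L, n, 2L)
  for (m in 1:2) {
    gm <- as.integer(aCopies / 2L)
    odd <- aCopies %% 2L == 1L
    if (any(odd)) gm[odd] <- as.integer(rhyper(sum(odd), aCopies[odd],
                                               4L - aCopies[odd], 2L))
    bal <- aCopies == 2L
    if (any(bal)) {
      multi <- bal & (runif(n) < pHE)
      if (any(multi)) gm[multi] <- as.integer(rhyper(sum(multi), 2L, 2L, 2L))
    }
    gam[, m] <- gm
  }
  gam[, 1L] + gam[, 2L]
}

## gamete A-dosage pmf over {0,1,2} for a segment with a A-copies of 4
gametePmf <- function(aCopies, pHE) {
  hyper <- stats::dhyper(0:2, aCopies, 4L - aCopies, 2L)
  if (aCopies %% 2L == 0L) {
    dis <- numeric(3); dis[aCopies / 2L + 1L] <- 1
    if (aCopies == 2L) (1 - pHE) * dis + pHE * hyper else dis
  } else hyper
}

#' Offspring dosage distribution of one selfed segment
#'
#' Probability over offspring A-dosage 0..4 for a euploid segment with
#' `aCopies` A copies under selfing: the convolution of two independent
#' gamete draws. Fixed segments (0 or 4) breed true; unbalanced segments
#' (1, 3) always segregate tetrasomically; the balanced segment (2) pairs
#' multivalently with per-meiosis probability `pHE`, else disomically
#' (breeding true).
#'
#' @param aCopies parental A-dosage, 0..4.
#' @param pHE per-meiosis multivalent-pairing probability.
#' @return named numeric vector of probabilities over dosages `0`..`4`.
#' @examples
#' offspringDosageDistribution(3)       # 0.25 / 0.50 / 0.25 on 2/3/4
#' offspringDosageDistribution(2, pHE = 0)   # breeds true
#' @export
offspringDosageDistribution <- function(aCopies, pHE = 1) {
  if (length(aCopies) != 1L || !aCopies %in% 0:4)
    stopf("aCopies must be a single integer in 0..4")
  g <- gametePmf(aCopies, pHE)
  out <- numeric(5)
  for (i in 0:2) for (j in 0:2)
    out[i + j + 1L] <- out[i + j + 1L] + g[i + 1L] * g[j + 1L]
  setNames(out, 0:4)
}

#' Selfing transition matrix of segment dosage
#'
#' @param pHE per-meiosis multivalent-pairing probability.
#' @return 5x5 row-stochastic matrix over dosages 0..4; rows 0 and 4 are
#'   absorbing.
#' @export
selfingTransitionMatrix <- function(pHE = 1) {
  t(vapply(0:4, offspringDosageDistribution, numeric(5), pHE = pHE))
}

#' Fixation probability of the AAAA state
#'
#' Solves the absorption problem of the selfing dosage chain: the
#' probability that a segment starting at `aCopies` A copies is eventually
#' fixed at dosage 4 (AAAA) rather than 0 (BBBB). Because the mean dosage
#' is a martingale, this equals `aCopies / 4` whenever `pHE > 0`.
#'
#' @param aCopies starting A-dosage, 0..4.
#' @param pHE per-meiosis multivalent-pairing probability (> 0 so the
#'   balanced state is not absorbing).
#' @return probability of fixing AAAA.
#' @examples
#' fixationProbability(3)  # 0.75
#' @export
fixationProbability <- function(aCopies, pHE = 1) {
  if (pHE <= 0) stopf("pHE must be > 0 (otherwise dosage 2 is absorbing)")
  P <- selfingTransitionMatrix(pHE)
  trans <- 2:4          # transient states 1,2,3 (rows are dosages 0..4)
  Q <- P[trans, trans]
  R <- P[trans, 5]      # one-step absorption into dosage 4
  h <- solve(diag(3) - Q, R)
  unname(c(0, h, 1)[aCopies + 1L])
}

#' Simulate the selfing dosage chain to a fixed horizon
#'
#' Vectorized simulation of `nReplicates` independent segments starting at
#' `aCopies`, each selfed for `nGenerations` generations under the same
#' segregation model as [simulateLineage()].
#'
#' @param aCopies starting A-dosage, 0..4.
#' @param pHE per-meiosis multivalent-pairing probability.
#' @param nGenerations generations to simulate.
#' @param nReplicates number of independent replicate segments.
#' @param seed integer seed.
#' @return integer matrix (`nReplicates` x `nGenerations + 1`) of dosages,
#'   column 1 the founder state.
#' @export
simulateDosageChain <- function(aCopies, pHE = 1, nGenerations = 40L,
                                nReplicates = 10000L, seed = 1L) {
  if (!aCopies %in% 0:4) stopf("aCopies must be in 0..4")
  withSeed(seed, {
    out <- matrix(NA_integer_, nReplicates, nGenerations + 1L)
    cur <- rep(as.integer(aCopies), nReplicates)
    out[, 1L] <- cur
    for (g in seq_len(nGenerations)) {
      cur <- selfDosageKernel(cur, pHE)
      out[, g + 1L] <- cur
    }
    out
  })
}
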