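## Chromosome-set composition matrices, per-set unbalanced-dosage summaries,
## generation-to-generation transition statistics, flower-colour prediction
## and PCA ordination.

#' Map a B-genome chromosome to its chromosome-set label
#'
#' Chromosome sets follow the simple numerical correspondence (B03 -> set
#' 03) except sets 07 and 08, which aggregate rearranged parts of A07 and
#' A08 (a reciprocal translocation in the A-genome lineage); those two sets
#' are flagged `rearranged`.
#'
#' @param chromB character vector of B-genome chromosome names (`B01`...).
#' @param nSets number of chromosome sets in the assembly.
#' @return character vector of set labels (`"01"`...), with a logical
#'   attribute `rearranged`.
#' @examples
#' mapChromSet("B03")
#' attr(mapChromSet("B07"), "rearranged")
#' @export
mapChromSet <- function(chromB, nSets = 10L) {
  num <- suppressWarnings(as.integer(sub("^B", "", chromB)))
  bad <- !grepl("^B[0-9]{1,2}$", chromB) | is.na(num) | num < 1L | num > nSets
  if (any(bad))
    stopf("invalid chromosome: %s", paste(unique(chromB[bad]), collapse = ", "))
  out <- sprintf("%02d", num)
  attr(out, "rearranged") <- num %in% c(7L, 8L)
  out
}

#' Build the colour-codeable composition matrix
#'
#' Maps a retained tetraploid dosage-call matrix to the five-state
#' composition labels (4 -> AAAA, 3 -> AAAB, 2 -> AABB, 1 -> ABBB,
#' 0 -> BBBB; NA -> missing), with markers ordered by chromosome set and
#' B-genome physical position.
#'
#' @param calls a [DosageCalls-class] with anchored markers.
#' @param nSets passed to [mapChromSet()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with character
#'   assay `"composition"` and `rowData` columns `chromB`, `posB`,
#'   `chromSet`.
#' @export
buildCompositionMatrix <- function(calls, nSets = 10L) {
  rd <- rowData(calls)
  if (anyNA(rd$chromB) || anyNA(rd$posB))
    stopf("all markers must be anchored to a B-genome position")
  if (anyDuplicated(rownames(calls)))
    stopf("data error: duplicate marker ids")
  set <- mapChromSet(as.character(rd$chromB), nSets)
  o <- order(set, rd$posB)
  d <- assay(calls, "dosage")[o, , drop = FALSE]
  lab <- matrix(dosageToLabel(d), nrow(d), ncol(d), dimnames = dimnames(d))
  SummarizedExperiment(
    assays = list(composition = lab),
    rowData = S4Vectors::DataFrame(chromB = rd$chromB[o], posB = rd$posB[o],
                                   chromSet = set[o],
                                   row.names = rownames(calls)[o]),
    colData = colData(calls))
}

#' Per-set normalized counts of unbalanced compositions
#'
#' For each chromosome set and each non-AABB state, counts the matrix cells
#' in that state across the given individuals and normalizes by the number
#' of markers on the set. With `perIndividual = TRUE` (default) the count is
#' further divided by the number of individuals, giving the mean per-marker
#' fraction; with `FALSE` the per-marker counts are summed over individuals.
#'
#' @param mat composition matrix from [buildCompositionMatrix()].
#' @param samples optional sample ids to include (default: all
#'   tetraploid-role samples, or all columns when roles are absent).
#' @param perIndividual normalization mode, see above.
#' @return data.frame with `chromSet`, `state`, `fraction`.
#' @export
unbalancedFraction <- function(mat, samples = NULL, perIndividual = TRUE) {
  lab <- assay(mat, "composition")
  if (is.null(samples)) {
    role <- colData(mat)$role
    samples <- if (!is.null(role) && any(role == "tetraploid"))
      colnames(mat)[role == "tetraploid"] else colnames(mat)
  }
  lab <- lab[, samples, drop = FALSE]
  set <- rowData(mat)$chromSet
  states <- setdiff(DOSAGE_LABELS, "AABB")
  out <- do.call(rbind, lapply(unique(set), function(cs) {
    sub <- lab[set == cs, , drop = FALSE]
    nMark <- nrow(sub)
    cnt <- vapply(states, function(s) sum(sub == s, na.rm = TRUE), numeric(1))
    frac <- cnt / nMark
    if (perIndividual) frac <- frac / ncol(sub)
    data.frame(chromSet = cs, state = states, fraction = frac,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-marker composition transitions across generations
#'
#' For every genotyped parent-child pair in the pedigree, records the
#' from-state to to-state transition at each marker (aggregated per child,
#' chromosome set and state pair) and summarizes the stability rate of each
#' from-state: the fraction of marker transmissions that kept the state.
#'
#' @param mat composition matrix from [buildCompositionMatrix()] whose
#'   columns include the pedigree individuals.
#' @param pedigree data.frame with columns `id`, `parentId`, `generation`.
#' @return list with `records` (`childId`, `parentId`, `chromSet`,
#'   `generation`, `fromState`, `toState`, `nMarkers`) and `summary`
#'   (`fromState`, `nTransmissions`, `stabilityRate`).
#' @export
transitionStats <- function(mat, pedigree) {
  lab <- assay(mat, "composition")
  set <- rowData(mat)$chromSet
  kids <- pedigree[!is.na(pedigree$parentId), , drop = FALSE]
  recs <- list()
  for (i in seq_len(nrow(kids))) {
    child <- kids$id[i]; parent <- kids$parentId[i]
    if (!(child %in% colnames(lab)) || !(parent %in% colnames(lab))) {
      message("skipping ", child, ": parent or child not genotyped")
      next
    }
    from <- lab[, parent]; to <- lab[, child]
    ok <- from != "missing" & to != "missing" & !is.na(from) & !is.na(to)
    if (!any(ok)) next
    tab <- as.data.frame(table(chromSet = set[ok], fromState = from[ok],
                               toState = to[ok]), stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0L, , drop = FALSE]
    tab$childId <- child; tab$parentId <- parent
    tab$generation <- kids$generation[i]
    recs[[length(recs) + 1L]] <- tab
  }
  if (!length(recs))
    stopf("no genotyped parent-child pair shares markers")
  records <- do.call(rbind, recs)
  names(records)[names(records) == "Freq"] <- "nMarkers"
  records <- records[, c("childId", "parentId", "chromSet", "generation",
                         "fromState", "toState", "nMarkers")]
  agg <- stats::aggregate(nMarkers ~ fromState,
                          data = records, FUN = sum)
  stay <- stats::aggregate(nMarkers ~ fromState,
                           data = records[records$fromState == records$toState, ,
                                          drop = FALSE], FUN = sum)
  summary <- merge(agg, stay, by = "fromState", all.x = TRUE,
                   suffixes = c("", "Stayed"))
  summary$nMarkersStayed[is.na(summary$nMarkersStayed)] <- 0
  summary <- data.frame(fromState = summary$fromState,
                        nTransmissions = summary$nMarkers,
                        stabilityRate = summary$nMarkersStayed / summary$nMarkers,
                        stringsAsFactors = FALSE)
  list(records = records, summary = summary)
}

#' Predict flower colour from the flower-locus composition
#'
#' Any A copy at the flower locus expresses the dominant A-genome yellow
#' allele; a pure-B (BBBB) locus gives orange, or white with probability
#' `silencingProb` through dosage-imbalance gene silencing.
#'
#' @param state composition label at the flower locus (`AAAA` ... `BBBB`).
#' @param silencingProb probability of BBBB silencing to white.
#' @return named numeric probability vector over `yellow`, `orange`,
#'   `white`.
#' @examples
#' flowerColorPredict("AABB")              # yellow with certainty
#' flowerColorPredict("BBBB", 0.3)
#' @export
flowerColorPredict <- function(state, silencingProb = 0.5) {
  if (length(state) != 1L || !state %in% DOSAGE_LABELS)
    stopf("state must be one of %s", paste(DOSAGE_LABELS, collapse = ", "))
  if (grepl("A", state)) c(yellow = 1, orange = 0, white = 0)
  else c(yellow = 0, orange = 1 - silencingProb, white = silencingProb)
}

#' PCA of the dosage matrix
#'
#' Centered, unscaled principal components of the integer dosage matrix
#' (samples as observations, markers as variables), as used to ordinate
#' tetraploid plants between their diploid progenitors.
#'
#' @param calls a [DosageCalls-class] (diploid controls rescaled to 4/0 when
#'   included).
#' @param includeDiploids keep the `duranensis`/`ipaensis` samples (TRUE) or
#'   ordinate the tetraploid plants only.
#' @param nComponents number of components to return.
#' @return list with `scores` (data.frame: sample, role, PC columns) and
#'   `percentVar` (non-increasing, sums to <= 100).
#' @export
pcaScores <- function(calls, includeDiploids = TRUE, nComponents = 5L) {
  roles <- sampleRoles(calls)
  keep <- if (includeDiploids) !(roles %in% c("mix11", "mix31", "mix13"))
          else roles == "tetraploid"
  d <- assay(calls, "dosage")[, keep, drop = FALSE]
  if (ncol(d) < 3L || nrow(d) < 2L) stopf("need >= 3 samples and >= 2 markers")
  x <- t(d)
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  }
  if (all(apply(x, 2L, function(v) stats::var(v) == 0)))
    stopf("degenerate input: constant dosage matrix")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(p$x))
  pv <- 100 * p$sdev^2 / sum(p$sdev^2)
  scores <- data.frame(sample = rownames(x), role = roles[keep],
                       p$x[, seq_len(k), drop = FALSE],
                       stringsAsFactors = FALSE, row.names = NULL)
  list(scores = scores, percentVar = pv[seq_len(k)])
}
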