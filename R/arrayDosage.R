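## Tetraploid (0-4) dosage calling from array signal ratios, the
## control-mixture marker filter cascade, and diploid-control rescaling.

#' Call tetraploid allele dosages from signal ratios
#'
#' Per marker, each sample's A-signal ratio is assigned the dosage
#' `d` in 0..4 minimizing `|ratio - d/4|`. Samples lying farther than
#' `maxSd` pooled within-class standard deviations from their class centre
#' (the mean ratio of the marker's samples sharing the call) are then set
#' missing. Markers where all samples collapse into one class are still
#' called (no dispersion estimate, no rejection).
#'
#' @param signals a [MarkerSignals-class].
#' @param maxSd dispersion-rejection threshold in pooled within-class s.d.
#' @return a [DosageCalls-class] with the same dimensions and annotation.
#' @export
callDosage <- function(signals, maxSd = 3) {
  if (!is(signals, "MarkerSignals")) stopf("signals must be a MarkerSignals")
  r <- assay(signals, "ratio")
  if (length(r) == 0L) stopf("invalid input: empty signal table")
  d <- matrix(as.integer(round(r * 4)), nrow(r), ncol(r), dimnames = dimnames(r))
  d[is.na(r)] <- NA_integer_
  for (i in seq_len(nrow(d))) {
    ri <- r[i, ]; di <- d[i, ]
    ok <- !is.na(di)
    if (!any(ok)) next
    centers <- tapply(ri[ok], di[ok], mean)
    nk <- tapply(ri[ok], di[ok], length)
    dfree <- sum(ok) - length(centers)
    if (dfree <= 0L) next
    pooled <- sqrt(sum(tapply(ri[ok], di[ok],
                              function(x) sum((x - mean(x))^2))) / dfree)
    if (!is.finite(pooled) || pooled == 0) next
    dev <- abs(ri - centers[as.character(di)])
    d[i, ok & dev > maxSd * pooled] <- NA_integer_
  }
  new("DosageCalls", SummarizedExperiment(
    assays = list(dosage = d),
    rowData = rowData(signals), colData = colData(signals)))
}

## modal call(s): all values attaining the maximum frequency (inclusive ties)
modalCalls <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(integer())
  tab <- table(x)
  as.integer(names(tab)[tab == max(tab)])
}

#' Control-mixture marker filter cascade
#'
#' Applies, per marker, the retention criteria used to reduce a raw
#' tetraploid-scale genotype-call table to its analysis-ready marker set:
#' (i) calls present for all samples; (ii) the 1:1 DNA mixtures (AABB) have
#' modal score 2; (iii) the 3:1 and 1:3 mixtures have modal scores 3 and 1
#' respectively (triplex compositions, counting A alleles); (iv) at least
#' 25% of the tetraploid plants score 2 (balanced AABB); and (v) the marker
#' is anchored to a B-genome physical position. A modal-score tie that
#' includes the required value passes.
#'
#' @param calls a [DosageCalls-class] whose `colData$role` covers the
#'   `mix11`, `mix31`, `mix13` and `tetraploid` classes.
#' @return data.frame with one row per marker: logical columns `complete`,
#'   `mix11Modal2`, `mixTriplex`, `tetraploid25`, `anchored` and `retained`
#'   (their conjunction).
#' @export
markerFilterCascade <- function(calls) {
  roles <- sampleRoles(calls)
  need <- c("mix11", "mix31", "mix13", "tetraploid")
  absent <- setdiff(need, roles)
  if (length(absent))
    stopf("configuration error: missing control roles: %s",
          paste(absent, collapse = ", "))
  d <- assay(calls, "dosage")
  rd <- rowData(calls)
  anchored <- if (all(c("chromB", "posB") %in% colnames(rd)))
    !is.na(rd$chromB) & !is.na(rd$posB) else rep(FALSE, nrow(d))
  res <- data.frame(
    marker = rownames(d),
    complete = apply(d, 1L, function(x) !anyNA(x)),
    mix11Modal2 = apply(d[, roles == "mix11", drop = FALSE], 1L,
                        function(x) 2L %in% modalCalls(x)),
    mixTriplex = apply(d[, roles == "mix31", drop = FALSE], 1L,
                       function(x) 3L %in% modalCalls(x)) &
                 apply(d[, roles == "mix13", drop = FALSE], 1L,
                       function(x) 1L %in% modalCalls(x)),
    tetraploid25 = apply(d[, roles == "tetraploid", drop = FALSE], 1L,
                         function(x) mean(x == 2L, na.rm = TRUE) >= 0.25),
    anchored = anchored,
    stringsAsFactors = FALSE)
  res$tetraploid25[is.na(res$tetraploid25)] <- FALSE
  res$retained <- res$complete & res$mix11Modal2 & res$mixTriplex &
    res$tetraploid25 & res$anchored
  rownames(res) <- NULL
  res
}

#' Subset a call matrix to the retained markers
#'
#' @param calls a [DosageCalls-class].
#' @return the retained-marker [DosageCalls-class].
#' @export
filterMarkers <- function(calls) {
  calls[markerFilterCascade(calls)$retained, ]
}

#' Rescale diploid-control calls to the tetraploid extremes
#'
#' Converts the diploid controls to the tetraploid scale by setting every
#' *A. duranensis* (pure-A) call to 4 and every *A. ipaensis* (pure-B) call
#' to 0; all other samples are unchanged.
#'
#' @param calls a [DosageCalls-class].
#' @return a [DosageCalls-class].
#' @export
rescaleDiploidControls <- function(calls) {
  d <- assay(calls, "dosage")
  roles <- sampleRoles(calls)
  d[, roles == "duranensis"] <- 4L
  d[, roles == "ipaensis"] <- 0L
  new("DosageCalls", SummarizedExperiment(
    assays = list(dosage = d),
    rowData = rowData(calls), colData = colData(calls)))
}

#' Assemble a dosage-call container from a raw call table
#'
#' Builds a [DosageCalls-class] from an in-memory raw-call matrix (marker
#' rows x sample columns, values 0-4 or NA), sample roles and marker
#' anchors, the layout of a raw tetraploid-scale genotype-call spreadsheet.
#'
#' @param calls integer matrix (markers x samples) with dimnames.
#' @param roles named character vector sample -> role.
#' @param chromB,posB optional marker anchor vectors (NA = unanchored).
#' @return a [DosageCalls-class].
#' @export
dosageCalls <- function(calls, roles, chromB = NA, posB = NA) {
  roles <- roles[colnames(calls)]
  new("DosageCalls", SummarizedExperiment(
    assays = list(dosage = calls),
    rowData = S4Vectors::DataFrame(
      chromB = rep_len(chromB, nrow(calls)),
      posB = rep_len(posB, nrow(calls)), row.names = rownames(calls)),
    colData = S4Vectors::DataFrame(role = unname(roles),
                                   row.names = colnames(calls))))
}
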