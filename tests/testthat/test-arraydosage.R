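# array dosage calling, the control-mixture filter cascade and diploid
# rescaling

test_that("nearest-class dosage calling recovers noise-free classes", {
  pp <- simulateParents(1, 2e4, 0.01, seed = 51)
  roles <- c(dur = "duranensis", ipa = "ipaensis", m11 = "mix11",
             m31 = "mix31", m13 = "mix13",
             p1 = "tetraploid", p2 = "tetraploid")
  maps <- list(p1 = balancedMap(c(B01 = 2e4L), 3L, 1L),
               p2 = balancedMap(c(B01 = 2e4L), 1L, 3L))
  sig <- simulateArraySignals(pp, roles, maps, noiseSd = 0, seed = 52)
  d <- SummarizedExperiment::assay(callDosage(sig), "dosage")
  expect_true(all(d[, "dur"] == 4L) && all(d[, "ipa"] == 0L))
  expect_true(all(d[, "m11"] == 2L) && all(d[, "m31"] == 3L) &&
              all(d[, "m13"] == 1L))
  expect_true(all(d[, "p1"] == 3L) && all(d[, "p2"] == 1L))
})

test_that("dosage assignment is the nearest of the five ratio classes", {
  mk <- function(ratios) {
    r <- matrix(ratios, nrow = 1L, ncol = length(ratios))
    rownames(r) <- "M1"
    if (ncol(r)) colnames(r) <- paste0("s", seq_len(ncol(r)))
    new("MarkerSignals", SummarizedExperiment::SummarizedExperiment(
      assays = list(ratio = r),
      rowData = S4Vectors::DataFrame(chromB = rep("B01", nrow(r)),
                                     posB = rep(1L, nrow(r)),
                                     row.names = rownames(r)),
      colData = S4Vectors::DataFrame(role = rep("tetraploid", ncol(r)),
                                     row.names = colnames(r))))
  }
  expect_true(all(SummarizedExperiment::assay(
    callDosage(mk(rep(0.5, 4))), "dosage") == 2L))
  expect_equal(SummarizedExperiment::assay(
    callDosage(mk(c(0.49, 0.5, 0.5))), "dosage")[1, 1], 2L)
  expect_error(callDosage(mk(numeric(0))), "empty")
})

test_that("dispersion rejection drops far outliers but keeps single-class markers", {
  ratios <- matrix(c(0.50, 0.51, 0.49, 0.50, 0.52, 0.48, 0.50, 0.62),
                   nrow = 1, dimnames = list("M1", paste0("s", 1:8)))
  sig <- new("MarkerSignals", SummarizedExperiment::SummarizedExperiment(
    assays = list(ratio = ratios),
    rowData = S4Vectors::DataFrame(chromB = "B01", posB = 1L, row.names = "M1"),
    colData = S4Vectors::DataFrame(role = rep("tetraploid", 8),
                                   row.names = colnames(ratios))))
  d <- SummarizedExperiment::assay(callDosage(sig, maxSd = 2), "dosage")
  expect_true(is.na(d[1, "s8"]))            # 0.62 sits far outside its class
  expect_true(all(d[1, 1:7] == 2L))
  # the permissive default keeps it: dispersion, not distance, decides
  lax <- SummarizedExperiment::assay(callDosage(sig, maxSd = 3), "dosage")
  expect_false(anyNA(lax))
})

test_that("the filter cascade retains exactly the conforming toy marker", {
  calls <- toyCascadeCalls()
  res <- markerFilterCascade(calls)
  expect_equal(res$marker[res$retained], "M1")
  expect_false(res$mix11Modal2[res$marker == "M2"])
  expect_false(res$complete[res$marker == "M3"])
  expect_false(res$tetraploid25[res$marker == "M4"])
  expect_equal(rownames(filterMarkers(calls)), "M1")

  # retention is the conjunction of marker-local criteria, so any
  # evaluation order gives the same set
  crit <- c("complete", "mix11Modal2", "mixTriplex", "tetraploid25", "anchored")
  for (perm in list(crit, rev(crit), sample(crit))) {
    agg <- Reduce(`&`, res[perm])
    expect_equal(agg, res$retained)
  }

  noCtl <- calls[, sampleRoles(calls) != "mix11"]
  expect_error(markerFilterCascade(noCtl), "configuration error")
})

test_that("a noise-free full-control table retains every marker", {
  pp <- simulateParents(1, 2e4, 0.01, seed = 53)
  roles <- c(m11 = "mix11", m31 = "mix31", m13 = "mix13",
             p1 = "tetraploid", p2 = "tetraploid")
  maps <- list(p1 = balancedMap(c(B01 = 2e4L)), p2 = balancedMap(c(B01 = 2e4L)))
  sig <- simulateArraySignals(pp, roles, maps, noiseSd = 0, seed = 54)
  expect_true(all(markerFilterCascade(callDosage(sig))$retained))
})

test_that("adding control noise never increases retention (seeded trend)", {
  pp <- simulateParents(1, 3e4, 0.01, seed = 55)
  roles <- c(m11a = "mix11", m11b = "mix11", m31a = "mix31", m31b = "mix31",
             m13a = "mix13", m13b = "mix13",
             p1 = "tetraploid", p2 = "tetraploid", p3 = "tetraploid",
             p4 = "tetraploid")
  maps <- lapply(setNames(nm = paste0("p", 1:4)),
                 function(i) balancedMap(c(B01 = 3e4L)))
  kept <- vapply(c(0, 0.05, 0.12, 0.2), function(ns) {
    sig <- simulateArraySignals(pp, roles, maps, noiseSd = ns, seed = 56)
    sum(markerFilterCascade(callDosage(sig))$retained)
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("diploid controls rescale to the tetraploid extremes, others untouched", {
  calls <- toyCascadeCalls()
  extra <- dosageCalls(
    cbind(SummarizedExperiment::assay(calls, "dosage"),
          dur = c(2L, 2L, 2L, 2L), ipa = c(1L, 2L, 2L, 2L)),
    c(sampleRoles(calls), dur = "duranensis", ipa = "ipaensis"),
    chromB = SummarizedExperiment::rowData(calls)$chromB,
    posB = SummarizedExperiment::rowData(calls)$posB)
  out <- SummarizedExperiment::assay(rescaleDiploidControls(extra), "dosage")
  expect_true(all(out[, "dur"] == 4L))
  expect_true(all(out[, "ipa"] == 0L))
  expect_equal(out[, colnames(out) != "dur" & colnames(out) != "ipa"],
               SummarizedExperiment::assay(calls, "dosage"))
})

test_that("the end-to-end array path reproduces true dosages at low noise", {
  pp <- simulateParents(2, 5e4, 0.005, seed = 57)
  lin <- simulateLineage(balancedMap(tinyLengths), 8, pHE = 0.4,
                         breakpointRate = 1, seed = 58)
  plantMaps <- compositionMaps(lin)[paste0("G", 5:8)]
  names(plantMaps) <- paste0("p", 1:4)
  roles <- c(m11 = "mix11", m31 = "mix31", m13 = "mix13",
             setNames(rep("tetraploid", 4), names(plantMaps)))
  sig <- simulateArraySignals(pp, roles, plantMaps, noiseSd = 0.04, seed = 59)
  calls <- filterMarkers(callDosage(sig))
  d <- SummarizedExperiment::assay(calls, "dosage")
  rd <- SummarizedExperiment::rowData(calls)
  truth <- vapply(names(plantMaps), function(p) {
    seg <- segments(plantMaps[[p]])
    gr <- GenomicRanges::GRanges(rd$chromB, IRanges::IRanges(rd$posB, width = 1))
    hit <- GenomicRanges::findOverlaps(gr, seg)
    seg$aCopies[S4Vectors::subjectHits(hit)]
  }, integer(nrow(d)))
  acc <- mean(d[, names(plantMaps)] == truth, na.rm = TRUE)
  expect_gte(acc, 0.99)
})
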