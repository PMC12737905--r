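# composition matrix, per-set summaries, transitions, flower colour, PCA

test_that("chromosome-set mapping follows numerical correspondence with 07/08 flagged", {
  expect_equal(as.character(mapChromSet("B03")), "03")
  s <- mapChromSet(c("B07", "B08", "B01"))
  expect_equal(as.character(s), c("07", "08", "01"))
  expect_equal(attr(s, "rearranged"), c(TRUE, TRUE, FALSE))
  expect_error(mapChromSet("Bxx"), "invalid chromosome")
  expect_error(mapChromSet("B11"), "invalid chromosome")
})

test_that("composition matrix maps dosages to labels, ordered by anchor", {
  calls <- dosageCalls(
    matrix(c(2L, 3L, 0L, NA), 2, 2,
           dimnames = list(c("Mb", "Ma"), c("s1", "s2"))),
    c(s1 = "tetraploid", s2 = "tetraploid"),
    chromB = c("B02", "B01"), posB = c(10L, 5L))
  mat <- buildCompositionMatrix(calls)
  lab <- SummarizedExperiment::assay(mat, "composition")
  expect_equal(rownames(lab), c("Ma", "Mb"))        # sorted by (set, pos)
  expect_equal(lab["Mb", "s1"], "AABB")
  expect_equal(lab["Ma", "s1"], "AAAB")
  expect_equal(lab["Mb", "s2"], "BBBB")
  expect_equal(lab["Ma", "s2"], "missing")

  shuffled <- calls[c(2, 1), ]
  expect_equal(SummarizedExperiment::assay(buildCompositionMatrix(shuffled),
                                           "composition"), lab)

  dup <- calls
  rownames(dup) <- c("Ma", "Ma")
  expect_error(buildCompositionMatrix(dup), "duplicate")
})

mkMatrix <- function(lab, chromB, posB) {
  roles <- setNames(rep("tetraploid", ncol(lab)), colnames(lab))
  d <- matrix(match(lab, c("BBBB", "ABBB", "AABB", "AAAB", "AAAA")) - 1L,
              nrow(lab), ncol(lab), dimnames = dimnames(lab))
  buildCompositionMatrix(dosageCalls(d, roles, chromB = chromB, posB = posB))
}

test_that("unbalanced fractions normalize by markers per set (and individuals)", {
  lab <- matrix("AABB", 20, 2, dimnames = list(paste0("M", 1:20), c("s1", "s2")))
  mat <- mkMatrix(lab, rep("B01", 20), 1:20)
  expect_true(all(unbalancedFraction(mat)$fraction == 0))

  lab[1:10, "s1"] <- "AAAA"
  mat <- mkMatrix(lab, rep("B01", 20), 1:20)
  uf <- unbalancedFraction(mat, samples = "s1", perIndividual = TRUE)
  expect_equal(uf$fraction[uf$state == "AAAA"], 0.5)

  lab[1:10, "s2"] <- "AAAA"
  mat <- mkMatrix(lab, rep("B01", 20), 1:20)
  expect_equal(unbalancedFraction(mat, perIndividual = FALSE)$fraction[
    unbalancedFraction(mat)$state == "AAAA"], 1.0)  # summed over individuals
  expect_equal(unbalancedFraction(mat, perIndividual = TRUE)$fraction[
    unbalancedFraction(mat)$state == "AAAA"], 0.5)
  expect_true(all(unbalancedFraction(mat)$fraction >= 0))
})

test_that("transition records track parent-child state changes per marker", {
  lab <- cbind(g0 = c("AABB", "AABB"), g1 = c("AAAB", "AABB"),
               g2 = c("AAAA", "AABB"))
  rownames(lab) <- c("M1", "M2")
  mat <- mkMatrix(lab, c("B01", "B01"), c(1L, 2L))
  ped <- data.frame(id = c("g0", "g1", "g2"),
                    parentId = c(NA, "g0", "g1"), generation = 0:2)
  ts <- transitionStats(mat, ped)
  r <- ts$records
  expect_true(any(r$fromState == "AABB" & r$toState == "AAAB" & r$childId == "g1"))
  expect_true(any(r$fromState == "AAAB" & r$toState == "AAAA" & r$childId == "g2"))
  expect_equal(sum(r$nMarkers), 4)
  stab <- ts$summary
  expect_equal(stab$stabilityRate[stab$fromState == "AABB"], 2 / 3)

  # ungenotyped parents are skipped with a log message
  ped2 <- rbind(ped, data.frame(id = "gX", parentId = "gZ", generation = 3))
  expect_message(transitionStats(mat, ped2), "skipping")
})

test_that("simulated absorbing states never transition", {
  lin <- simulateLineage(balancedMap(tinyLengths, 4L, 0L), 6, pHE = 1,
                        breakpointRate = 0.5, seed = 61)
  maps <- compositionMaps(lin)
  ind <- individuals(lin)
  pos <- seq(1000L, 49000L, by = 1000L)
  lab <- vapply(ind$id, function(id) {
    seg <- segments(maps[[id]])
    gr <- GenomicRanges::GRanges("B01", IRanges::IRanges(pos, width = 1))
    hit <- GenomicRanges::findOverlaps(gr, seg)
    dosageLabel <- c("BBBB", "ABBB", "AABB", "AAAB", "AAAA")
    dosageLabel[seg$aCopies[S4Vectors::subjectHits(hit)] + 1L]
  }, character(length(pos)))
  rownames(lab) <- paste0("M", seq_along(pos))
  mat <- mkMatrix(lab, rep("B01", length(pos)), pos)
  ts <- transitionStats(mat, ind[, c("id", "parentId", "generation")])
  expect_equal(ts$summary$stabilityRate[ts$summary$fromState == "AAAA"], 1.0)
  expect_equal(unique(ts$records$fromState), "AAAA")
})

test_that("flower colour follows A-allele dominance with BBBB silencing", {
  expect_equal(flowerColorPredict("AABB"),
               c(yellow = 1, orange = 0, white = 0))
  expect_equal(flowerColorPredict("AAAA"),
               c(yellow = 1, orange = 0, white = 0))
  expect_equal(flowerColorPredict("BBBB", 0),
               c(yellow = 0, orange = 1, white = 0))
  expect_equal(flowerColorPredict("BBBB", 0.3),
               c(yellow = 0, orange = 0.7, white = 0.3))
  expect_error(flowerColorPredict("ABAB"), "state")
})

test_that("PCA separates ploidy on PC1 with diploid controls at the extremes", {
  set.seed(62)
  nM <- 40
  dur <- matrix(4L, nM, 2)                       # rescaled duranensis
  ipa <- matrix(0L, nM, 2)                       # rescaled ipaensis
  tet <- matrix(2L, nM, 6)
  tet[1:10, 1:3] <- 3L; tet[11:20, 4:6] <- 1L    # two composition groups
  d <- cbind(dur, ipa, tet)
  colnames(d) <- c("d1", "d2", "i1", "i2", paste0("t", 1:6))
  rownames(d) <- paste0("M", 1:nM)
  roles <- setNames(c("duranensis", "duranensis", "ipaensis", "ipaensis",
                      rep("tetraploid", 6)), colnames(d))
  calls <- dosageCalls(d, roles, chromB = "B01", posB = 1:nM)
  p <- pcaScores(calls)
  expect_true(all(diff(p$percentVar) <= 1e-9))
  expect_lte(sum(p$percentVar), 100 + 1e-9)
  pc1 <- setNames(p$scores$PC1, p$scores$sample)
  expect_equal(unname(pc1["d1"]), unname(pc1["d2"]))  # duplicates coincide
  # diploids flank the tetraploids on PC1
  lo <- min(pc1[c("d1", "i1")]); hi <- max(pc1[c("d1", "i1")])
  expect_true(all(pc1[paste0("t", 1:6)] > lo & pc1[paste0("t", 1:6)] < hi))

  expect_error(pcaScores(dosageCalls(matrix(2L, 5, 3,
    dimnames = list(paste0("M", 1:5), c("a", "b", "c"))),
    setNames(rep("tetraploid", 3), c("a", "b", "c")),
    chromB = "B01", posB = 1:5)), "degenerate")
})
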