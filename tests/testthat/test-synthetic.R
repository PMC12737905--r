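# synthetic polyploid generator: parents, segregation, lineages, read
# counts, array signals and phenotypes

test_that("simulateParents draws diagnostic sites at the requested rate, deterministically", {
  pp <- simulateParents(2, 1e5, 0.005, seed = 1)
  gr <- abSites(pp)
  expect_true(all(gr$aAllele != gr$bAllele))
  # expected ~500 sites/chrom; binomial 4-sigma band
  perChrom <- table(as.character(GenomeInfoDb::seqnames(gr)))
  expect_true(all(abs(perChrom - 500) < 4 * sqrt(500)))
  pos <- split(GenomicRanges::start(gr), as.character(GenomeInfoDb::seqnames(gr)))
  expect_true(all(vapply(pos, function(p) !is.unsorted(p, strictly = TRUE), TRUE)))

  expect_identical(pp, simulateParents(2, 1e5, 0.005, seed = 1))
  expect_false(identical(pp, simulateParents(2, 1e5, 0.005, seed = 2)))

  expect_length(abSites(simulateParents(2, 1e4, 0, seed = 1)), 0)
  expect_error(simulateParents(2, -5, 0.005, seed = 1), "chromLen")
})

test_that("gamete dosage follows the disomic and tetrasomic laws", {
  expect_true(all(gameteSegmentDosage(2, "disomic", n = 50) == 1L))
  expect_true(all(gameteSegmentDosage(4, "disomic", n = 50) == 2L))
  expect_error(gameteSegmentDosage(3, "disomic"), "tetrasomic")

  # enumerated two-subsets of {A,A,A,B}: P(2)=1/2, P(1)=1/2;
  # of {A,A,B,B}: P(0)=1/6, P(1)=4/6, P(2)=1/6
  laws <- list(`3` = c(`0` = 0, `1` = 0.5, `2` = 0.5),
               `2` = c(`0` = 1 / 6, `1` = 4 / 6, `2` = 1 / 6))
  set.seed(42)
  for (a in names(laws)) {
    draws <- gameteSegmentDosage(as.integer(a), "tetrasomic", n = 20000)
    obs <- tabulate(draws + 1L, 3)
    law <- laws[[a]]
    expect_true(all(obs[law == 0] == 0))   # impossible outcomes never drawn
    p <- suppressWarnings(
      stats::chisq.test(obs[law > 0], p = law[law > 0])$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("selfing offspring law convolves the gamete law", {
  expect_equal(unname(offspringDosageDistribution(3)),
               c(0, 0, 0.25, 0.5, 0.25))
  expect_equal(unname(offspringDosageDistribution(2, pHE = 0)),
               c(0, 0, 1, 0, 0))
  # full multivalent pairing of AABB: classic autotetraploid ratios
  expect_equal(unname(offspringDosageDistribution(2, pHE = 1)),
               c(1, 8, 18, 8, 1) / 36)
  P <- selfingTransitionMatrix(0.3)
  expect_equal(rowSums(P), rep(1, 5))
  expect_equal(P[1, ], c(`0` = 1, `1` = 0, `2` = 0, `3` = 0, `4` = 0))
})

test_that("fixation probability from dosage 3 is 3/4 (martingale), by chain solve and simulation", {
  expect_equal(fixationProbability(3, pHE = 1), 0.75)
  expect_equal(fixationProbability(1, pHE = 1), 0.25)
  expect_equal(fixationProbability(2, pHE = 0.2), 0.5)
  ch <- simulateDosageChain(3, pHE = 1, nGenerations = 40,
                            nReplicates = 10000, seed = 7)
  final <- ch[, ncol(ch)]
  expect_gt(mean(final %in% c(0L, 4L)), 0.995)        # absorbed
  expect_lt(abs(mean(final == 4L) - 0.75), 3.5 * sqrt(0.75 * 0.25 / 1e4))
  # mean dosage is a martingale: generation means stay at 3
  expect_true(all(abs(colMeans(ch) - 3) < 0.07))
})

test_that("lineages are composition-invariant without exchange and absorbing at fixed states", {
  founder <- balancedMap(tinyLengths)
  lin <- simulateLineage(founder, 10, pHE = 0, breakpointRate = 0, seed = 3)
  for (m in compositionMaps(lin)) {
    seg <- segments(m)
    expect_true(all(seg$aCopies == 2L & seg$bCopies == 2L))
  }
  # dosage 0 and 4 never change in any descendant, even at pHE = 1
  for (a in c(0L, 4L)) {
    fixed <- balancedMap(tinyLengths, aCopies = a, bCopies = 4L - a)
    lin <- simulateLineage(fixed, 8, pHE = 1, breakpointRate = 1, seed = 5)
    for (m in compositionMaps(lin)) {
      seg <- segments(m)
      expect_true(all(seg$aCopies == a & seg$bCopies == 4L - a))
    }
  }
})

test_that("one selfing of an AAAB founder yields 1/4 AAAA, 1/2 AAAB, 1/4 AABB", {
  founder <- balancedMap(c(B01 = 1e4L), aCopies = 3L, bCopies = 1L)
  set.seed(11)
  out <- vapply(1:2000, function(i) {
    lin <- simulateLineage(founder, 1, pHE = 1, seed = sample.int(2^30, 1))
    segments(compositionMaps(lin)[["G1"]])$aCopies[1]
  }, integer(1))
  obs <- c(sum(out == 2L), sum(out == 3L), sum(out == 4L))
  expect_equal(sum(obs), 2000)  # only dosages 2..4 reachable in one step
  p <- suppressWarnings(stats::chisq.test(obs, p = c(0.25, 0.5, 0.25))$p.value)
  expect_gt(p, 0.001)
})

test_that("breakpoints split but segments still tile the genome", {
  founder <- balancedMap(tinyLengths)
  lin <- simulateLineage(founder, 10, pHE = 0.5, breakpointRate = 2, seed = 9)
  last <- compositionMaps(lin)[["G10"]]
  expect_true(validObject(last, test = TRUE))  # tiling enforced by validity
})

test_that("read counts follow the copy-ratio binomial model", {
  pp <- simulateParents(2, 5e4, 0.01, seed = 2)
  pureA <- balancedMap(tinyLengths, aCopies = 4L, bCopies = 0L)
  rc <- simulateReadCounts(pureA, pp, meanCov = 30, seed = 4)
  expect_true(all(rc$bCount == 0L))

  balanced <- balancedMap(tinyLengths)
  rc <- simulateReadCounts(balanced, pp, meanCov = 30, seed = 4)
  frac <- sum(rc$aCount) / sum(rc$aCount + rc$bCount)
  se <- 0.5 / sqrt(sum(rc$aCount + rc$bCount))
  expect_lt(abs(frac - 0.5), 3 * se)

  expect_identical(rc, simulateReadCounts(balanced, pp, meanCov = 30, seed = 4))
  expect_error(simulateReadCounts(balanced, pp, meanCov = 0), "meanCov")

  tiny <- simulateReadCounts(balanced, pp, meanCov = 1e-4, seed = 4)
  expect_true(all(tiny$missing[tiny$aCount + tiny$bCount == 0]))
  expect_gt(mean(tiny$missing), 0.99)

  # sites on a chromosome absent from the map are an invalid composition
  oneChrom <- balancedMap(tinyLengths[1])
  expect_error(simulateReadCounts(oneChrom, pp, meanCov = 30),
               "outside any segment")
})

test_that("array signals encode roles and dosage ratios", {
  pp <- simulateParents(1, 2e4, 0.01, seed = 6)
  roles <- c(dur = "duranensis", ipa = "ipaensis", m11 = "mix11",
             m31 = "mix31", m13 = "mix13", p1 = "tetraploid")
  maps <- list(p1 = balancedMap(c(B01 = 2e4L), aCopies = 3L, bCopies = 1L))
  sig <- simulateArraySignals(pp, roles, maps, noiseSd = 0, seed = 8)
  r <- SummarizedExperiment::assay(sig, "ratio")
  expect_true(all(r[, "dur"] == 1))
  expect_true(all(r[, "ipa"] == 0))
  expect_true(all(r[, "m31"] == 0.75))
  expect_true(all(r[, "m13"] == 0.25))
  expect_true(all(r[, "p1"] == 0.75))

  expect_identical(sig, simulateArraySignals(pp, roles, maps, noiseSd = 0, seed = 8))
  expect_error(simulateArraySignals(pp, c(x = "hexaploid")), "invalid role")
})

test_that("phenotypes follow the additive dosage model and flower-locus dominance", {
  lengths <- c(B01 = 1e4L, B02 = 1e4L, B03 = 1e4L, B04 = 1e4L,
               B05 = 1e4L, B06 = 1e4L)
  mk <- function(a, b) {  # state applied genome-wide
    founder <- balancedMap(lengths, aCopies = a, bCopies = b)
    new("Lineage",
        individuals = data.frame(id = "G0", parentId = NA_character_,
                                 generation = 0L,
                                 selectionClass = NA_character_),
        maps = list(G0 = founder), seed = 1L)
  }
  model <- defaultTraitModel(lengths, baseline = 0.10,
                             perExtraBEffect = 0.015, noiseSd = 0,
                             silencingProbBBBB = 0)
  # BBBB at the single seed locus: 0.10 + 0.015 * (4 - 2) = 0.13
  ph <- simulatePhenotypes(mk(0L, 4L), model, seed = 1)
  expect_equal(ph$seedWeight, 0.13)
  expect_equal(ph$flowerColor, "orange")

  expect_equal(simulatePhenotypes(mk(2L, 2L), model, seed = 1)$flowerColor, "yellow")
  expect_equal(simulatePhenotypes(mk(4L, 0L), model, seed = 1)$flowerColor, "yellow")
  expect_equal(simulatePhenotypes(mk(4L, 0L), model, seed = 1)$seedWeight,
               0.10 - 0.015 * 2)

  silenced <- defaultTraitModel(lengths, noiseSd = 0, silencingProbBBBB = 1)
  expect_equal(simulatePhenotypes(mk(0L, 4L), silenced, seed = 1)$flowerColor,
               "white")
})
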