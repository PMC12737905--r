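## Response to divergent seed-weight selection: the heavy-minus-light delta
## statistic, assumption-checked group tests, and the tetraploid-vs-diploid
## selection-response simulation experiment.

#' Heavy-minus-light seed-weight difference
#'
#' Computes the selection-response statistic Delta = mean(heavy) -
#' mean(light) in g/seed for one population, pooling records across years
#' (per-plant mean seed weights) to absorb yearly environmental effects.
#' Average-class plants do not enter Delta.
#'
#' @param records phenotype data.frame with columns `plantId`, `population`,
#'   `year`, `selectionClass` (`heavy`/`average`/`light`) and `seedWeight`
#'   (g/seed).
#' @param population population to summarize (`NULL` = use all records).
#' @param poolYears pool each plant's records across years into one
#'   per-plant mean before averaging (default), else treat each plant-year
#'   as one observation.
#' @return list with `population`, `meanHeavy`, `meanLight`, `delta`,
#'   `nHeavy`, `nLight`.
#' @examples
#' rec <- data.frame(plantId = c("h1", "h2", "l1", "l2"),
#'                   population = "ipadur1", year = 3,
#'                   selectionClass = c("heavy", "heavy", "light", "light"),
#'                   seedWeight = c(0.16, 0.16, 0.11, 0.10))
#' selectionDelta(rec, "ipadur1")$delta  # 0.055
#' @export
selectionDelta <- function(records, population = NULL, poolYears = TRUE) {
  if (!is.null(population)) records <- records[records$population == population, ]
  records <- records[!is.na(records$seedWeight), ]
  classMean <- function(cls) {
    r <- records[records$selectionClass == cls & !is.na(records$selectionClass), ]
    if (!nrow(r)) stopf("undefined delta: no '%s'-class records%s", cls,
                        if (is.null(population)) "" else paste0(" for ", population))
    w <- if (poolYears) tapply(r$seedWeight, r$plantId, mean) else r$seedWeight
    c(mean = mean(w), n = length(w))
  }
  h <- classMean("heavy"); l <- classMean("light")
  list(population = population %||% "all", meanHeavy = unname(h["mean"]),
       meanLight = unname(l["mean"]), delta = unname(h["mean"] - l["mean"]),
       nHeavy = unname(h["n"]), nLight = unname(l["n"]))
}

## Dunn's post-hoc z tests after Kruskal-Wallis (two-sided, tie-corrected)
dunnTest <- function(x, g, method = "holm") {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lev <- levels(g)
  cmp <- t(combn(lev, 2))
  z <- apply(cmp, 1L, function(p) {
    (mr[[p[1]]] - mr[[p[2]]]) /
      sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[[p[1]]] + 1 / n[[p[2]]]))
  })
  p <- p.adjust(2 * pnorm(-abs(z)), method = method)
  data.frame(group1 = cmp[, 1], group2 = cmp[, 2], z = z, p = p,
             stringsAsFactors = FALSE)
}

## compact letter display from a pairwise data.frame(group1, group2, p):
## groups in a maximal clique of "not significantly different" share a letter
letterDisplay <- function(pairs, groups, means, alpha = 0.05) {
  k <- length(groups)
  ns <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairs)))
    ns[pairs$group1[i], pairs$group2[i]] <- ns[pairs$group2[i], pairs$group1[i]] <-
      pairs$p[i] >= alpha
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(0:(k - 1))) > 0))
  isClique <- vapply(subsets, function(s)
    all(ns[s, s, drop = FALSE]), logical(1))
  cl <- subsets[isClique]
  maximal <- cl[vapply(seq_along(cl), function(i)
    !any(vapply(cl[-i], function(o) all(cl[[i]] %in% o), logical(1))), logical(1))]
  ord <- order(-vapply(maximal, function(s) max(means[s]), numeric(1)))
  maximal <- maximal[ord]
  out <- setNames(rep("", k), groups)
  for (i in seq_along(maximal))
    out[maximal[[i]]] <- paste0(out[maximal[[i]]], letters[i])
  out[order(-means)]
}

#' Assumption-checked group comparison report
#'
#' Runs the standard phenotypic-trait comparison: Shapiro-Wilk normality of
#' the model residuals and Levene's homoscedasticity test decide between the
#' parametric path (ANOVA with Tukey's post hoc) and the non-parametric path
#' (Kruskal-Wallis with Dunn's post hoc, Holm-adjusted). Returns a compact
#' letter display over the groups and the adjusted R-squared of the linear
#' regression of the trait on group.
#'
#' @param data data.frame holding the trait and grouping columns.
#' @param trait,group column names.
#' @param alpha significance level for assumption checks and letters.
#' @return list: `normalityP`, `leveneP`, `method` (`"anova"` or
#'   `"kruskal"`), `omnibusP`, `posthoc` (pairwise data.frame), `letters`,
#'   `adjRsquared`.
#' @export
statsReport <- function(data, trait, group, alpha = 0.05) {
  x <- data[[trait]]; g <- factor(data[[group]])
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  sizes <- table(g)
  if (length(sizes) < 2L || any(sizes < 2L))
    stopf("need >= 2 groups with >= 2 observations each (got: %s)",
          paste(names(sizes), sizes, sep = "=", collapse = ", "))
  fit <- lm(x ~ g)
  res <- stats::residuals(fit)
  normP <- if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0)
    shapiro.test(res)$p.value else NA_real_
  levP <- tryCatch(car::leveneTest(x ~ g)[1, "Pr(>F)"], error = function(e) NA_real_)
  parametric <- isTRUE(normP > alpha) && (is.na(levP) || levP > alpha)
  means <- tapply(x, g, mean)
  if (parametric) {
    a <- aov(x ~ g)
    omni <- summary(a)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(a)$g
    cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    posthoc <- data.frame(group1 = cmp[, 1], group2 = cmp[, 2],
                          p = tk[, "p adj"], stringsAsFactors = FALSE)
    method <- "anova"
  } else {
    omni <- kruskal.test(x, g)$p.value
    posthoc <- dunnTest(x, g)
    method <- "kruskal"
  }
  letters <- letterDisplay(posthoc, levels(g), means, alpha)
  list(normalityP = normP, leveneP = levP, method = method, omnibusP = omni,
       posthoc = posthoc, letters = letters,
       adjRsquared = summary(fit)$adj.r.squared)
}

## advance one tetraploid lineage a generation under truncation selection:
## generate nCandidates selfed seeds, phenotype their seed weight, keep the
## heaviest (heavy class) or lightest (light class); "none" keeps a random one
advanceLineage <- function(df, class, model, pHE, breakpointRate, chromLengths,
                           nCandidates) {
  cands <- lapply(seq_len(nCandidates),
                  function(i) selfStep(df, pHE, breakpointRate, chromLengths))
  w <- vapply(cands, function(cd)
    genotypicSeedWeight(cd, model) + rnorm(1, 0, model@noiseSd), numeric(1))
  pick <- switch(class, heavy = which.max(w), light = which.min(w),
                 sample.int(nCandidates, 1L))
  cands[[pick]]
}

## additive genotypic value on the internal segment frame
genotypicSeedWeight <- function(df, model) {
  extraB <- 0L
  for (i in seq_along(model@seedLoci)) {
    loc <- model@seedLoci[i]
    chr <- as.character(seqnames(loc))
    mid <- (GenomicRanges::start(loc) + GenomicRanges::end(loc)) %/% 2L
    seg <- df[df$chrom == chr & df$start <= mid & df$end >= mid, ]
    if (!nrow(seg)) stopf("seed locus outside the simulated chromosome sets")
    extraB <- extraB + (seg$b[1L] - 2L)
  }
  model@baseline + model@perExtraBEffect * extraB
}

#' Tetraploid-vs-diploid selection-response experiment
#'
#' Simulates divergent truncation selection on seed weight in a
#' neoallotetraploid population segregating through homoeologous exchange,
#' against diploid control populations with no heritable variance. A
#' population of `3 * nLineages` balanced-AABB founders undergoes `burnIn`
#' generations of unselected single-seed descent, during which standing
#' composition variation accumulates via `pHE`. At selection onset each
#' lineage is phenotyped once and lineages are ranked by seed weight: the
#' heaviest `nLineages` become the heavy class and the lightest the light
#' class (the middle third is the unselected average class), mirroring
#' selection programmes in which whole lineages are consistently assigned
#' to a class by their observed seed size. Each selected lineage then
#' advances `nGenerations` further by within-family truncation: its
#' `nCandidates` candidate seeds are phenotyped and the heaviest (heavy
#' class) or lightest (light class) is the single seed advanced. Diploid
#' control lineages carry a fixed genotypic value, so both ranking and
#' truncation act on environmental noise only and leave no heritable
#' response. The response statistic is Delta = mean(final heavy) -
#' mean(final light) in g/seed, measured with fresh phenotyping noise.
#'
#' @param pHE per-meiosis multivalent-pairing probability.
#' @param perExtraBEffect seed-weight effect (g) per extra B copy.
#' @param breakpointRate expected new segment breakpoints per chromosome
#'   set per generation (the locus-level response does not depend on it).
#' @param nLineages lineages per selection class per population (>= 5).
#' @param nGenerations generations of truncation selection.
#' @param burnIn unselected selfing generations before selection starts.
#' @param nCandidates candidate seeds scored per plant per generation.
#' @param nReplicates independent replicates of the whole experiment.
#' @param selection with `FALSE`, selection is disabled: classes are
#'   assigned at random and a random seed is advanced each generation, so
#'   Delta is centred on zero.
#' @param chromLengths simulated chromosome-set lengths.
#' @param model a [TraitModel-class] (default [defaultTraitModel()]).
#' @param seed integer master seed.
#' @return list with `perReplicate` (data.frame: replicate,
#'   `deltaTetraploid`, `deltaDiploid`) and `summary` (means and 2.5/97.5%
#'   replicate quantiles).
#' @export
responseExperiment <- function(pHE = 0.1, perExtraBEffect = 0.015,
                               breakpointRate = 0,
                               nLineages = 10L, nGenerations = 3L,
                               burnIn = 12L, nCandidates = 6L,
                               nReplicates = 20L, selection = TRUE,
                               chromLengths = setNames(rep(1e6L, 10),
                                                       sprintf("B%02d", 1:10)),
                               model = NULL, seed = 1L) {
  if (nLineages < 5L) stopf("nLineages must be >= 5 per class")
  if (is.null(model))
    model <- defaultTraitModel(chromLengths,
                               perExtraBEffect = perExtraBEffect)
  else model@perExtraBEffect <- perExtraBEffect
  seeds <- splitSeed(seed, nReplicates)
  founder <- segFrame(balancedMap(chromLengths))
  oneReplicate <- function(rseed) {
    withSeed(rseed, {
      nPop <- 3L * nLineages
      pop <- lapply(seq_len(nPop), function(i) {
        df <- founder
        for (gge in seq_len(burnIn))
          df <- selfStep(df, pHE, breakpointRate, chromLengths)
        df
      })
      # rank lineages by observed seed weight; extremes form the classes
      onset <- vapply(pop, function(df)
        genotypicSeedWeight(df, model) + rnorm(1, 0, model@noiseSd), numeric(1))
      o <- if (selection) order(onset) else sample.int(nPop)
      classFinal <- function(idx, class) {
        if (!selection) class <- "average"   # random advancement
        vapply(pop[idx], function(df) {
          for (gge in seq_len(nGenerations))
            df <- advanceLineage(df, class, model, pHE, breakpointRate,
                                 chromLengths, nCandidates)
          genotypicSeedWeight(df, model) + rnorm(1, 0, model@noiseSd)
        }, numeric(1))
      }
      dTet <- mean(classFinal(o[(nPop - nLineages + 1L):nPop], "heavy")) -
              mean(classFinal(o[seq_len(nLineages)], "light"))
      # diploid controls: fixed homozygous genotype, so ranking and
      # truncation act on noise alone; the fresh final measurement is
      # baseline + noise for either class
      dDip <- mean(model@baseline + rnorm(nLineages, 0, model@noiseSd)) -
              mean(model@baseline + rnorm(nLineages, 0, model@noiseSd))
      c(deltaTetraploid = dTet, deltaDiploid = dDip)
    })
  }
  per <- t(vapply(seeds, oneReplicate, numeric(2)))
  perReplicate <- data.frame(replicate = seq_len(nReplicates), per)
  qs <- apply(per, 2L, stats::quantile, probs = c(0.025, 0.975))
  list(perReplicate = perReplicate,
       summary = data.frame(population = c("tetraploid", "diploid"),
                            meanDelta = colMeans(per),
                            lower = qs[1, ], upper = qs[2, ],
                            row.names = NULL))
}
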