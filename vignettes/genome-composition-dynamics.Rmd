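---
title: "Modelling genome-composition dynamics in a neoallotetraploid"
author: "tetradose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling genome-composition dynamics in a neoallotetraploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetradose)
```

# The system and the model

A neoallotetraploid carries two complete diploid genomes — here an
A subgenome (*Arachis duranensis*-like) and a B subgenome
(*A. ipaënsis*-like) — in one nucleus, with the balanced constitution
AABB. Chromosomes mostly pair with their homologs (disomic, diploid-like
inheritance), but in a segmental allotetraploid occasional homoeologous
(multivalent) pairing recombines the two subgenomes. The visible outcome
at any locus is its *dosage state*: the count of A vs B copies, AABB when
balanced, AAAB/ABBB when unbalanced, AAAA/BBBB when fixed to one parent,
and AAAAB-like states when aneuploidy adds or removes whole copies.

`tetradose` models the dosage state of a chromosome segment as a Markov
chain over A-dosage $a \in \{0,\dots,4\}$ under selfing:

* $a \in \{0, 4\}$: transmitted unchanged. Once a selfed lineage fixes a
  segment to one subgenome there is no route back — these states are
  absorbing.
* $a \in \{1, 3\}$: the four copies are treated as exchangeable
  (tetrasomic); a gamete receives 2 of the 4 homologs uniformly without
  replacement, i.e. a hypergeometric draw. Disomic pairing is undefined
  for odd dosage, and the package refuses it.
* $a = 2$: pairing is disomic (gamete gets exactly one A and one B) except
  with probability $p_\mathrm{HE}$ per meiosis, when the segment joins a
  multivalent and draws hypergeometrically. This encodes the "mostly
  bivalent, occasionally multivalent" behaviour of a segmental
  allotetraploid.

Offspring dosage is the sum of two independent gamete draws (the two
meioses of one selfing). We apply the $p_\mathrm{HE}$ decision per meiosis
rather than once per plant; nothing in the biology fixes this choice, and
at realistic $p_\mathrm{HE}$ the two conventions differ only at second
order.

Because each gamete's expected A-count is $a/2$, offspring dosage has
expectation $a$: mean dosage is a martingale. By optional stopping, a
segment starting at dosage 3 fixes AAAA with probability $3/4$ —
`fixationProbability(3)` computes the same number by solving the
absorption system of the transition matrix, and
`simulateDosageChain()` reproduces it by simulation. This is the
quantitative content of the observation that AAAA/BBBB states are stable
across generations while AAAB/ABBB states revert or fix.

```{r chain}
offspringDosageDistribution(3)        # 1/4 revert, 1/2 persist, 1/4 fix
fixationProbability(3)
```

# The synthetic-data generator

The generator is the package's stand-in for the study system: two diverged
parental subgenomes, selfed tetraploid lineages, WGS read counts, array
signals with DNA-mixture controls, and dosage-linked phenotypes. Its
components and defaults:

* `simulateParents()` draws subgenome-diagnostic AB sites independently
  per bp. Chromosome sets are named after the B-genome assembly
  (`B01`, ...) because all coordinates in the pipeline are anchored to the
  B reference, mirroring analyses that map everything to the larger
  parental genome. A site rate of 0.005/bp on 10^5^–10^6^ bp sets gives
  hundreds to thousands of sites per set — enough for windowed inference
  while keeping test runtimes in seconds. Real subgenomes diverge at a
  similar order of magnitude, but the absolute rate is a desk-scale
  choice, not an estimate.
* `simulateLineage()` advances one individual per generation
  (single-seed descent, as in the greenhouse programme). Breakpoints
  arrive per set per generation as a Poisson count at rate
  `breakpointRate`, at uniform positions: no recombination map is
  published for this material, so uniformity is the neutral choice.
  Aneuploidy enters only through an explicit `nondisjunctionProb`
  (default 0), kept separate from $p_\mathrm{HE}$ because observed
  aneuploid plants are reported without a rate.
* $p_\mathrm{HE}$ is deliberately a free parameter — the study
  demonstrates exchange but does not quantify a per-generation rate. The
  package default of 0.1 makes exchange "rare but recurrent": over ~12
  generations of selfing roughly half of all initially balanced
  chromosome-scale segments have left the balanced state, which matches
  the qualitative picture of widespread but not universal composition
  shifts after many selfing generations.
* `simulateReadCounts()` models site depth as
  Poisson(meanCov · copies/4) and the A-read count as
  Binomial(depth, a/total). There is deliberately *no* mapping bias: on
  this generator mean normalized counts converge exactly to their
  expected profiles at high coverage, so the systematic underestimation
  seen in real mapped data is attributable to mapping, not to the
  normalization arithmetic.
* `simulateArraySignals()` produces A-signal fractions for plants and for
  the control classes used by genotyping arrays: pure diploid parents
  (1 and 0) and 1:1 / 3:1 / 1:3 DNA mixtures (0.5 / 0.75 / 0.25), with
  Gaussian noise clipped to [0, 1].
* `simulatePhenotypes()` uses an additive model: seed weight = baseline +
  effect · (B copies − 2) summed over seed-weight loci, plus Gaussian
  noise. The default places one locus on the distal 10% of set `B06`
  (the documented large-seed factor region) with baseline 0.13 g and
  effect 0.015 g per extra B copy, so the genotypic range
  (±2 B copies → ±0.03 g) brackets the seed weights reported for
  divergently selected material (~0.107–0.160 g/seed). Flower colour
  follows dominance at a locus on the top 10% of set `B05`: any A copy
  gives yellow; BBBB gives orange, or white with probability
  `silencingProbBBBB` (default 0.5 — "either orange or white" is all the
  data say). A transient white phenotype reported once in an AAAA plant
  is *not* modelled; only BBBB silencing is.

What the generator does **not** emulate — and therefore what passing
tests cannot certify about real data: mapping bias and error rates,
GC/mappability structure, a nonuniform recombination landscape,
outcrossing, scorer-specific artefacts of real array software, and any
genotype–environment interaction. Tests against this generator validate
the *inference machinery*, not the instruments.

# Numerical and procedural choices

**AB-site discovery.** Read-consensus calls use "at least" semantics
(fraction ≥ `minFrac`, default 0.95), so ties at the threshold are kept.
Fragment evidence is low-depth by nature (depth ≥ 1 suffices), so the
fragment consensus is a plain majority; requiring a 95% fraction of a
depth-2 pileup would be vacuous. Consensus is computed over all observed
alleles — candidate positions are not pre-reduced to biallelic. Indels are
out of scope.

**Normalization.** Per-sample mean coverage is the mean total count over
all AB sites; it is otherwise undefined in the source formulas. The
ratio-of-ratios makes the result invariant to any rescaling of a sample's
depth. Sites with a zero reference count are flagged missing and never
divided. Note a subtlety the recovery experiment respects: the (a/2, b/2)
expectation assumes the sample's mean coverage reflects the euploid
baseline, which holds when aberrant segments are a minority of the genome
(as in real plants). A genome that is wholly aneuploid would inflate its
own normalizer.

**Window classification.** Windows are defined by site count (default
`windowN = 200`; tests use 100 on smaller genomes) rather than bp, so
sparse regions keep statistical power. The window statistic is the median
of the normalized counts — robust to the occasional wild site. The call is
the nearest expected profile in Euclidean distance over a configurable
state alphabet; the default alphabet is the five euploid states plus the
four aneuploid configurations actually observed in sequenced plants
(AAAAA, AAAAB, AAAABB, AABBBB). Ties break toward euploid totals, then
toward smaller |A − B|: the profile (2, 0.5) is exactly equidistant from
AAAB and AAAA under a euploid-only alphabet, and the tie rule makes the
degradation deterministic — an AAAAB region collapses to AAAB, the same
artefact reported for fixed-ploidy genotype callers. Windows over 50%
missing are called `missing`. No HMM is used: windowed nearest-profile
classification is the minimal model consistent with density-style
evidence, and `mergeSegments()` (runs shorter than `minRun = 2` windows
absorbed into the nearer-profile flank, flagged) provides the contiguity.

**Array calling.** The published mixture-model scorer is not reproduced;
the defined stand-in assigns each sample the dosage minimizing
|ratio − d/4| and then rejects samples farther than `maxSd` (default 3)
pooled within-class standard deviations from their class centre. Raw
printed call tables can be ingested directly (`readRawCalls()`), which is
the intended path for reproducing published marker counts. Modal-score
criteria treat a tie that includes the required score as passing — the
source says only "modal score", and inclusive ties avoid discarding
informative markers. The 25% balanced-plants rule is inclusive (≥).
Rescaling diploid controls to 4/0 happens after filtering, as in the
source workflow.

**Composition summaries.** The per-set normalization of unbalanced-state
counts is ambiguous in its source ("normalized by the number of SNP
markers per chromosome") between a per-individual mean and a sum over
individuals; both are implemented (`perIndividual`, default the mean,
which keeps values interpretable as per-marker fractions). Transitions are
scored per marker, the order-free conservative choice, then aggregated.
PCA runs on centred, unscaled integer dosages — scaling is never stated,
and unscaled dosages preserve the ploidy axis that separates rescaled
diploid controls (all 4 vs all 0) at the PC1 extremes. Genetic groups are
pedigree-defined sets, not re-derived clusters: the pedigree is the
reproducible part of that classification.

**Selection statistics.** The Δ statistic is the difference of class
means of per-plant mean seed weights (g/seed), heavy minus light,
pooling all recorded years (the source pools "across years" without
listing them; per-year treatment is available via `poolYears = FALSE`).
Average-class plants never enter Δ. `statsReport()` follows the standard
agronomic decision tree: Shapiro–Wilk on residuals and Levene's test
choose between ANOVA + Tukey and Kruskal–Wallis + Dunn (Holm-adjusted);
the compact letter display marks groups sharing a maximal
not-significantly-different clique.

**The response experiment.** `responseExperiment()` contrasts a
tetraploid population segregating through HE with diploid controls that
have no heritable variance. Design choices mirror the greenhouse
programme: a burn-in of 12 unselected selfing generations (the material
entered selection at roughly its 13th selfing generation) lets standing
composition variation accumulate; lineages are then *assigned* to heavy
and light classes by ranking their observed seed weights (whole lineages
were consistently selected by seed size), and each class advances three
further generations by within-family truncation — the heaviest or
lightest of `nCandidates = 6` candidate seeds is the single seed
advanced. Final weights are measured with fresh noise. For diploids the
genotypic value is constant, so ranking and truncation act on noise alone
and the expected Δ is zero; the simulation draws that case directly from
its distribution. With `selection = FALSE` classes are assigned at random
and advancement is random, giving the null experiment.

# Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data sized for interactive use: genomes of 2–10 chromosome sets of
50–1000 kb, site rate 0.005/bp, 30× coverage (reference at 60×), windows
of 100–200 sites, dosage chains of 10^4^ replicates, and 20 replicates of
the selection experiment with 30 founder lineages each. These sizes give
Monte-Carlo errors comfortably inside the asserted tolerances; all
quantities scale to larger genomes without algorithmic change.

# Known limitations

* Segment dosage is the unit of inheritance; there is no chromatid-level
  crossover bookkeeping, so double exchanges within one segment and
  generation are not representable.
* Aneuploid segments are transmitted unchanged unless nondisjunction is
  enabled; no meiotic model for 5- or 6-copy segments is attempted.
* The windowed classifier has no positional smoothing across windows;
  breakpoints are localized to window resolution and sub-window segments
  are absorbed (flagged) rather than detected.
* The array-path stand-in is deliberately simple; it reproduces class
  structure, not the scorer's mixture-model behaviour on distorted
  clusters (e.g. markers collapsing to a diploid scale).
* Phenotypes are additive with Gaussian noise; epistasis, dominance at
  the seed-weight loci, and genotype-by-year interaction are not
  modelled.
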