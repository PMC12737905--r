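#' @import GenomicRanges
#' @import S4Vectors
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths seqinfo Seqinfo
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

## ---------------------------------------------------------------------------
## ParentalPair: diagnostic AB sites distinguishing the two parental subgenomes
## ---------------------------------------------------------------------------

#' Diagnostic sites of a pair of diverged parental subgenomes
#'
#' A `ParentalPair` holds the subgenome-diagnostic biallelic positions
#' (AB sites) of two parental genomes, anchored to the B-genome assembly:
#' width-1 genomic positions whose consensus allele differs between the
#' A-genome parent (e.g. *A. duranensis*) and the B-genome parent
#' (e.g. *A. ipaensis*).
#'
#' @slot abSites a [GenomicRanges::GRanges] of width-1 positions with metadata
#'   columns `aAllele` and `bAllele` (single bases, always different) and
#'   seqlengths set to the chromosome-set lengths.
#' @slot seed integer seed the object was generated from (`NA` for real data).
#' @export
setClass("ParentalPair",
  representation(abSites = "GRanges", seed = "integer"))

setValidity("ParentalPair", function(object) {
  gr <- object@abSites
  msg <- character()
  if (length(gr)) {
    mc <- S4Vectors::mcols(gr)
    if (!all(c("aAllele", "bAllele") %in% colnames(mc)))
      msg <- c(msg, "abSites must carry 'aAllele' and 'bAllele' columns")
    else if (any(mc$aAllele == mc$bAllele))
      msg <- c(msg, "every AB site must have aAllele != bAllele")
    if (any(GenomicRanges::width(gr) != 1L))
      msg <- c(msg, "AB sites must be width-1 positions")
    pos <- GenomicRanges::start(gr)
    byChrom <- split(pos, as.character(seqnames(gr)))
    if (any(vapply(byChrom, function(p) is.unsorted(p, strictly = TRUE), TRUE)))
      msg <- c(msg, "positions must be strictly increasing within a chromosome set")
  }
  if (anyNA(seqlengths(gr)))
    msg <- c(msg, "chromosome-set lengths (seqlengths) must be set")
  if (length(msg)) msg else TRUE
})

#' @describeIn ParentalPair accessor for the AB-site [GenomicRanges::GRanges].
#' @param x,object a `ParentalPair`.
#' @export
setGeneric("abSites", function(x) standardGeneric("abSites"))

#' @rdname ParentalPair
#' @export
setMethod("abSites", "ParentalPair", function(x) x@abSites)

#' @rdname ParentalPair
#' @export
setMethod("show", "ParentalPair", function(object) {
  cat("ParentalPair with", length(object@abSites), "AB sites on",
      length(seqlevels(object@abSites)), "chromosome set(s)\n")
  cat("  seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## CompositionMap: per-individual tiling of chromosome sets into dosage states
## ---------------------------------------------------------------------------

#' Genome-composition map of one individual
#'
#' A `CompositionMap` tiles every chromosome set of an individual into
#' contiguous segments labelled with subgenome copy numbers
#' `(aCopies, bCopies)`: the local count of A- and B-subgenome chromosomes.
#' Euploid tetraploid segments sum to 4 (AABB, AAAB, ...), diploid controls
#' to 2, and aneuploid segments to 3, 5 or 6.
#'
#' @slot segments a [GenomicRanges::GRanges] with integer metadata columns
#'   `aCopies` and `bCopies`; segments tile each chromosome set without gap or
#'   overlap (1-based inclusive coordinates, seqlengths set).
#' @export
setClass("CompositionMap", representation(segments = "GRanges"))

setValidity("CompositionMap", function(object) {
  gr <- object@segments
  msg <- character()
  mc <- S4Vectors::mcols(gr)
  if (!all(c("aCopies", "bCopies") %in% colnames(mc)))
    return("segments must carry integer 'aCopies' and 'bCopies' columns")
  tot <- mc$aCopies + mc$bCopies
  if (any(mc$aCopies < 0L | mc$bCopies < 0L))
    msg <- c(msg, "copy numbers must be non-negative")
  if (!all(tot %in% c(2L, 3L, 4L, 5L, 6L)))
    msg <- c(msg, "total copies per segment must be 2 (diploid) or 3..6 (tetraploid +/- aneuploidy)")
  sl <- seqlengths(gr)
  if (anyNA(sl)) return(c(msg, "chromosome-set lengths (seqlengths) must be set"))
  o <- order(as.factor(seqnames(gr)), GenomicRanges::start(gr))
  gr <- gr[o]
  for (chr in seqlevels(gr)) {
    g <- gr[seqnames(gr) == chr]
    if (!length(g)) { msg <- c(msg, paste0("chromosome set ", chr, " is untiled")); next }
    s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
    if (s[1] != 1L || e[length(e)] != sl[[chr]] ||
        (length(s) > 1 && any(s[-1] != e[-length(e)] + 1L)))
      msg <- c(msg, paste0("segments must tile chromosome set ", chr,
                           " without gap or overlap"))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CompositionMap accessor for the segment [GenomicRanges::GRanges].
#' @param x,object a `CompositionMap`.
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname CompositionMap
#' @export
setMethod("segments", "CompositionMap", function(x) x@segments)

#' @rdname CompositionMap
#' @export
setMethod("show", "CompositionMap", function(object) {
  gr <- object@segments
  lab <- dosageLabel(gr$aCopies, gr$bCopies)
  cat("CompositionMap:", length(gr), "segment(s) on",
      length(seqlevels(gr)), "chromosome set(s)\n")
  cat("  states:", paste(names(table(lab)), table(lab), sep = ":", collapse = " "), "\n")
})

#' Build a uniform (single-state) composition map
#'
#' Convenience constructor for founder individuals: every chromosome set is a
#' single segment with the same copy numbers, by default the balanced AABB
#' state of a fresh neoallotetraploid.
#'
#' @param chromLengths named integer vector of chromosome-set lengths (bp).
#' @param aCopies,bCopies copy numbers applied to every set.
#' @return a [CompositionMap-class].
#' @examples
#' balancedMap(c(B01 = 1e6, B02 = 1e6))
#' @export
balancedMap <- function(chromLengths, aCopies = 2L, bCopies = 2L) {
  if (is.null(names(chromLengths)))
    names(chromLengths) <- sprintf("B%02d", seq_along(chromLengths))
  gr <- GRanges(names(chromLengths),
                IRanges(1L, as.integer(chromLengths)),
                aCopies = as.integer(aCopies), bCopies = as.integer(bCopies),
                seqlengths = setNames(as.integer(chromLengths), names(chromLengths)))
  new("CompositionMap", segments = gr)
}

#' Construct a composition map from explicit segments
#'
#' @param chrom,start,end,aCopies,bCopies parallel vectors of segment
#'   coordinates (1-based inclusive) and copy numbers.
#' @param chromLengths named integer vector of chromosome-set lengths.
#' @return a [CompositionMap-class]; segments must tile each set.
#' @export
compositionMap <- function(chrom, start, end, aCopies, bCopies, chromLengths) {
  gr <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)),
                aCopies = as.integer(aCopies), bCopies = as.integer(bCopies),
                seqlengths = setNames(as.integer(chromLengths), names(chromLengths)))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  new("CompositionMap", segments = gr)
}

## internal plain-frame view used by the simulator hot loop
segFrame <- function(map) {
  gr <- segments(map)
  data.frame(chrom = as.character(seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             a = gr$aCopies, b = gr$bCopies, stringsAsFactors = FALSE)
}

frameToMap <- function(df, chromLengths) {
  compositionMap(df$chrom, df$start, df$end, df$a, df$b, chromLengths)
}

## ---------------------------------------------------------------------------
## Lineage: pedigree of selfed individuals with their composition maps
## ---------------------------------------------------------------------------

#' A selfing lineage under single-seed descent
#'
#' @slot individuals a data.frame with columns `id`, `parentId` (`NA` for the
#'   founder), `generation` (0-based) and `selectionClass`
#'   (`heavy`/`average`/`light` or `NA`).
#' @slot maps named list of [CompositionMap-class], one per individual.
#' @slot seed integer seed of the simulation (`NA` for real pedigrees).
#' @export
setClass("Lineage",
  representation(individuals = "data.frame", maps = "list", seed = "integer"))

setValidity("Lineage", function(object) {
  ind <- object@individuals
  msg <- character()
  need <- c("id", "parentId", "generation", "selectionClass")
  if (!all(need %in% colnames(ind)))
    return(paste("individuals needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(ind$id)) msg <- c(msg, "duplicate individual ids")
  if (!setequal(names(object@maps), ind$id))
    msg <- c(msg, "maps must be named by individual id")
  kid <- !is.na(ind$parentId)
  gen <- setNames(ind$generation, ind$id)
  if (any(kid & !(ind$parentId %in% ind$id)))
    msg <- c(msg, "parentId must reference an individual in the lineage")
  else if (any(ind$generation[kid] != gen[ind$parentId[kid]] + 1L))
    msg <- c(msg, "generation(child) must equal generation(parent) + 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn Lineage accessor for the pedigree table.
#' @param x,object a `Lineage`.
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname Lineage
#' @export
setMethod("individuals", "Lineage", function(x) x@individuals)

#' @describeIn Lineage accessor for the per-individual composition maps.
#' @export
setGeneric("compositionMaps", function(x) standardGeneric("compositionMaps"))

#' @rdname Lineage
#' @export
setMethod("compositionMaps", "Lineage", function(x) x@maps)

#' @rdname Lineage
#' @export
setMethod("show", "Lineage", function(object) {
  ind <- object@individuals
  cat("Lineage with", nrow(ind), "individual(s), generations",
      min(ind$generation), "-", max(ind$generation), "\n")
})

## ---------------------------------------------------------------------------
## TraitModel: dosage -> phenotype mapping
## ---------------------------------------------------------------------------

#' Dosage-to-phenotype model
#'
#' Encodes the additive seed-weight model (baseline plus a per-extra-B-copy
#' effect at designated loci, e.g. the large-seed factor at the distal end of
#' chromosome set 06) and the flower-colour locus at the top of chromosome
#' set 05, where any A copy gives yellow flowers and a pure-B (BBBB) state
#' gives orange, or white through dosage-imbalance silencing.
#'
#' @slot baseline baseline per-seed weight (g) of the balanced AABB genotype.
#' @slot perExtraBEffect seed-weight change (g) per B copy above 2 at each
#'   seed-weight locus.
#' @slot seedLoci [GenomicRanges::GRanges] of seed-weight loci.
#' @slot flowerLocus [GenomicRanges::GRanges] (length 1) flower-colour locus.
#' @slot noiseSd residual (environmental) s.d. of seed weight, g.
#' @slot silencingProbBBBB probability that a BBBB flower locus is silenced
#'   to white rather than expressing orange.
#' @export
setClass("TraitModel",
  representation(baseline = "numeric", perExtraBEffect = "numeric",
                 seedLoci = "GRanges", flowerLocus = "GRanges",
                 noiseSd = "numeric", silencingProbBBBB = "numeric"))

setValidity("TraitModel", function(object) {
  msg <- character()
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  p <- object@silencingProbBBBB
  if (p < 0 || p > 1) msg <- c(msg, "silencingProbBBBB must be in [0, 1]")
  if (length(object@flowerLocus) != 1L)
    msg <- c(msg, "flowerLocus must be a single range")
  if (length(msg)) msg else TRUE
})

#' Construct a trait model
#'
#' @param baseline,perExtraBEffect,noiseSd,silencingProbBBBB see
#'   [TraitModel-class]. Defaults place the balanced AABB genotype at
#'   0.13 g/seed with a 0.015 g effect per extra B copy, bracketing the
#'   seed weights observed in divergently selected neoallotetraploid
#'   populations.
#' @param seedLoci,flowerLocus `GRanges` of the seed-weight loci and the
#'   flower-colour locus.
#' @return a [TraitModel-class].
#' @export
traitModel <- function(baseline = 0.13, perExtraBEffect = 0.015,
                       seedLoci, flowerLocus, noiseSd = 0.01,
                       silencingProbBBBB = 0.5) {
  new("TraitModel", baseline = baseline, perExtraBEffect = perExtraBEffect,
      seedLoci = seedLoci, flowerLocus = flowerLocus, noiseSd = noiseSd,
      silencingProbBBBB = silencingProbBBBB)
}

#' Default trait model for a simulated genome
#'
#' Places one seed-weight locus on the distal 10% of chromosome set 06 (the
#' large-seed factor) and the flower-colour locus on the top 10% of set 05;
#' if the simulated genome has fewer sets, the last and second-to-last sets
#' are used instead.
#'
#' @param chromLengths named integer vector of chromosome-set lengths.
#' @param ... passed on to [traitModel()].
#' @return a [TraitModel-class].
#' @export
defaultTraitModel <- function(chromLengths, ...) {
  nm <- names(chromLengths)
  seedChr <- if ("B06" %in% nm) "B06" else nm[length(nm)]
  flowChr <- if ("B05" %in% nm) "B05" else nm[max(1L, length(nm) - 1L)]
  sl <- setNames(as.integer(chromLengths), nm)
  seedLen <- sl[[seedChr]]; flowLen <- sl[[flowChr]]
  seedLoci <- GRanges(seedChr,
                      IRanges(as.integer(ceiling(seedLen * 0.9)), seedLen),
                      seqlengths = sl)
  flowerLocus <- GRanges(flowChr,
                         IRanges(1L, as.integer(ceiling(flowLen * 0.1))),
                         seqlengths = sl)
  traitModel(seedLoci = seedLoci, flowerLocus = flowerLocus, ...)
}

#' @rdname TraitModel-class
#' @param object a `TraitModel`.
#' @export
setMethod("show", "TraitModel", function(object) {
  cat("TraitModel: baseline", object@baseline, "g;",
      object@perExtraBEffect, "g per extra B copy at",
      length(object@seedLoci), "locus/loci; noise sd", object@noiseSd, "g\n")
})

## ---------------------------------------------------------------------------
## Marker containers (SummarizedExperiment-backed)
## ---------------------------------------------------------------------------

#' Array-style marker signal table
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"ratio"`
#' (markers x samples, A-signal fraction in \[0, 1\]), `rowData` columns
#' `chromB`/`posB` anchoring markers to the B-genome assembly, and a
#' `colData` column `role` giving each sample's control class
#' (`duranensis`, `ipaensis`, `mix11`, `mix31`, `mix13`, `tetraploid`).
#'
#' @export
setClass("MarkerSignals", contains = "SummarizedExperiment")

setValidity("MarkerSignals", function(object) {
  msg <- character()
  if (!"ratio" %in% SummarizedExperiment::assayNames(object))
    return("assay 'ratio' is required")
  r <- assay(object, "ratio")
  if (any(r < 0 | r > 1, na.rm = TRUE)) msg <- c(msg, "ratios must lie in [0, 1]")
  if (!"role" %in% colnames(colData(object))) msg <- c(msg, "colData$role is required")
  if (length(msg)) msg else TRUE
})

#' Tetraploid dosage-call matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"dosage"`
#' holding integer A-allele dosages on the tetraploid 0-4 scale (`NA` =
#' missing), `rowData` columns `chromB`/`posB`, and `colData$role`.
#'
#' @export
setClass("DosageCalls", contains = "SummarizedExperiment")

setValidity("DosageCalls", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- assay(object, "dosage")
  if (!all(is.na(d) | d %in% 0:4)) return("dosages must be in {0..4} or NA")
  if (!"role" %in% colnames(colData(object))) return("colData$role is required")
  TRUE
})

#' @describeIn DosageCalls sample roles of a marker container.
#' @param x a `DosageCalls` or `MarkerSignals`.
#' @export
setGeneric("sampleRoles", function(x) standardGeneric("sampleRoles"))

#' @rdname DosageCalls
#' @export
setMethod("sampleRoles", "SummarizedExperiment",
          function(x) setNames(as.character(colData(x)$role), colnames(x)))
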