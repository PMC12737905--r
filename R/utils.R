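#' @importFrom methods new validObject is setClass setGeneric setMethod setValidity show slot
#' @importFrom stats rpois rbinom rhyper rnorm runif median prcomp shapiro.test
#'   kruskal.test aov TukeyHSD lm pnorm p.adjust setNames
#' @importFrom utils read.csv read.delim write.csv write.table combn
NULL

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Deterministically derive `n` child seeds (< 2^31) from one master seed, so
## every stochastic table can record the single integer it flowed from.
splitSeed <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Dosage label from copy numbers: (3,1) -> "AAAB", (4,2) -> "AAAABB".
dosageLabel <- function(aCopies, bCopies) {
  ifelse(is.na(aCopies) | is.na(bCopies), "missing",
         paste0(strrep("A", pmax(aCopies, 0L)), strrep("B", pmax(bCopies, 0L))))
}

## Integer A-dosage (0-4) -> five-state tetraploid label.
DOSAGE_LABELS <- c("BBBB", "ABBB", "AABB", "AAAB", "AAAA")

dosageToLabel <- function(dosage) {
  lab <- rep(NA_character_, length(dosage))
  ok <- !is.na(dosage) & dosage %in% 0:4
  lab[ok] <- DOSAGE_LABELS[dosage[ok] + 1L]
  lab[!ok] <- "missing"
  lab
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
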