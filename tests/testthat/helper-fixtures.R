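# small in-code fixtures shared across the suite

tinyLengths <- c(B01 = 5e4L, B02 = 5e4L)

# toy raw-call table for the control-mixture filter cascade: each of
# M2..M4 violates exactly one criterion, M1 passes all
toyCascadeCalls <- function(anchorM4 = TRUE) {
  samples <- c(paste0("m11_", 1:3), paste0("m31_", 1:3), paste0("m13_", 1:3),
               paste0("t", 1:10))
  roles <- setNames(c(rep("mix11", 3), rep("mix31", 3), rep("mix13", 3),
                      rep("tetraploid", 10)), samples)
  m1 <- c(2, 2, 2, 3, 3, 3, 1, 1, 1, 2, 2, 2, 3, 3, 1, 1, 2, 2, 2)  # passes
  m2 <- c(3, 3, 3, 3, 3, 3, 1, 1, 1, 2, 2, 2, 3, 3, 1, 1, 2, 2, 2)  # mix11 mode 3
  m3 <- c(2, 2, 2, 3, 3, 3, 1, 1, 1, NA, 2, 2, 3, 3, 1, 1, 2, 2, 2) # missing call
  m4 <- c(2, 2, 2, 3, 3, 3, 1, 1, 1, 2, 3, 3, 3, 3, 1, 1, 1, 3, 3)  # 10% at 2
  calls <- rbind(M1 = m1, M2 = m2, M3 = m3, M4 = m4)
  colnames(calls) <- samples
  mode(calls) <- "integer"
  dosageCalls(calls, roles, chromB = rep("B01", 4), posB = c(100L, 200L, 300L, 400L))
}

# composition map with one aberrant segment on B01 of a small AABB genome
aberrantMap <- function(aCopies, bCopies, lengths = tinyLengths) {
  seg <- data.frame(
    chrom = c("B01", "B01", names(lengths)[-1]),
    start = c(1L, lengths[[1]] %/% 2L + 1L, rep(1L, length(lengths) - 1L)),
    end = c(lengths[[1]] %/% 2L, lengths[[1]], unname(lengths[-1])),
    a = c(2L, aCopies, rep(2L, length(lengths) - 1L)),
    b = c(2L, bCopies, rep(2L, length(lengths) - 1L)))
  compositionMap(seg$chrom, seg$start, seg$end, seg$a, seg$b, lengths)
}

# normalized track with a prescribed per-site (A, B) profile per chromosome
constantTrack <- function(nSites, normA, normB, chrom = "B01") {
  data.frame(chrom = chrom, pos = seq_len(nSites),
             normalizedA = normA, normalizedB = normB,
             missing = FALSE, stringsAsFactors = FALSE)
}
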