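## Internal helpers shared across modules.

#' Draw random DNA sequences with a given GC fraction
#'
#' Bases are i.i.d.: C and G each with probability `gc/2`, A and T each with
#' probability `(1 - gc)/2`.
#'
#' @param n number of sequences
#' @param len integer vector of lengths (recycled to `n`)
#' @param gc GC fraction in \[0, 1\]
#' @return character vector of uppercase DNA sequences
#' @keywords internal
random_dna <- function(n, len, gc = 0.5) {
  stopifnot(gc >= 0, gc <= 1)
  len <- rep_len(len, n)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  total <- sum(len)
  bases <- sample(names(p), total, replace = TRUE, prob = p)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  seqs <- character(n)
  big <- paste(bases, collapse = "")
  substring(big, starts, ends)
}

#' Reverse-complement a DNA string (character in, character out)
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Derive a child RNG seed from a base seed and a stream label; keeps
## every generator independently reproducible and the seed < 2^31.
child_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 2654435761 + offs) %% 2147483647)
}

## substring of a genome (DNAStringSet) on 0-based half-open coordinates;
## returns NA_character_ if the window falls off the chromosome.
genome_sub <- function(genome, chrom, start0, end0) {
  if (!chrom %in% names(genome)) return(NA_character_)
  L <- length(genome[[chrom]])
  if (start0 < 0 || end0 > L || start0 >= end0) return(NA_character_)
  as.character(Biostrings::subseq(genome[[chrom]], start0 + 1L, end0))
}

## length-safe sampling: never falls into sample(n, 1) scalar semantics
resample <- function(x, size = 1L, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

## all k-mers over ACGT in lexicographic order
all_kmers <- function(k) {
  stopifnot(k >= 1, k <= 8)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  ## expand.grid varies the first column fastest; reverse for lexicographic
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}
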