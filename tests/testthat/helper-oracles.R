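## Independent naive oracles, deliberately written without the package's
## code paths (and without Biostrings matching).

## presence counts: per tag, scan every k-window once
oracle_kmer_presence <- function(tags, k) {
  motifs <- circrip:::all_kmers(k)
  counts <- setNames(integer(length(motifs)), motifs)
  for (tg in tags) {
    wins <- unique(substring(tg, seq_len(nchar(tg) - k + 1L),
                             seq_len(nchar(tg) - k + 1L) + k - 1L))
    wins <- wins[wins %in% motifs]
    counts[wins] <- counts[wins] + 1L
  }
  counts
}

## per-round z: mean / population sd across motifs
oracle_zscores <- function(counts_matrix) {
  apply(counts_matrix, 2L, function(x) {
    mu <- sum(x) / length(x)
    sdev <- sqrt(sum((x - mu)^2) / length(x))
    if (sdev == 0) rep(0, length(x)) else (x - mu) / sdev
  })
}

## overlapping occurrence count: position-by-position scan
oracle_occurrences <- function(s, motifs) {
  k <- nchar(motifs[1])
  n <- nchar(s)
  if (n < k) return(0L)
  wins <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  sum(wins %in% motifs)
}

## textbook Welch statistic
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  dof <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t_stat), dof)
  list(t = t_stat, dof = dof, p = p)
}

## reverse-complement without Biostrings
oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
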