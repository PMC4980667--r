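## SELEX-seq preprocessing and k-mer enrichment.

## Hamming distance between equal-length string vectors x and a single
## pattern; only used when mismatches are allowed.
hamming_to <- function(x, pattern) {
  k <- nchar(pattern)
  pat <- strsplit(pattern, "")[[1]]
  m <- do.call(rbind, strsplit(x, ""))
  rowSums(m != matrix(pat, nrow = length(x), ncol = k, byrow = TRUE))
}

#' Demultiplex SELEX-seq reads and trim them to sequence tags
#'
#' Reads are assigned to samples by their sample barcode (exact match by
#' default), the constant 5' and 3' PCR primers are trimmed, duplicates --
#' reads sharing an identical (random barcode, insert) pair -- are collapsed
#' to one tag, and inserts outside the accepted tag length range are
#' discarded. Reads matching no barcode are counted as unassigned.
#'
#' @param fastq_paths character vector of FASTQ paths (gzip allowed)
#' @param layout a [selex_layout()]
#' @param max_mismatch mismatches tolerated in barcode and primer matches
#'   (default 0, exact)
#' @return list with `pools` (named list, sample -> character vector of
#'   tags) and `stats` (data.table of per-reason read counts)
#' @export
demultiplex_and_trim <- function(fastq_paths, layout, max_mismatch = 0L) {
  stopifnot(inherits(layout, "selex_layout"))
  reads <- unlist(lapply(fastq_paths, function(p) {
    as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
  }), use.names = FALSE)
  n_total <- length(reads)
  rb_len <- layout$random_barcode_length
  bc_len <- nchar(layout$sample_barcodes[[1]])
  p5 <- layout$primer_5p
  p3 <- layout$primer_3p
  n5 <- nchar(p5)
  n3 <- nchar(p3)

  if (layout$random_barcode_side == "5p") {
    rb <- substr(reads, 1L, rb_len)
    body <- substr(reads, rb_len + 1L, nchar(reads))
  } else {
    rb <- substr(reads, nchar(reads) - rb_len + 1L, nchar(reads))
    body <- substr(reads, 1L, nchar(reads) - rb_len)
  }
  bc <- substr(body, 1L, bc_len)
  match_ok <- function(x, pattern) {
    if (max_mismatch == 0L) x == pattern
    else nchar(x) == nchar(pattern) & hamming_to(x, pattern) <= max_mismatch
  }
  sample_of <- rep(NA_character_, n_total)
  for (s in names(layout$sample_barcodes)) {
    hit <- is.na(sample_of) & match_ok(bc, layout$sample_barcodes[[s]])
    sample_of[hit] <- s
  }
  assigned <- !is.na(sample_of)
  after_bc <- substr(body, bc_len + 1L, nchar(body))
  ok5 <- match_ok(substr(after_bc, 1L, n5), p5)
  ok3 <- match_ok(substr(after_bc, nchar(after_bc) - n3 + 1L,
                         nchar(after_bc)), p3)
  insert <- substr(after_bc, n5 + 1L, nchar(after_bc) - n3)
  len_ok <- nchar(insert) >= layout$tag_length_range[1] &
    nchar(insert) <= layout$tag_length_range[2]

  keep <- assigned & ok5 & ok3 & len_ok
  pools <- list()
  n_dup <- 0L
  for (s in names(layout$sample_barcodes)) {
    idx <- which(keep & sample_of == s)
    key <- paste(rb[idx], insert[idx])
    first <- !duplicated(key)
    n_dup <- n_dup + sum(!first)
    pools[[s]] <- insert[idx][first]
  }
  stats <- data.table(
    reason = c("total", "unassigned_barcode", "primer_5p_mismatch",
               "primer_3p_mismatch", "length_out_of_range",
               "duplicate_random_barcode_insert", "retained"),
    n = c(n_total, sum(!assigned), sum(assigned & !ok5),
          sum(assigned & ok5 & !ok3), sum(assigned & ok5 & ok3 & !len_ok),
          n_dup, sum(vapply(pools, length, integer(1))))
  )
  list(pools = pools, stats = stats)
}

#' Count tags containing each k-mer
#'
#' Presence/absence semantics: a tag containing a motif several times still
#' contributes 1 to that motif's count. All 4^k motifs are reported,
#' including zeros.
#'
#' @param tags character vector of sequence tags (uppercase ACGT)
#' @param k motif length, 4 or 6
#' @param chunk_size tags per processing chunk (memory guard for k = 6)
#' @return named integer vector over all 4^k motifs (lexicographic order)
#' @export
count_kmer_presence <- function(tags, k = 4L, chunk_size = 20000L) {
  stopifnot(k %in% c(4L, 6L))
  motifs <- all_kmers(k)
  counts <- setNames(integer(length(motifs)), motifs)
  if (!length(tags)) return(counts)
  idx <- split(seq_along(tags), ceiling(seq_along(tags) / chunk_size))
  for (ii in idx) {
    freq <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(tags[ii]), width = k)
    counts <- counts + colSums(freq > 0L)[motifs]
  }
  counts
}

#' Per-round k-mer enrichment z-scores with cumulative ranking
#'
#' Within each round, a motif's z-score standardizes its tag count against
#' the mean and population standard deviation across all 4^k motifs of that
#' round; per-round z-scores therefore sum to zero. The cumulative z-score
#' sums the selection rounds named in `cumulative_rounds` and defines the
#' ranking (descending, lexicographic tie-break on the motif).
#'
#' @param counts_by_round numeric matrix, rows = all 4^k motifs (rownames),
#'   columns = rounds (colnames, e.g. R1..R4; a round-0 or control column
#'   may be present)
#' @param cumulative_rounds columns summed into `z_cumulative`; default all
#'   columns except any named "R0"
#' @return data.table ranked by decreasing z_cumulative: motif, one count_*
#'   and z_* column per round, z_cumulative
#' @export
kmer_zscores <- function(counts_by_round,
                         cumulative_rounds = setdiff(
                           colnames(counts_by_round), "R0")) {
  m <- as.matrix(counts_by_round)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("counts_by_round needs motif rownames and round colnames",
         call. = FALSE)
  z <- apply(m, 2L, function(x) {
    mu <- mean(x)
    sdev <- sqrt(mean((x - mu)^2))  # population sd: the 4^k motifs are all
    if (sdev == 0) {
      message("zero variance across motifs in a round; z set to 0")
      rep(0, length(x))
    } else (x - mu) / sdev
  })
  zc <- rowSums(z[, cumulative_rounds, drop = FALSE])
  out <- data.table(motif = rownames(m))
  for (cn in colnames(m)) out[, (paste0("count_", cn)) := m[, cn]]
  for (cn in colnames(m)) out[, (paste0("z_", cn)) := z[, cn]]
  out[, z_cumulative := zc]
  setorder(out, -z_cumulative, motif)
  out[]
}

#' Rank enriched motifs and export the heatmap table and top-motif list
#'
#' Keeps the `top_n` most and `bottom_n` least cumulatively enriched motifs
#' (the published display shows the top 20 and bottom 10), writes them as a
#' heatmap-ready TSV, and returns the top 10 motifs consumed by the
#' motif-density comparison.
#'
#' @param enrichments ranked table from [kmer_zscores()]
#' @param top_n,bottom_n rows kept from each end of the ranking
#' @param path optional TSV output path
#' @param top_motifs_path optional plain-text output (one motif per line)
#' @param n_top_motifs motifs in the exported top list (default 10)
#' @return list with `table` (top_n + bottom_n rows) and `top_motifs`
#' @export
rank_and_export <- function(enrichments, top_n = 20L, bottom_n = 10L,
                            path = NULL, top_motifs_path = NULL,
                            n_top_motifs = 10L) {
  enr <- as.data.table(enrichments)
  stopifnot(nrow(enr) >= top_n + bottom_n)
  tab <- rbind(head(enr, top_n), tail(enr, bottom_n))
  top_motifs <- head(enr$motif, n_top_motifs)
  if (!is.null(path)) fwrite(tab, path, sep = "\t")
  if (!is.null(top_motifs_path)) writeLines(top_motifs, top_motifs_path)
  list(table = tab, top_motifs = top_motifs)
}
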