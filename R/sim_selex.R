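#' SELEX-seq library layout
#'
#' Describes how a sequencing read is assembled around the selected insert:
#' an optional random barcode (for PCR-duplicate removal), a sample barcode
#' identifying the selection round, and constant PCR primers flanking the
#' insert. Simulated reads are laid out as
#' `[random barcode (5p)] [sample barcode] [primer_5p] [insert] [primer_3p]
#' [random barcode (3p)]`, with the random barcode on the side named by
#' `random_barcode_side`.
#'
#' @param sample_barcodes named character vector, sample -> barcode sequence
#' @param primer_5p,primer_3p constant primer sequences
#' @param random_barcode_length nt (default 5)
#' @param random_barcode_side "5p" or "3p"
#' @param tag_length_range accepted insert lengths after trimming
#' @return list of class `selex_layout`
#' @export
selex_layout <- function(sample_barcodes = c(R0 = "ACGT", R1 = "CGTA",
                                             R2 = "GTAC", R3 = "TACG",
                                             R4 = "AATT"),
                         primer_5p = "GGGAGAC",
                         primer_3p = "TCTCCCT",
                         random_barcode_length = 5L,
                         random_barcode_side = c("5p", "3p"),
                         tag_length_range = c(18L, 20L)) {
  random_barcode_side <- match.arg(random_barcode_side)
  if (is.null(names(sample_barcodes)) || anyDuplicated(sample_barcodes) ||
      any(!nzchar(sample_barcodes)))
    stop("sample_barcodes must be a named vector of unique non-empty ",
         "sequences", call. = FALSE)
  if (length(unique(nchar(sample_barcodes))) != 1L)
    stop("sample barcodes must share one length", call. = FALSE)
  if (tag_length_range[1] > tag_length_range[2])
    stop("tag_length_range must be c(min, max)", call. = FALSE)
  structure(list(sample_barcodes = sample_barcodes,
                 primer_5p = primer_5p, primer_3p = primer_3p,
                 random_barcode_length = as.integer(random_barcode_length),
                 random_barcode_side = random_barcode_side,
                 tag_length_range = as.integer(tag_length_range)),
            class = "selex_layout")
}

## summed weighted occurrence count of the affinity motifs per tag
affinity_score <- function(tags, weights) {
  xs <- Biostrings::DNAStringSet(tags)
  score <- numeric(length(tags))
  for (m in names(weights)) {
    score <- score + weights[[m]] * Biostrings::vcountPattern(m, xs)
  }
  score
}

#' Simulate SELEX selection rounds and write per-round FASTQ files
#'
#' Round 0 is a pool of `config$pool_size` uniform random 20-mers (the N20
#' pool). Each selection round keeps a tag with probability
#' `plogis(stringency_r * affinity)` where affinity is the summed weighted
#' occurrence count of `config$affinity_weights` motifs in the tag, then
#' resamples with replacement back to `pool_size` (PCR amplification).
#' Reads are written per round with the layout of [selex_layout()] and
#' constant Phred+33 qualities.
#'
#' @param config a [sim_config()]
#' @param layout a [selex_layout()]; must provide one sample barcode per
#'   round, named R0..R`rounds`
#' @param dir output directory for FASTQ files (created if missing)
#' @return list with `fastq_paths` (named by round), `layout`, and `truth`
#'   (list with `pools` = insert character vectors per round and
#'   `true_selex_motif` = highest-weight motif)
#' @export
simulate_selex <- function(config, layout = selex_layout(),
                           dir = tempfile("selex")) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "selex_layout"))
  if (config$pool_size < 1e4)
    stop("pool_size must be >= 10^4", call. = FALSE)
  if (!length(config$affinity_weights))
    stop("affinity_weights must be non-empty", call. = FALSE)
  rounds <- config$rounds
  want <- paste0("R", 0:rounds)
  if (!all(want %in% names(layout$sample_barcodes)))
    stop("layout must provide sample barcodes named ",
         paste(want, collapse = ", "), call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pools <- vector("list", rounds + 1L)
  names(pools) <- want
  withr::with_seed(child_seed(config$seed, "selex"), {
    pool <- random_dna(config$pool_size, 20L, gc = 0.5)
    pools[["R0"]] <- pool
    for (r in seq_len(rounds)) {
      sc <- affinity_score(pool, config$affinity_weights)
      p_survive <- stats::plogis(config$stringency_schedule[r] * sc)
      keep <- stats::runif(length(pool)) < p_survive
      survivors <- pool[keep]
      if (!length(survivors)) survivors <- pool  # degenerate guard
      pool <- sample(survivors, config$pool_size, replace = TRUE)
      pools[[paste0("R", r)]] <- pool
    }
    paths <- setNames(file.path(dir, paste0(want, ".fastq")), want)
    for (rn in want) {
      write_selex_fastq(pools[[rn]], rn, layout, paths[[rn]])
    }
  })
  top <- names(config$affinity_weights)[
    which.max(unlist(config$affinity_weights))]
  list(fastq_paths = paths, layout = layout,
       truth = list(pools = pools, true_selex_motif = top))
}

## assemble reads per the layout and write FASTQ (Phred+33, constant 'I')
write_selex_fastq <- function(inserts, sample, layout, path) {
  n <- length(inserts)
  rb <- random_dna(n, layout$random_barcode_length, gc = 0.5)
  core <- paste0(layout$sample_barcodes[[sample]], layout$primer_5p,
                 inserts, layout$primer_3p)
  reads <- if (layout$random_barcode_side == "5p") paste0(rb, core)
           else paste0(core, rb)
  xs <- Biostrings::DNAStringSet(reads)
  names(xs) <- sprintf("%s_read%07d", sample, seq_len(n))
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(xs, path, format = "fastq", qualities = qual)
  invisible(path)
}
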