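## Reading chimeric records from the TSV dialect and from SAM/BAM.

CHIM_COLS <- c("record_id", "library_id", "chrom_a", "start_a", "end_a",
               "strand_a", "chrom_b", "start_b", "end_b", "strand_b",
               "chimeric_score", "best_linear_score")

#' Read a chimeric record table
#'
#' Parses the 12-column TSV dialect written by [write_chimeric_table()]
#' (header required, coordinates 1-based inclusive) into the internal
#' 0-based half-open representation. Malformed rows are collected and
#' reported with their line numbers; with `strict = TRUE` they are fatal.
#'
#' @param path TSV path
#' @param strict error (instead of warn) on malformed rows
#' @return data.table of chimeric records; attribute `bad_rows` holds a
#'   data.table(line, reason) of rejected rows
#' @export
read_chimeric_table <- function(path, strict = FALSE) {
  raw <- fread(path, sep = "\t", colClasses = "character", header = TRUE)
  miss <- setdiff(CHIM_COLS, names(raw))
  if (length(miss))
    stop("chimeric table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  raw <- raw[, CHIM_COLS, with = FALSE]
  int_cols <- c("start_a", "end_a", "start_b", "end_b",
                "chimeric_score", "best_linear_score")
  conv <- raw[, lapply(.SD, function(x) suppressWarnings(as.integer(x))),
              .SDcols = int_cols]
  bad <- !stats::complete.cases(conv) |
    !raw$strand_a %in% c("+", "-") | !raw$strand_b %in% c("+", "-")
  bad_rows <- data.table(line = which(bad) + 1L,  # +1 for the header line
                         reason = "non-integer coordinate/score or bad strand")
  if (any(bad)) {
    msg <- paste0(sum(bad), " malformed row(s) at line(s) ",
                  paste(head(bad_rows$line, 10L), collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  rec <- data.table(
    record_id = raw$record_id, library_id = raw$library_id,
    chrom_a = raw$chrom_a, start_a = conv$start_a - 1L, end_a = conv$end_a,
    strand_a = raw$strand_a,
    chrom_b = raw$chrom_b, start_b = conv$start_b - 1L, end_b = conv$end_b,
    strand_b = raw$strand_b,
    chimeric_score = conv$chimeric_score,
    best_linear_score = conv$best_linear_score
  )[!bad]
  data.table::setattr(rec, "bad_rows", bad_rows)
  rec
}

## ---- SAM -------------------------------------------------------------------

#' Write simulated chimeric records as SAM
#'
#' Each record becomes a primary + supplementary alignment pair (SA-tagged,
#' soft-clipped so the clip structure encodes each segment's position in the
#' read) plus one secondary alignment carrying the best linear score in its
#' AS tag. Read sequences are taken from the genome, reverse-complemented
#' for minus-strand records, and SAM-stored in reference orientation.
#'
#' @param records chimeric record data.table (0-based half-open)
#' @param genome `DNAStringSet`
#' @param path output SAM path
#' @return `path`, invisibly
#' @export
write_chimeric_sam <- function(records, genome, path) {
  rec <- as.data.table(records)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  lines <- character(0)
  for (i in seq_len(nrow(rec))) {
    r <- rec[i]
    oh_a <- r$end_a - r$start_a
    oh_b <- r$end_b - r$start_b
    seq_a <- genome_sub(genome, r$chrom_a, r$start_a, r$end_a)
    seq_b <- genome_sub(genome, r$chrom_b, r$start_b, r$end_b)
    ## read = seg_a part then seg_b part, in transcript orientation;
    ## SAM stores SEQ in reference orientation per record
    minus_a <- r$strand_a == "-"
    minus_b <- r$strand_b == "-"
    read_seq <- paste0(if (minus_a) revcomp(seq_a) else seq_a,
                       if (minus_b) revcomp(seq_b) else seq_b)
    sam_seq_a <- if (minus_a) revcomp(read_seq) else read_seq
    sam_seq_b <- if (minus_b) revcomp(read_seq) else read_seq
    ## CIGARs: aligned block of seg_a covers read positions [0, oh_a);
    ## clip structure depends on the record's strand in SAM orientation
    cig_a <- if (minus_a) sprintf("%dS%dM", oh_b, oh_a)
             else sprintf("%dM%dS", oh_a, oh_b)
    cig_b <- if (minus_b) sprintf("%dM%dS", oh_b, oh_a)
             else sprintf("%dS%dM", oh_a, oh_b)
    flag_a <- if (minus_a) 16L else 0L
    flag_b <- (if (minus_b) 16L else 0L) + 2048L
    sa_a <- sprintf("SA:Z:%s,%d,%s,%s,60,0;", r$chrom_b, r$start_b + 1L,
                    r$strand_b, cig_b)
    sa_b <- sprintf("SA:Z:%s,%d,%s,%s,60,0;", r$chrom_a, r$start_a + 1L,
                    r$strand_a, cig_a)
    qual <- strrep("I", oh_a + oh_b)
    lines <- c(lines,
      sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tAS:i:%d\t%s",
              r$record_id, flag_a, r$chrom_a, r$start_a + 1L, cig_a,
              sam_seq_a, qual, r$chimeric_score, sa_a),
      sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tAS:i:%d\t%s",
              r$record_id, flag_b, r$chrom_b, r$start_b + 1L, cig_b,
              sam_seq_b, qual, r$chimeric_score, sa_b),
      ## secondary linear alignment carrying the best linear score
      sprintf("%s\t%d\t%s\t%d\t0\t%dM%dS\t*\t0\t0\t*\t*\tAS:i:%d",
              r$record_id, 256L + (if (minus_a) 16L else 0L),
              r$chrom_a, r$start_a + 1L, oh_a, oh_b, r$best_linear_score))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

## read-coordinate start of the aligned block, from the clip structure:
## leading clip for plus-strand records, trailing clip for minus-strand.
read_start_from_cigar <- function(cigar, minus) {
  lead <- trail <- integer(length(cigar))
  has_lead <- grepl("^\\d+[SH]", cigar)
  lead[has_lead] <- as.integer(sub("^(\\d+)[SH].*", "\\1", cigar[has_lead]))
  has_trail <- grepl("\\d+[SH]$", cigar)
  trail[has_trail] <- as.integer(sub(".*?(\\d+)[SH]$", "\\1",
                                     cigar[has_trail]))
  ifelse(minus, trail, lead)
}

## reference width consumed by a CIGAR (M/D/N/=/X)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    parts <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    w <- 0L
    for (p in parts) {
      n <- as.integer(sub("[A-Z=]$", "", p))
      op <- sub("^\\d+", "", p)
      if (op %in% c("M", "D", "N", "=", "X")) w <- w + n
    }
    w
  }, integer(1), USE.NAMES = FALSE)
}

#' Extract chimeric records from a SAM/BAM file
#'
#' Chimeric alignments are primary + supplementary (`SA`-tagged) pairs of the
#' same read. Segment order in the read is inferred from the soft/hard-clip
#' structure (leading clip on plus-strand records, trailing clip on minus).
#' The best linear score is the maximum AS among the read's non-SA-tagged
#' records; if none exists and a genome is supplied, an ungapped local
#' alignment (match +1 / mismatch -1) against the genomic window spanning
#' both segments +/- 500 nt is used as fallback.
#'
#' @param path SAM or BAM path
#' @param library_id library id to assign to all extracted records
#' @param genome optional `DNAStringSet` for the fallback linear scorer
#' @return chimeric record data.table (0-based half-open)
#' @export
extract_from_sam <- function(path, library_id = "sam", genome = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq"),
    tag = c("AS", "SA"))
  bam <- Rsamtools::scanBam(path, param = param)[[1]]
  n <- length(bam$qname)
  if (!n) return(extract_from_sam_empty())
  dt <- data.table(
    qname = bam$qname, flag = bam$flag, rname = as.character(bam$rname),
    pos = bam$pos, strand = as.character(bam$strand), cigar = bam$cigar,
    seq = as.character(bam$seq),
    AS = if (is.null(bam$tag$AS)) NA_integer_ else bam$tag$AS,
    SA = if (is.null(bam$tag$SA)) NA_character_ else bam$tag$SA
  )
  dt[, secondary := bitwAnd(flag, 256L) > 0L]
  chim <- dt[!is.na(SA) & !secondary]
  lin <- dt[is.na(SA)]
  out <- list()
  for (qn in unique(chim$qname)) {
    segs <- chim[qname == qn]
    if (nrow(segs) != 2L) {
      message("skipping read with ", nrow(segs), " chimeric segments: ", qn)
      next
    }
    minus <- segs$strand == "-"
    rs <- read_start_from_cigar(segs$cigar, minus)
    ord <- order(rs)
    segs <- segs[ord]
    minus <- minus[ord]
    w <- cigar_ref_width(segs$cigar)
    start0 <- segs$pos - 1L
    best_lin <- lin[qname == qn & !is.na(AS)]
    if (nrow(best_lin)) {
      bl <- max(best_lin$AS)
    } else if (!is.null(genome) && segs$rname[1] == segs$rname[2]) {
      bl <- fallback_linear_score(
        segs$seq[1], genome, segs$rname[1],
        min(start0) - 500L, max(start0 + w) + 500L)
    } else {
      bl <- NA_integer_
    }
    out[[length(out) + 1L]] <- chim_row(
      qn, library_id,
      segs$rname[1], start0[1], start0[1] + w[1], segs$strand[1],
      segs$rname[2], start0[2], start0[2] + w[2], segs$strand[2],
      max(segs$AS, na.rm = TRUE), bl)
  }
  if (!length(out)) return(extract_from_sam_empty())
  rbindlist(out)
}

extract_from_sam_empty <- function() {
  data.table(record_id = character(), library_id = character(),
             chrom_a = character(), start_a = integer(), end_a = integer(),
             strand_a = character(), chrom_b = character(),
             start_b = integer(), end_b = integer(), strand_b = character(),
             chimeric_score = integer(), best_linear_score = integer())
}

## best ungapped local alignment score of the read (either strand) against
## a genomic window; match +1 / mismatch -1.
fallback_linear_score <- function(read_seq, genome, chrom, w_start, w_end) {
  L <- length(genome[[chrom]])
  w_start <- max(0L, w_start)
  w_end <- min(L, w_end)
  window <- Biostrings::subseq(genome[[chrom]], w_start + 1L, w_end)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  sc <- function(s) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), window, type = "local",
      substitutionMatrix = mat, gapOpening = 1e6, gapExtension = 1e6,
      scoreOnly = TRUE)
  }
  as.integer(max(sc(read_seq),
                 sc(revcomp(read_seq))))
}
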