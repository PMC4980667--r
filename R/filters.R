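#' Filtering parameters for back-splice junction calling
#'
#' Defaults hold the published thresholds: junction overhang of at least
#' 12 nt, chimeric-vs-linear alignment score margin strictly greater than 2,
#' at least 30 junction reads in one library for high confidence, at least
#' 10 junction reads for the expression-based non-target group, and a
#' protein-coding host gene requirement for non-targets.
#'
#' @param min_overhang minimum overhang (shorter junction anchor), nt
#' @param score_margin records pass iff chimeric - linear score > this
#' @param high_conf_threshold junction reads (max over libraries) for
#'   high-confidence status
#' @param nontarget_min_count minimum expression junction count for the
#'   non-target group
#' @param require_biotype host-gene biotype required for non-targets
#' @return list of class `filter_params`
#' @export
filter_params <- function(min_overhang = 12L, score_margin = 2L,
                          high_conf_threshold = 30L,
                          nontarget_min_count = 10L,
                          require_biotype = "protein_coding") {
  stopifnot(min_overhang >= 0, score_margin >= 0, high_conf_threshold >= 0,
            nontarget_min_count >= 0)
  structure(list(min_overhang = as.integer(min_overhang),
                 score_margin = as.integer(score_margin),
                 high_conf_threshold = as.integer(high_conf_threshold),
                 nontarget_min_count = as.integer(nontarget_min_count),
                 require_biotype = require_biotype),
            class = "filter_params")
}

## ---- criterion predicates (vectorized over a records data.table) -----------

## C1: same chromosome, same strand, segments in reverse genomic order
## relative to read order. A plus-strand linear read has seg_a genomically
## before seg_b, so "reverse" means seg_a at/after seg_b's end; the minus
## strand mirrors.
criterion1 <- function(rec) {
  same <- rec$chrom_a == rec$chrom_b & rec$strand_a == rec$strand_b
  rev_plus <- rec$start_a >= rec$end_b
  rev_minus <- rec$end_a <= rec$start_b
  same & ifelse(rec$strand_a == "+", rev_plus, rev_minus)
}

## C2: the shorter junction anchor is at least min_overhang nt
criterion2 <- function(rec, params) {
  pmin(rec$end_a - rec$start_a, rec$end_b - rec$start_b) >=
    params$min_overhang
}

## C3: chimeric score exceeds the best linear score by more than the margin
criterion3 <- function(rec, params) {
  ok <- (rec$chimeric_score - rec$best_linear_score) > params$score_margin
  ok & !is.na(ok)
}

## junction coordinates implied by an accepted record: the circle spans
## [acceptor_pos, donor_pos) with acceptor_pos the genomic-leftmost boundary
record_junction <- function(rec) {
  plus <- rec$strand_a == "+"
  data.table(
    chrom = rec$chrom_a,
    strand = rec$strand_a,
    acceptor_pos = ifelse(plus, rec$start_b, rec$start_a),
    donor_pos = ifelse(plus, rec$end_a, rec$end_b)
  )
}

#' Test whether a back-splice junction is annotated or canonical
#'
#' The annotated test asks whether `acceptor_pos` equals an annotated exon
#' start and `donor_pos` an annotated exon end of the same gene on the same
#' strand. The canonical test is strand-aware in back-splice orientation: on
#' the plus strand the genome must read `AG` immediately before
#' `acceptor_pos` and `GT` immediately after `donor_pos`; on the minus
#' strand the reverse-complement arrangement (`AC` before `acceptor_pos`,
#' `CT` after `donor_pos` in genome coordinates).
#'
#' @param chrom,strand,acceptor_pos,donor_pos junction coordinates (0-based
#'   half-open circle span, `acceptor_pos < donor_pos`)
#' @param genome `DNAStringSet`
#' @param annotation `circ_annotation`
#' @return list with `ok` (logical) and `label` in
#'   {"annotated", "canonical", "both", "neither"}
#' @export
canonical_or_annotated <- function(chrom, strand, acceptor_pos, donor_pos,
                                   genome, annotation) {
  ex <- annotation$exons
  hits <- ex[ex$chrom == chrom & ex$strand == strand &
               ex$start0 == acceptor_pos, gene_id]
  annotated <- length(hits) > 0L &&
    nrow(ex[ex$chrom == chrom & ex$strand == strand &
              ex$end0 == donor_pos & ex$gene_id %in% hits]) > 0L
  left <- genome_sub(genome, chrom, acceptor_pos - 2L, acceptor_pos)
  right <- genome_sub(genome, chrom, donor_pos, donor_pos + 2L)
  canonical <- if (is.na(left) || is.na(right)) FALSE
  else if (strand == "+") left == "AG" && right == "GT"
  else left == "AC" && right == "CT"
  label <- if (annotated && canonical) "both"
  else if (annotated) "annotated"
  else if (canonical) "canonical"
  else "neither"
  list(ok = annotated || canonical, label = label)
}

## side-wise C4 used when C1 fails and no single junction exists: each
## segment's junction-side boundary must be an annotated exon boundary of
## the matching kind on its own chromosome/strand, or carry the canonical
## flank. Reduces to the junction-level test when both segments agree.
criterion4_sidewise <- function(rec, genome, annotation) {
  ex <- annotation$exons
  n <- nrow(rec)
  out <- logical(n)
  for (i in seq_len(n)) {
    ## donor side = seg_a's transcript-end boundary
    if (rec$strand_a[i] == "+") {
      dpos <- rec$end_a[i]
      dann <- nrow(ex[ex$chrom == rec$chrom_a[i] & ex$strand == "+" &
                        ex$end0 == dpos]) > 0L
      dcan <- identical(genome_sub(genome, rec$chrom_a[i], dpos, dpos + 2L),
                        "GT")
    } else {
      dpos <- rec$start_a[i]
      dann <- nrow(ex[ex$chrom == rec$chrom_a[i] & ex$strand == "-" &
                        ex$start0 == dpos]) > 0L
      dcan <- identical(genome_sub(genome, rec$chrom_a[i], dpos - 2L, dpos),
                        "AC")
    }
    ## acceptor side = seg_b's transcript-start boundary
    if (rec$strand_b[i] == "+") {
      apos <- rec$start_b[i]
      aann <- nrow(ex[ex$chrom == rec$chrom_b[i] & ex$strand == "+" &
                        ex$start0 == apos]) > 0L
      acan <- identical(genome_sub(genome, rec$chrom_b[i], apos - 2L, apos),
                        "AG")
    } else {
      apos <- rec$end_b[i]
      aann <- nrow(ex[ex$chrom == rec$chrom_b[i] & ex$strand == "-" &
                        ex$end0 == apos]) > 0L
      acan <- identical(genome_sub(genome, rec$chrom_b[i], apos, apos + 2L),
                        "CT")
    }
    out[i] <- (dann || dcan) && (aann || acan)
  }
  out
}

#' Apply the four back-splice selection criteria
#'
#' A record is accepted iff all four hold: C1 same chromosome and strand
#' with the two segments in reverse genomic order relative to read order;
#' C2 junction overhang (the shorter segment) at least `params$min_overhang`
#' nt; C3 chimeric alignment score strictly more than `params$score_margin`
#' above the best linear score; C4 both splice sites annotated exon
#' boundaries or canonical splice dinucleotides. For records failing C1 the
#' junction is undefined, so C4 is evaluated side-wise per segment.
#'
#' @param records chimeric record data.table (0-based half-open)
#' @param genome `DNAStringSet`
#' @param annotation `circ_annotation`
#' @param params [filter_params()]
#' @return list with `accepted` (subset of `records`) and `flags`
#'   (data.table: record_id, library_id, C1..C4, accepted, reason)
#' @export
apply_filters <- function(records, genome, annotation,
                          params = filter_params()) {
  rec <- as.data.table(records)
  n <- nrow(rec)
  if (!n) {
    flags <- data.table(record_id = character(), library_id = character(),
                        C1 = logical(), C2 = logical(), C3 = logical(),
                        C4 = logical(), accepted = logical(),
                        reason = character())
    return(list(accepted = rec, flags = flags))
  }
  c1 <- criterion1(rec)
  c2 <- criterion2(rec, params)
  c3 <- criterion3(rec, params)
  ## bounds check: junction positions must lie inside the chromosome
  lens <- setNames(Biostrings::width(genome), names(genome))
  in_bounds <- rec$chrom_a %in% names(genome) &
    rec$chrom_b %in% names(genome) &
    rec$start_a >= 0L & rec$start_b >= 0L &
    rec$end_a <= lens[rec$chrom_a] & rec$end_b <= lens[rec$chrom_b]
  in_bounds[is.na(in_bounds)] <- FALSE
  c4 <- logical(n)
  jx <- record_junction(rec)
  for (i in seq_len(n)) {
    if (!in_bounds[i]) {
      c4[i] <- FALSE
    } else if (c1[i]) {
      c4[i] <- canonical_or_annotated(jx$chrom[i], jx$strand[i],
                                      jx$acceptor_pos[i], jx$donor_pos[i],
                                      genome, annotation)$ok
    } else {
      c4[i] <- criterion4_sidewise(rec[i], genome, annotation)
    }
  }
  acc <- c1 & c2 & c3 & c4 & in_bounds
  reason <- rep("accepted", n)
  reason[!c4] <- "C4:not annotated or canonical"
  reason[!c3] <- "C3:score margin"
  reason[!c2] <- "C2:overhang"
  reason[!c1] <- "C1:geometry"
  reason[!in_bounds] <- "out of chromosome bounds"
  flags <- data.table(record_id = rec$record_id,
                      library_id = rec$library_id,
                      C1 = c1, C2 = c2, C3 = c3, C4 = c4,
                      accepted = acc, reason = reason)
  list(accepted = rec[acc], flags = flags)
}
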