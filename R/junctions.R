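#' Count back-splice junctions from accepted records
#'
#' Records are grouped by exact junction coordinates (chrom, strand,
#' acceptor_pos, donor_pos) and counted per library. A record_id appearing
#' more than once within a library contributes a single count, so the sum of
#' all counts equals the number of distinct accepted (record_id, library_id)
#' pairs.
#'
#' @param accepted accepted chimeric record data.table (from
#'   [apply_filters()])
#' @return data.table with one row per (junction, library): chrom, strand,
#'   acceptor_pos, donor_pos, library_id, count (all counts >= 1)
#' @export
count_junctions <- function(accepted) {
  rec <- as.data.table(accepted)
  if (!nrow(rec))
    return(data.table(chrom = character(), strand = character(),
                      acceptor_pos = integer(), donor_pos = integer(),
                      library_id = character(), count = integer()))
  jx <- cbind(record_junction(rec),
              rec[, .(record_id, library_id)])
  jx <- unique(jx, by = c("record_id", "library_id"))
  counts <- jx[, .(count = .N),
               by = .(chrom, strand, acceptor_pos, donor_pos, library_id)]
  setorder(counts, chrom, acceptor_pos, donor_pos, library_id)
  counts[]
}

## host gene of a junction: prefer a gene with exons at both boundaries,
## else the same-strand gene whose span overlaps the junction most.
host_gene <- function(chrom_, strand_, a, d, annotation) {
  ex <- annotation$exons
  cand <- annotation$genes[chrom == chrom_ & strand == strand_ &
                             start0 < d & end0 > a]
  if (!nrow(cand)) return(NULL)
  exact <- cand$gene_id[vapply(cand$gene_id, function(g) {
    gex <- ex[gene_id == g]
    any(gex$start0 == a) && any(gex$end0 == d)
  }, logical(1))]
  if (length(exact)) return(annotation$genes[gene_id == exact[1]])
  ov <- pmin(cand$end0, d) - pmax(cand$start0, a)
  cand[which.max(ov)]
}

#' Annotate counted junctions and select high-confidence circRNA candidates
#'
#' Each distinct junction is annotated with its host gene, the exons of that
#' gene falling fully inside the circle span, and the circularized length
#' (sum of those exon lengths). Status is `high_confidence` when the maximum
#' per-library count reaches `params$high_conf_threshold` (i.e. in at least
#' one library), otherwise `detected`. Junctions with no overlapping gene are
#' retained as `intergenic` with zero exons and the genomic span as length.
#'
#' @param junctions counted junctions from [count_junctions()]
#' @param annotation `circ_annotation`
#' @param params [filter_params()]
#' @return data.table with one row per junction: coordinates, per-library
#'   counts collapsed to `max_count` and `total`, gene_id, gene_biotype,
#'   n_exons, circ_length, status
#' @export
select_targets <- function(junctions, annotation, params = filter_params()) {
  jx <- as.data.table(junctions)
  if (!nrow(jx))
    return(data.table(chrom = character(), strand = character(),
                      acceptor_pos = integer(), donor_pos = integer(),
                      max_count = integer(), total = integer(),
                      gene_id = character(), gene_biotype = character(),
                      n_exons = integer(), circ_length = integer(),
                      status = character()))
  agg <- jx[, .(max_count = max(count), total = sum(count)),
            by = .(chrom, strand, acceptor_pos, donor_pos)]
  ex <- annotation$exons
  ann <- lapply(seq_len(nrow(agg)), function(i) {
    r <- agg[i]
    g <- host_gene(r$chrom, r$strand, r$acceptor_pos, r$donor_pos,
                   annotation)
    if (is.null(g)) {
      data.table(gene_id = "intergenic", gene_biotype = NA_character_,
                 n_exons = 0L,
                 circ_length = r$donor_pos - r$acceptor_pos)
    } else {
      inside <- ex[gene_id == g$gene_id & start0 >= r$acceptor_pos &
                     end0 <= r$donor_pos]
      data.table(gene_id = g$gene_id, gene_biotype = g$gene_biotype,
                 n_exons = nrow(inside),
                 circ_length = if (nrow(inside))
                   sum(inside$end0 - inside$start0)
                 else r$donor_pos - r$acceptor_pos)
    }
  })
  out <- cbind(agg, rbindlist(ann))
  out[, status := ifelse(max_count >= params$high_conf_threshold,
                         "high_confidence", "detected")]
  setorder(out, -max_count)
  out[]
}

#' Derive the non-target circRNA comparison group
#'
#' From expression-library junction counts, keeps junctions that (1) reach
#' `params$nontarget_min_count` reads, (2) derive from exons of genes of the
#' required biotype (protein_coding by default), and (3) are absent from the
#' IP-detected junction set -- any IP count of 1 or more disqualifies.
#'
#' @param expression_junctions counted junctions (expression libraries)
#' @param ip_junctions counted junctions from the IP libraries (any junction
#'   present here is excluded); may also be a candidate table from
#'   [select_targets()]
#' @param annotation `circ_annotation`
#' @param params [filter_params()]
#' @return data.table like [select_targets()] output with status
#'   `non_target`
#' @export
derive_nontarget_group <- function(expression_junctions, ip_junctions,
                                   annotation, params = filter_params()) {
  cand <- select_targets(expression_junctions, annotation, params)
  if (!nrow(cand)) return(cand)
  keep <- cand$max_count >= params$nontarget_min_count &
    !is.na(cand$gene_biotype) &
    cand$gene_biotype == params$require_biotype
  ip <- as.data.table(ip_junctions)
  if (nrow(ip)) {
    key <- paste(cand$chrom, cand$strand, cand$acceptor_pos, cand$donor_pos)
    ip_key <- paste(ip$chrom, ip$strand, ip$acceptor_pos, ip$donor_pos)
    keep <- keep & !(key %in% ip_key)
  }
  out <- cand[keep]
  if (nrow(out)) out[, status := "non_target"]
  out[]
}

#' Write candidate junctions as BED6 plus a full TSV
#'
#' BED name is `gene_id|n_exons|circ_length`, score the maximum library
#' count; BED coordinates are 0-based half-open as the format requires.
#'
#' @param candidates output of [select_targets()] or
#'   [derive_nontarget_group()]
#' @param bed_path,tsv_path output paths (either may be NULL to skip)
#' @return invisibly, the candidate table
#' @export
write_junction_outputs <- function(candidates, bed_path = NULL,
                                   tsv_path = NULL) {
  cand <- as.data.table(candidates)
  if (!is.null(bed_path)) {
    bed <- cand[, .(chrom, acceptor_pos, donor_pos,
                    name = paste(gene_id, n_exons, circ_length, sep = "|"),
                    score = max_count, strand)]
    fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  }
  if (!is.null(tsv_path)) fwrite(cand, tsv_path, sep = "\t")
  invisible(cand)
}
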