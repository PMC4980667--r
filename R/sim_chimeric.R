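## Simulation of chimeric alignment records (back-splice junction reads)
## with ground truth, including decoys that violate exactly one of the four
## selection criteria.

#' Draw a truth specification of back-splice junctions from an annotation
#'
#' Picks genes with at least two exons and defines one circle per picked gene
#' spanning a random run of its exons (always starting and ending on
#' annotated exon boundaries). Per-library read counts are drawn uniformly
#' from `count_range`.
#'
#' @param annotation a `circ_annotation`
#' @param config a [sim_config()] (supplies the seed)
#' @param n_junctions number of true junctions
#' @param libraries character vector of library ids
#' @param count_range integer range of per-library read counts
#' @return data.table with one row per (junction, library):
#'   junction_id, gene_id, chrom, strand, acceptor_pos, donor_pos,
#'   library_id, n_reads (coordinates 0-based half-open)
#' @export
make_truth_spec <- function(annotation, config, n_junctions = 5L,
                            libraries = c("ip_hepg2", "ip_panc1", "ip_patu"),
                            count_range = c(5L, 50L)) {
  ex <- annotation$exons
  genes <- annotation$genes[n_exons >= 2L]
  if (nrow(genes) < n_junctions)
    stop("not enough multi-exon genes for ", n_junctions, " junctions",
         call. = FALSE)
  withr::with_seed(child_seed(config$seed, "truth_spec"), {
    pick <- sample(genes$gene_id, n_junctions)
    rows <- lapply(seq_along(pick), function(i) {
      gex <- ex[gene_id == pick[i]][order(start0)]
      from <- resample(seq_len(nrow(gex) - 1L))
      to <- resample(seq(from + 1L, nrow(gex)))
      data.table(
        junction_id = sprintf("junc%02d", i),
        gene_id = pick[i],
        chrom = gex$chrom[1], strand = gex$strand[1],
        acceptor_pos = gex$start0[from], donor_pos = gex$end0[to]
      )
    })
    spec <- rbindlist(rows)
    spec <- spec[rep(seq_len(.N), each = length(libraries))]
    spec[, library_id := rep(libraries, times = n_junctions)]
    spec[, n_reads := resample(seq(count_range[1], count_range[2]),
                               .N, replace = TRUE)]
  })
  spec[]
}

## one chimeric record row (0-based half-open segment intervals)
chim_row <- function(id, lib, chrom_a, start_a, end_a, strand_a,
                     chrom_b, start_b, end_b, strand_b, score, linear) {
  data.table(record_id = id, library_id = lib,
             chrom_a = chrom_a, start_a = as.integer(start_a),
             end_a = as.integer(end_a), strand_a = strand_a,
             chrom_b = chrom_b, start_b = as.integer(start_b),
             end_b = as.integer(end_b), strand_b = strand_b,
             chimeric_score = as.integer(score),
             best_linear_score = as.integer(linear))
}

## segments of a junction-spanning record: seg_a is the first part of the
## read. On '+' the read runs donor-side exon end -> acceptor-side exon
## start, so seg_a sits genomically right of seg_b; on '-' the arrangement
## mirrors (seg_a genomically left).
junction_segments <- function(strand, acceptor, donor, oh_a, oh_b) {
  if (strand == "+") {
    list(a = c(donor - oh_a, donor), b = c(acceptor, acceptor + oh_b))
  } else {
    list(a = c(acceptor, acceptor + oh_a), b = c(donor - oh_b, donor))
  }
}

#' Simulate chimeric alignment records with ground truth
#'
#' For every (junction, library) row of `truth_spec`, emits the requested
#' number of criterion-passing records (both segments on one
#' chromosome/strand, in reverse genomic order relative to read order,
#' overhangs at least `config$overhang_min_sim`, score margin at least 3,
#' junction on annotated exon boundaries with canonical flanks). In addition,
#' `decoys_per_class` decoy records are generated per criterion class, each
#' violating exactly the named criterion and satisfying the other three:
#' class 1 trans-chromosome / opposite-strand / forward-order chimeras,
#' class 2 overhang 11 nt, class 3 score margin <= 2, class 4 junctions at
#' non-annotated positions with non-canonical flanks.
#'
#' @param genome patched `DNAStringSet` from [make_annotation()]
#' @param annotation a `circ_annotation`
#' @param truth_spec data.table from [make_truth_spec()] (or the same shape)
#' @param config a [sim_config()]
#' @param decoys_per_class decoy records per criterion class and per library
#' @return list with `records` (chimeric record data.table) and `truth`
#'   (list: `junctions` = truth_spec, `decoys` = data.table(record_id,
#'   violated_criterion))
#' @export
simulate_chimeric_records <- function(genome, annotation, truth_spec, config,
                                      decoys_per_class = 25L) {
  ex <- annotation$exons
  spec <- as.data.table(truth_spec)
  ## every true junction must join exon boundaries of its gene
  if (nrow(spec)) {
    ok <- vapply(seq_len(nrow(spec)), function(i) {
      gex <- ex[gene_id == spec$gene_id[i]]
      any(gex$start0 == spec$acceptor_pos[i]) &&
        any(gex$end0 == spec$donor_pos[i])
    }, logical(1))
    if (!all(ok))
      stop("truth_spec junction(s) not on annotated exon boundaries: ",
           paste(unique(spec$junction_id[!ok]), collapse = ", "),
           call. = FALSE)
  }
  L <- config$read_length
  ohmin <- config$overhang_min_sim
  libs <- unique(spec$library_id)
  if (!length(libs)) libs <- "ip_hepg2"

  withr::with_seed(child_seed(config$seed, "chimeric"), {
    out <- list()
    idc <- 0L
    next_id <- function() {
      idc <<- idc + 1L
      sprintf("sim%06d", idc)
    }
    ## --- true records ---
    for (i in seq_len(nrow(spec))) {
      s <- spec[i]
      n <- s$n_reads
      if (n < 1L) next
      oh_a <- resample(seq(ohmin, L - ohmin), n, replace = TRUE)
      margin <- sample(3:30, n, replace = TRUE)
      score <- L - sample(0:5, n, replace = TRUE)
      for (j in seq_len(n)) {
        sg <- junction_segments(s$strand, s$acceptor_pos, s$donor_pos,
                                oh_a[j], L - oh_a[j])
        out[[length(out) + 1L]] <- chim_row(
          next_id(), s$library_id, s$chrom, sg$a[1], sg$a[2], s$strand,
          s$chrom, sg$b[1], sg$b[2], s$strand, score[j], score[j] - margin[j])
      }
    }
    ## --- decoys ---
    decoys <- list()
    add_decoy <- function(row, crit) {
      out[[length(out) + 1L]] <<- row
      decoys[[length(decoys) + 1L]] <<-
        data.table(record_id = row$record_id,
                   violated_criterion = crit)
    }
    genes <- annotation$genes[n_exons >= 2L]
    plus_genes <- genes[strand == "+"]
    minus_genes <- genes[strand == "-"]
    rand_gene_junction <- function(g) {
      gex <- ex[gene_id == g][order(start0)]
      list(chrom = gex$chrom[1], strand = gex$strand[1],
           acceptor = gex$start0[1], donor = gex$end0[nrow(gex)],
           gex = gex)
    }
    for (lib in libs) {
      for (d in seq_len(decoys_per_class)) {
        oh_a <- resample(seq(ohmin, L - ohmin))
        oh_b <- L - oh_a
        score <- L - sample(0:5, 1L)
        margin <- sample(3:30, 1L)

        ## class 1: rotate through trans-chromosome, opposite-strand and
        ## forward-order variants; every side stays on annotated boundaries
        kind <- (d %% 3L)
        if (kind == 0L && length(unique(genes$chrom)) >= 2L) {
          g1 <- rand_gene_junction(sample(genes[chrom == genes$chrom[1]]$gene_id, 1L))
          g2 <- rand_gene_junction(sample(genes[chrom != g1$chrom]$gene_id, 1L))
          sa <- if (g1$strand == "+") c(g1$donor - oh_a, g1$donor)
                else c(g1$acceptor, g1$acceptor + oh_a)
          sb <- if (g2$strand == "+") c(g2$acceptor, g2$acceptor + oh_b)
                else c(g2$donor - oh_b, g2$donor)
          add_decoy(chim_row(next_id(), lib, g1$chrom, sa[1], sa[2],
                             g1$strand, g2$chrom, sb[1], sb[2], g2$strand,
                             score, score - margin), 1L)
        } else if (kind == 1L && nrow(plus_genes) && nrow(minus_genes)) {
          ## opposite strand, same chromosome when possible
          gp <- rand_gene_junction(sample(plus_genes$gene_id, 1L))
          gm <- rand_gene_junction(sample(minus_genes$gene_id, 1L))
          add_decoy(chim_row(next_id(), lib, gp$chrom,
                             gp$donor - oh_a, gp$donor, "+",
                             gm$chrom, gm$donor - oh_b, gm$donor, "-",
                             score, score - margin), 1L)
        } else {
          ## forward (linear) order over one intron of a multi-exon gene
          g <- rand_gene_junction(sample(genes$gene_id, 1L))
          k <- resample(seq_len(nrow(g$gex) - 1L))
          e1 <- g$gex[k]; e2 <- g$gex[k + 1L]
          if (g$strand == "+") {
            sa <- c(e1$end0 - oh_a, e1$end0)
            sb <- c(e2$start0, e2$start0 + oh_b)
          } else {
            sa <- c(e2$start0, e2$start0 + oh_a)
            sb <- c(e1$end0 - oh_b, e1$end0)
          }
          add_decoy(chim_row(next_id(), lib, g$chrom, sa[1], sa[2],
                             g$strand, g$chrom, sb[1], sb[2], g$strand,
                             score, score - margin), 1L)
        }

        ## class 2: overhang 11 nt (< 12), everything else valid
        g <- rand_gene_junction(sample(genes$gene_id, 1L))
        sg <- junction_segments(g$strand, g$acceptor, g$donor, 11L, L - 11L)
        add_decoy(chim_row(next_id(), lib, g$chrom, sg$a[1], sg$a[2],
                           g$strand, g$chrom, sg$b[1], sg$b[2], g$strand,
                           score, score - margin), 2L)

        ## class 3: score margin exactly <= 2 (boundary value 2 included)
        g <- rand_gene_junction(sample(genes$gene_id, 1L))
        m3 <- sample(c(0L, 1L, 2L, 2L), 1L)
        sg <- junction_segments(g$strand, g$acceptor, g$donor, oh_a, oh_b)
        add_decoy(chim_row(next_id(), lib, g$chrom, sg$a[1], sg$a[2],
                           g$strand, g$chrom, sg$b[1], sg$b[2], g$strand,
                           score, score - m3), 3L)

        ## class 4: junction at non-annotated, non-canonical positions
        repeat {
          chr <- sample(names(genome), 1L)
          strandx <- sample(c("+", "-"), 1L)
          wlen <- length(genome[[chr]])
          a <- sample(seq(200L, wlen - 1500L), 1L)
          dd <- a + sample(200:1000, 1L)
          on_boundary <- nrow(ex[chrom == chr &
                                   (start0 == a | end0 == dd)]) > 0L
          left <- genome_sub(genome, chr, a - 2L, a)
          right <- genome_sub(genome, chr, dd, dd + 2L)
          canon <- if (strandx == "+") {
            identical(left, "AG") || identical(right, "GT")
          } else {
            identical(left, "AC") || identical(right, "CT")
          }
          if (!on_boundary && !canon) break
        }
        sg <- junction_segments(strandx, a, dd, oh_a, oh_b)
        add_decoy(chim_row(next_id(), lib, chr, sg$a[1], sg$a[2], strandx,
                           chr, sg$b[1], sg$b[2], strandx,
                           score, score - margin), 4L)
      }
    }
    records <- rbindlist(out)
    decoy_dt <- if (length(decoys)) rbindlist(decoys)
                else data.table(record_id = character(),
                                violated_criterion = integer())
  })
  list(records = records,
       truth = list(junctions = spec, decoys = decoy_dt))
}

#' Write / read the chimeric record TSV
#'
#' Dialect: header line, 12 tab-separated columns (record_id, library_id,
#' chrom_a, start_a, end_a, strand_a, chrom_b, start_b, end_b, strand_b,
#' chimeric_score, best_linear_score), coordinates 1-based inclusive. The
#' in-memory representation is 0-based half-open; conversion happens at this
#' boundary.
#'
#' @param records chimeric record data.table (0-based half-open)
#' @param path file path
#' @return `path`, invisibly
#' @export
write_chimeric_table <- function(records, path) {
  out <- copy(as.data.table(records))
  out[, start_a := start_a + 1L]   # to 1-based inclusive
  out[, start_b := start_b + 1L]
  fwrite(out[, .(record_id, library_id, chrom_a, start_a, end_a, strand_a,
                 chrom_b, start_b, end_b, strand_b, chimeric_score,
                 best_linear_score)],
         path, sep = "\t")
  invisible(path)
}
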