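#' Generate a toy genome
#'
#' Chromosomes are i.i.d. random DNA at the configured GC fraction. The same
#' config (including seed) always yields the same sequences.
#'
#' @param config a [sim_config()]
#' @return a [Biostrings::DNAStringSet] named chr1, chr2, ...
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_chrom < 1L) stop("n_chrom must be >= 1", call. = FALSE)
  if (config$chrom_length < 1000L)
    stop("chrom_length must be >= 1000", call. = FALSE)
  seqs <- withr::with_seed(
    child_seed(config$seed, "genome"),
    random_dna(config$n_chrom, config$chrom_length, config$gc_fraction)
  )
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(config$n_chrom))
  genome
}

#' Write a genome FASTA plus a samtools-style .fai index
#'
#' @param genome a `DNAStringSet`
#' @param path output FASTA path (`path`.fai is written next to it)
#' @return `path`, invisibly
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA path
#' @return a `DNAStringSet`
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  ## strip FASTA descriptions, keep bare sequence names
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

## ---- gene model ------------------------------------------------------------

new_annotation <- function(exons) {
  exons <- as.data.table(exons)
  setorder(exons, chrom, start0, exon_number)
  genes <- if (nrow(exons)) {
    exons[, .(chrom = chrom[1], strand = strand[1],
              start0 = min(start0), end0 = max(end0),
              gene_biotype = gene_biotype[1], n_exons = .N),
          by = gene_id]
  } else {
    data.table(gene_id = character(), chrom = character(),
               strand = character(), start0 = integer(), end0 = integer(),
               gene_biotype = character(), n_exons = integer())
  }
  structure(list(exons = exons, genes = genes), class = "circ_annotation")
}

#' Build an annotation object from an exon table
#'
#' Mostly useful in tests and for constructing small gene models by hand.
#'
#' @param exons data.frame with columns chrom, start0, end0 (0-based
#'   half-open), strand, gene_id, transcript_id, exon_number, gene_biotype
#' @return a `circ_annotation` (list with `exons` and `genes` data.tables)
#' @export
annotation_from_exons <- function(exons) {
  need <- c("chrom", "start0", "end0", "strand", "gene_id",
            "transcript_id", "exon_number", "gene_biotype")
  miss <- setdiff(need, names(exons))
  if (length(miss))
    stop("missing exon columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  new_annotation(exons)
}

#' Simulate a gene annotation and patch splice-site flanks into the genome
#'
#' Genes are placed left to right on the chromosomes without overlap, each
#' with 3-5 exons (configurable) and a biotype of protein_coding or lincRNA.
#' The genome sequence is patched so that every exon boundary carries
#' canonical splice dinucleotides on the transcribed strand: on the plus
#' strand `AG` immediately before each exon start and `GT` immediately after
#' each exon end; on the minus strand the reverse-complement arrangement
#' (`AC` before starts, `CT` after ends in genome coordinates). Back-splice
#' junctions at exon boundaries are therefore both annotated and canonical.
#'
#' @param genome a `DNAStringSet` from [make_genome()]
#' @param config a [sim_config()]
#' @return list with `annotation` (a `circ_annotation`) and `genome` (the
#'   patched `DNAStringSet`); use the patched genome downstream.
#' @export
make_annotation <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(child_seed(config$seed, "annotation"), {
    n_genes <- config$n_genes
    chroms <- rep(names(genome), length.out = n_genes)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    biotypes <- sample(c("protein_coding", "lincRNA"), n_genes,
                       replace = TRUE, prob = c(0.8, 0.2))
    if (n_genes >= 2L) {
      ## guarantee both biotypes exist so biotype filters are exercised
      biotypes[1] <- "protein_coding"
      biotypes[2] <- "lincRNA"
    }
    cursor <- setNames(rep(10L, length(genome)), names(genome))
    rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      chr <- chroms[i]
      n_ex <- resample(seq(config$exons_per_gene[1], config$exons_per_gene[2]))
      ex_len <- sample(80:300, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) sample(100:500, n_ex - 1L, replace = TRUE)
                else integer(0)
      gap <- sample(500:2000, 1L)
      gstart <- cursor[chr] + gap
      starts <- gstart + cumsum(c(0L, head(ex_len, -1L) + in_len))
      ends <- starts + ex_len
      if (max(ends) + 10L > length(genome[[chr]]))
        stop("cannot place gene ", i, " on ", chr,
             " without exceeding chromosome bounds", call. = FALSE)
      cursor[chr] <- max(ends)
      gid <- sprintf("gene%03d", i)
      rows[[i]] <- data.table(
        chrom = chr, start0 = as.integer(starts), end0 = as.integer(ends),
        strand = strands[i], gene_id = gid,
        transcript_id = paste0(gid, ".t1"),
        exon_number = seq_len(n_ex), gene_biotype = biotypes[i]
      )
    }
    exons <- rbindlist(rows)
  })
  ann <- new_annotation(exons)
  list(annotation = ann, genome = patch_splice_flanks(genome, ann))
}

## Overwrite the 2-nt flanks around every exon boundary with canonical
## splice dinucleotides on the transcribed strand.
patch_splice_flanks <- function(genome, annotation) {
  ex <- annotation$exons
  for (chr in unique(ex$chrom)) {
    e <- ex[chrom == chr]
    before <- ifelse(e$strand == "+", "AG", "AC")  # ends at exon start
    after <- ifelse(e$strand == "+", "GT", "CT")   # begins at exon end
    at <- IRanges::IRanges(start = c(e$start0 - 1L, e$end0 + 1L),
                           width = 2L)             # 1-based
    val <- c(before, after)
    keep <- IRanges::start(at) >= 1L &
      IRanges::end(at) <= length(genome[[chr]])
    genome[[chr]] <- Biostrings::replaceAt(genome[[chr]], at[keep],
                                           Biostrings::DNAStringSet(val[keep]))
  }
  genome
}

## ---- GTF I/O ---------------------------------------------------------------

#' Write an annotation as GTF2.2
#'
#' Emits gene, transcript and exon features with `gene_id`, `transcript_id`,
#' `gene_biotype` (and `exon_number` on exons). Coordinates are written
#' 1-based inclusive.
#'
#' @param annotation a `circ_annotation`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gtf <- function(annotation, path) {
  ex <- annotation$exons
  g <- annotation$genes
  attr_gene <- sprintf('gene_id "%s"; gene_biotype "%s";',
                       g$gene_id, g$gene_biotype)
  attr_tx <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                     g$gene_id, paste0(g$gene_id, ".t1"), g$gene_biotype)
  attr_ex <- sprintf(
    'gene_id "%s"; transcript_id "%s"; exon_number "%d"; gene_biotype "%s";',
    ex$gene_id, ex$transcript_id, ex$exon_number, ex$gene_biotype)
  lines <- c(
    sprintf("%s\tcircrip\tgene\t%d\t%d\t.\t%s\t.\t%s",
            g$chrom, g$start0 + 1L, g$end0, g$strand, attr_gene),
    sprintf("%s\tcircrip\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            g$chrom, g$start0 + 1L, g$end0, g$strand, attr_tx),
    sprintf("%s\tcircrip\texon\t%d\t%d\t.\t%s\t.\t%s",
            ex$chrom, ex$start0 + 1L, ex$end0, ex$strand, attr_ex)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF into an annotation object
#'
#' Uses `rtracklayer` for parsing; only exon features are retained.
#'
#' @param path GTF path
#' @return a `circ_annotation`
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  exons <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    exon_number = as.integer(gr$exon_number),
    gene_biotype = gr$gene_biotype
  )
  new_annotation(exons)
}
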