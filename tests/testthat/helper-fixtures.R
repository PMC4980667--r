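## Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

## default toy world: 2 chromosomes, 20 genes, patched splice flanks
toy_world <- function() {
  if (is.null(.fx$world)) {
    cfg <- sim_config(seed = 11L)
    genome <- make_genome(cfg)
    ann <- make_annotation(genome, cfg)
    .fx$world <- list(config = cfg, genome = ann$genome,
                      annotation = ann$annotation)
  }
  .fx$world
}

## simulated chimeric dataset over the toy world (3 IP libraries)
toy_dataset <- function() {
  if (is.null(.fx$dataset)) {
    w <- toy_world()
    spec <- make_truth_spec(w$annotation, w$config, n_junctions = 5L)
    sim <- simulate_chimeric_records(w$genome, w$annotation, spec,
                                     w$config, decoys_per_class = 10L)
    .fx$dataset <- c(w, list(truth_spec = spec, records = sim$records,
                             decoys = sim$truth$decoys))
  }
  .fx$dataset
}

## a hand-built single-gene annotation on a hand-built genome, with exact
## splice flanks, for boundary tests. Gene on '+': two exons of 150 and
## 69 nt (circle length 219).
hand_world <- function() {
  if (is.null(.fx$hand)) {
    set.seed(99)
    n <- 3000L
    seqc <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = "")
    ## exon1 [500,650), exon2 [850,919) on +; flanks AG before starts,
    ## GT after ends
    exons <- data.frame(
      chrom = "chrT", start0 = c(500L, 850L), end0 = c(650L, 919L),
      strand = "+", gene_id = "geneT", transcript_id = "geneT.t1",
      exon_number = 1:2, gene_biotype = "protein_coding")
    ann <- annotation_from_exons(exons)
    genome <- Biostrings::DNAStringSet(seqc)
    names(genome) <- "chrT"
    genome <- circrip:::patch_splice_flanks(genome, ann)
    .fx$hand <- list(genome = genome, annotation = ann)
  }
  .fx$hand
}

## one well-formed chimeric record over hand_world's gene (plus strand),
## with tweakable geometry/scores
hand_record <- function(oh_a = 40L, oh_b = 60L, score = 95L, margin = 10L,
                        acceptor = 500L, donor = 919L) {
  data.table::data.table(
    record_id = "r1", library_id = "libA",
    chrom_a = "chrT", start_a = donor - oh_a, end_a = donor, strand_a = "+",
    chrom_b = "chrT", start_b = acceptor, end_b = acceptor + oh_b,
    strand_b = "+",
    chimeric_score = score, best_linear_score = score - margin)
}
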