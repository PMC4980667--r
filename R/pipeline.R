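#' Simulate a complete co-IP chimeric dataset
#'
#' Convenience wrapper chaining [make_genome()], [make_annotation()],
#' [make_truth_spec()] and [simulate_chimeric_records()].
#'
#' @param config a [sim_config()]
#' @param n_junctions true back-splice junctions
#' @param libraries library ids
#' @param decoys_per_class decoys per criterion class per library
#' @param count_range per-library read count range for true junctions
#' @return list: genome (patched), annotation, truth_spec, records, truth
#' @export
simulate_dataset <- function(config, n_junctions = 5L,
                             libraries = c("ip_hepg2", "ip_panc1",
                                           "ip_patu"),
                             decoys_per_class = 25L,
                             count_range = c(5L, 50L)) {
  genome <- make_genome(config)
  ann <- make_annotation(genome, config)
  spec <- make_truth_spec(ann$annotation, config, n_junctions = n_junctions,
                          libraries = libraries, count_range = count_range)
  sim <- simulate_chimeric_records(ann$genome, ann$annotation, spec, config,
                                   decoys_per_class = decoys_per_class)
  list(genome = ann$genome, annotation = ann$annotation, truth_spec = spec,
       records = sim$records, truth = sim$truth)
}

#' Run the full synthetic end-to-end pipeline
#'
#' Simulates the co-IP dataset plus an expression library, calls and
#' annotates back-splice junctions, derives the high-confidence target and
#' non-target candidate sets, simulates SELEX selection rounds, demultiplexes
#' and ranks k-mer enrichment, simulates the two circRNA sequence groups with
#' a planted density offset, and compares their top-motif densities.
#'
#' @param config a [sim_config()]
#' @param out_dir directory for file outputs (created)
#' @param offset planted density offset for the sequence groups
#' @return list with the main intermediate objects: candidates, nontargets,
#'   enrichment, top_motifs, densities, comparison, and file paths
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("circrip"),
                         offset = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ## --- circRNA calling on IP + expression libraries ---
  ## half the simulated circRNAs are expression-only (never seen in the IP),
  ## so the non-target derivation has something to find
  genome <- make_genome(config)
  ann <- make_annotation(genome, config)
  libraries <- c("ip_hepg2", "ip_panc1", "ip_patu", "expr_hepg2")
  spec <- make_truth_spec(ann$annotation, config, n_junctions = 8L,
                          libraries = libraries,
                          count_range = c(10L, 50L))
  expr_only <- unique(spec$junction_id)
  expr_only <- expr_only[seq_along(expr_only) %% 2L == 0L]
  spec[junction_id %in% expr_only & library_id != "expr_hepg2",
       n_reads := 0L]
  sim <- simulate_chimeric_records(ann$genome, ann$annotation, spec, config)
  ds <- list(genome = ann$genome, annotation = ann$annotation,
             truth_spec = spec, records = sim$records, truth = sim$truth)
  params <- filter_params()
  filt <- apply_filters(ds$records, ds$genome, ds$annotation, params)
  ip_lib <- c("ip_hepg2", "ip_panc1", "ip_patu")
  ip_counts <- count_junctions(filt$accepted[library_id %in% ip_lib])
  expr_counts <- count_junctions(
    filt$accepted[library_id == "expr_hepg2"])
  candidates <- select_targets(ip_counts, ds$annotation, params)
  nontargets <- derive_nontarget_group(expr_counts, ip_counts,
                                       ds$annotation, params)
  write_junction_outputs(candidates,
                         bed_path = file.path(out_dir, "candidates.bed"),
                         tsv_path = file.path(out_dir, "candidates.tsv"))
  write_junction_outputs(nontargets,
                         tsv_path = file.path(out_dir, "nontargets.tsv"))
  ## --- SELEX ---
  sx <- simulate_selex(config, dir = file.path(out_dir, "selex"))
  dm <- demultiplex_and_trim(sx$fastq_paths, sx$layout)
  rounds <- paste0("R", 0:config$rounds)
  counts <- sapply(rounds, function(r) count_kmer_presence(dm$pools[[r]], 4L))
  enr <- kmer_zscores(counts)
  rk <- rank_and_export(enr,
                        path = file.path(out_dir, "tetramer_enrichment.tsv"),
                        top_motifs_path = file.path(out_dir,
                                                    "top10_motifs.txt"))
  ## --- motif density comparison ---
  grp <- simulate_circ_groups(
    config, offset = offset,
    target_path = file.path(out_dir, "target.fa"),
    nontarget_path = file.path(out_dir, "nontarget.fa"))
  dens <- motif_densities(grp$target, grp$nontarget, rk$top_motifs)
  fwrite(dens, file.path(out_dir, "densities.tsv"), sep = "\t")
  cmp <- compare_groups(dens)
  write_comparison(cmp, file.path(out_dir, "comparison.json"),
                   kde_path = file.path(out_dir, "kde.tsv"))
  list(dataset = ds, candidates = candidates, nontargets = nontargets,
       selex_stats = dm$stats, enrichment = enr, top_motifs = rk$top_motifs,
       densities = dens, comparison = cmp, out_dir = out_dir)
}
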