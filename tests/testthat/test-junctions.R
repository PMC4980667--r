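## counted-junction rows for one junction across libraries
jx_row <- function(counts, a = 500L, d = 919L, chrom = "chrT",
                   strand = "+") {
  data.table::data.table(chrom = chrom, strand = strand, acceptor_pos = a,
                         donor_pos = d, library_id = names(counts),
                         count = unname(unlist(counts)))
}

test_that("high-confidence status needs >= 30 reads in one library", {
  hw <- hand_world()
  high <- select_targets(jx_row(c(A = 40L, B = 5L)), hw$annotation)
  expect_identical(high$status, "high_confidence")
  expect_equal(high$max_count, 40L)
  low <- select_targets(jx_row(c(A = 29L, B = 29L, C = 29L)),
                        hw$annotation)
  expect_identical(low$status, "detected")
})

test_that("exon composition and circle length come from the gene model", {
  hw <- hand_world()
  cand <- select_targets(jx_row(c(A = 40L)), hw$annotation)
  expect_identical(cand$gene_id, "geneT")
  expect_equal(cand$n_exons, 2L)
  ## oracle: sum of exon lengths from the gene model, 150 + 69
  ex <- hw$annotation$exons
  expect_equal(cand$circ_length, sum(ex$end0 - ex$start0))
  expect_equal(cand$circ_length, 219L)

  ## intergenic junction is retained and flagged
  solo <- select_targets(jx_row(c(A = 31L), a = 2000L, d = 2400L),
                         hw$annotation)
  expect_identical(solo$gene_id, "intergenic")
  expect_equal(solo$n_exons, 0L)
  expect_equal(solo$circ_length, 400L)
})

test_that("non-target derivation enforces all three criteria", {
  hw <- hand_world()
  params <- filter_params()
  ip <- jx_row(c(ip = 1L), a = 2000L, d = 2400L)

  ## count 10, protein-coding host, absent from IP -> included
  nt <- derive_nontarget_group(jx_row(c(expr = 10L)), ip, hw$annotation,
                               params)
  expect_equal(nrow(nt), 1L)
  expect_identical(nt$status, "non_target")
  ## boundary: count 9 -> excluded
  expect_equal(nrow(derive_nontarget_group(jx_row(c(expr = 9L)), ip,
                                           hw$annotation, params)), 0L)
  ## present in IP with a single read -> excluded
  ip2 <- jx_row(c(ip = 1L))
  expect_equal(nrow(derive_nontarget_group(jx_row(c(expr = 50L)), ip2,
                                           hw$annotation, params)), 0L)
  ## lincRNA host -> excluded even at high count
  linc <- annotation_from_exons(data.frame(
    chrom = "chrT", start0 = c(500L, 850L), end0 = c(650L, 919L),
    strand = "+", gene_id = "geneL", transcript_id = "geneL.t1",
    exon_number = 1:2, gene_biotype = "lincRNA"))
  expect_equal(nrow(derive_nontarget_group(jx_row(c(expr = 100L)), ip,
                                           linc, params)), 0L)
})

test_that("raising the high-confidence threshold never adds candidates", {
  ds <- toy_dataset()
  filt <- apply_filters(ds$records, ds$genome, ds$annotation)
  counts <- count_junctions(filt$accepted)
  hc <- function(thr) {
    out <- select_targets(counts, ds$annotation,
                          filter_params(high_conf_threshold = thr))
    out[out$status == "high_confidence",
        paste(chrom, acceptor_pos, donor_pos)]
  }
  sets <- lapply(c(10L, 30L, 45L, 60L), hc)
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("BED/TSV outputs are written with the documented layout", {
  hw <- hand_world()
  cand <- select_targets(jx_row(c(A = 40L)), hw$annotation)
  bed <- tempfile(fileext = ".bed")
  tsv <- tempfile(fileext = ".tsv")
  write_junction_outputs(cand, bed_path = bed, tsv_path = tsv)
  b <- data.table::fread(bed, header = FALSE)
  expect_equal(b$V2, 500L)  # BED stays 0-based half-open
  expect_equal(b$V3, 919L)
  expect_identical(b$V4, "geneT|2|219")
  expect_equal(b$V5, 40L)
  expect_true(file.exists(tsv))
})
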