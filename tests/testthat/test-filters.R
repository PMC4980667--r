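test_that("threshold boundaries match the published criteria exactly", {
  hw <- hand_world()
  params <- filter_params()
  run1 <- function(rec) apply_filters(rec, hw$genome, hw$annotation,
                                      params)$flags

  ## C2: overhang 12 accepts, 11 rejects
  expect_true(run1(hand_record(oh_a = 12L, oh_b = 40L))$accepted)
  f11 <- run1(hand_record(oh_a = 11L, oh_b = 40L))
  expect_false(f11$accepted)
  expect_false(f11$C2)
  expect_true(f11$C1 && f11$C3 && f11$C4)

  ## C3: margin 2 is not > 2; margin 3 passes
  f2 <- run1(hand_record(score = 50L, margin = 2L))
  expect_false(f2$accepted)
  expect_false(f2$C3)
  expect_true(f2$C1 && f2$C2 && f2$C4)
  expect_true(run1(hand_record(score = 50L, margin = 3L))$accepted)
})

test_that("canonical_or_annotated labels and strand rules are right", {
  hw <- hand_world()
  ## simulated exon boundaries carry planted flanks: annotated AND canonical
  r <- canonical_or_annotated("chrT", "+", 500L, 919L, hw$genome,
                              hw$annotation)
  expect_true(r$ok)
  expect_identical(r$label, "both")
  ## shifting 1 nt into the exon breaks both tests (flank no longer AG/GT
  ## by construction of the planted genome at these offsets)
  r2 <- canonical_or_annotated("chrT", "+", 501L, 918L, hw$genome,
                               hw$annotation)
  expect_false(r2$ok)
  expect_identical(r2$label, "neither")
  ## off-chromosome flank window -> neither
  expect_false(canonical_or_annotated("chrT", "+", 1L, 2999L, hw$genome,
                                      hw$annotation)$ok)
})

test_that("minus-strand canonical test agrees with a revcomp oracle", {
  w <- toy_world()
  L <- length(w$genome[[1]])
  rc_chr1 <- oracle_revcomp(as.character(w$genome[[1]]))
  set.seed(42)
  for (i in 1:200) {
    a <- sample(100:(L - 2000), 1)
    d <- a + sample(100:1000, 1)
    got <- canonical_or_annotated("chr1", "-", a, d, w$genome,
                                  annotation_from_exons(
                                    w$annotation$exons[0]))$label
    ## oracle: mirror the junction into revcomp coordinates and apply the
    ## plus-strand rule there
    a2 <- L - d
    d2 <- L - a
    left <- substr(rc_chr1, a2 - 1, a2)
    right <- substr(rc_chr1, d2 + 1, d2 + 2)
    want <- if (left == "AG" && right == "GT") "canonical" else "neither"
    expect_identical(got, want, info = paste(a, d))
  }
})

test_that("junction set is strand-symmetric under genome mirroring", {
  ds <- toy_dataset()
  filt <- apply_filters(ds$records, ds$genome, ds$annotation)
  jx <- count_junctions(filt$accepted)

  lens <- setNames(Biostrings::width(ds$genome), names(ds$genome))
  mirror_genome <- Biostrings::reverseComplement(ds$genome)
  flip <- function(s) ifelse(s == "+", "-", "+")
  ex <- data.table::copy(ds$annotation$exons)
  ex[, `:=`(start0 = unname(lens[chrom]) - end0,
            end0 = unname(lens[chrom]) - start0,
            strand = flip(strand))]
  mirror_ann <- annotation_from_exons(ex)
  rec <- data.table::copy(ds$records)
  rec[, `:=`(start_a = unname(lens[chrom_a]) - end_a,
             end_a = unname(lens[chrom_a]) - start_a,
             strand_a = flip(strand_a),
             start_b = unname(lens[chrom_b]) - end_b,
             end_b = unname(lens[chrom_b]) - start_b,
             strand_b = flip(strand_b))]
  filt2 <- apply_filters(rec, mirror_genome, mirror_ann)
  jx2 <- count_junctions(filt2$accepted)
  ## mirrored coordinates: acceptor' = L - donor, donor' = L - acceptor
  jx_m <- jx[, .(chrom, strand = flip(strand),
                 acceptor_pos = unname(lens[chrom]) - donor_pos,
                 donor_pos = unname(lens[chrom]) - acceptor_pos,
                 library_id, count)]
  data.table::setorder(jx_m, chrom, acceptor_pos, donor_pos, library_id)
  expect_equal(as.data.frame(jx2), as.data.frame(jx_m))
})

test_that("tightening any threshold never enlarges the accepted set", {
  ds <- toy_dataset()
  base <- apply_filters(ds$records, ds$genome, ds$annotation,
                        filter_params())$accepted
  for (p in list(filter_params(min_overhang = 25L),
                 filter_params(score_margin = 10L),
                 filter_params(min_overhang = 40L, score_margin = 20L))) {
    tighter <- apply_filters(ds$records, ds$genome, ds$annotation,
                             p)$accepted
    expect_true(all(tighter$record_id %in% base$record_id))
  }
})

test_that("counting conserves and dedupes record ids", {
  ds <- toy_dataset()
  filt <- apply_filters(ds$records, ds$genome, ds$annotation)
  counts <- count_junctions(filt$accepted)
  n_pairs <- nrow(unique(filt$accepted[, c("record_id", "library_id")]))
  expect_equal(sum(counts$count), n_pairs)
  ## a duplicated record_id within a library counts once
  dup <- rbind(filt$accepted, filt$accepted[1])
  expect_equal(sum(count_junctions(dup)$count), n_pairs)
})
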