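## small hand-made FASTQ around a fixed layout
tiny_layout <- selex_layout(sample_barcodes = c(S1 = "ACGT", S2 = "CGTA"),
                            primer_5p = "GGG", primer_3p = "CCC",
                            random_barcode_length = 3L)

write_reads <- function(reads, path) {
  xs <- Biostrings::DNAStringSet(reads)
  names(xs) <- paste0("r", seq_along(reads))
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(xs, path, format = "fastq", qualities = qual)
  path
}

test_that("demultiplex/trim assigns, dedups and length-filters", {
  insert20 <- strrep("CA", 10)
  mk <- function(rb, bc, insert) paste0(rb, bc, "GGG", insert, "CCC")
  reads <- c(
    mk("AAA", "ACGT", insert20),            # S1, kept
    mk("AAA", "ACGT", insert20),            # exact duplicate -> collapsed
    mk("TTT", "ACGT", insert20),            # distinct random barcode -> kept
    mk("AAA", "CGTA", insert20),            # S2
    mk("AAA", "ACGT", substr(insert20, 1, 17)),  # 17 nt -> discarded
    mk("AAA", "GGGG", insert20)             # unknown barcode -> unassigned
  )
  fq <- write_reads(reads, tempfile(fileext = ".fastq"))
  res <- demultiplex_and_trim(fq, tiny_layout)
  expect_equal(sort(res$pools$S1), c(insert20, insert20))
  expect_equal(res$pools$S2, insert20)
  st <- setNames(res$stats$n, res$stats$reason)
  expect_equal(st[["unassigned_barcode"]], 1L)
  expect_equal(st[["length_out_of_range"]], 1L)
  expect_equal(st[["duplicate_random_barcode_insert"]], 1L)
  expect_equal(st[["retained"]], 3L)
})

test_that("simulator reads demultiplex 100% with inserts preserved", {
  cfg <- sim_config(seed = 9L, pool_size = 10000L)
  sx <- simulate_selex(cfg, dir = tempfile())
  dm <- demultiplex_and_trim(sx$fastq_paths, sx$layout)
  st <- setNames(dm$stats$n, dm$stats$reason)
  expect_equal(st[["unassigned_barcode"]], 0L)
  expect_equal(st[["primer_5p_mismatch"]], 0L)
  expect_equal(st[["length_out_of_range"]], 0L)
  ## retained tags are exactly the simulated pool minus barcode collisions
  expect_equal(st[["retained"]] + st[["duplicate_random_barcode_insert"]],
               st[["total"]])
  for (r in names(dm$pools)) {
    expect_true(all(dm$pools[[r]] %in% sx$truth$pools[[r]]))
    expect_true(all(nchar(dm$pools[[r]]) == 20L))
  }
})

test_that("presence counting has per-tag semantics and matches the oracle", {
  c1 <- count_kmer_presence("CACACACACACACACACACA", 4L)
  expect_equal(unname(c1["CACA"]), 1L)   # presence, not 8 occurrences
  expect_equal(unname(c1["ACAC"]), 1L)
  c2 <- count_kmer_presence(strrep("A", 20L), 4L)
  expect_equal(unname(c2["AAAA"]), 1L)
  expect_equal(sum(c2), 1L)
  expect_length(c2, 256L)

  set.seed(31)
  tags <- circrip:::random_dna(1000L, sample(18:20, 1000L, replace = TRUE))
  got <- count_kmer_presence(tags, 4L, chunk_size = 170L)
  expect_equal(got, oracle_kmer_presence(tags, 4L))
  ## order-invariance
  expect_equal(count_kmer_presence(rev(tags), 4L), got)
})

test_that("z-scores match the naive oracle and sum to zero per round", {
  ## 4-motif toy: counts (10, 0, 0, 0) -> z = 7.5 / 4.3301 for the hot motif
  toy <- matrix(c(10, 0, 0, 0), ncol = 1,
                dimnames = list(c("AA", "AC", "AG", "AT"), "R1"))
  z <- kmer_zscores(toy, cumulative_rounds = "R1")
  expect_equal(z[z$motif == "AA", z_R1], 7.5 / sqrt(75 / 4),
               tolerance = 1e-9)
  expect_equal(z[z$motif == "AA", z_R1], 1.7320508, tolerance = 1e-6)

  ## 256-motif random toy vs oracle, 4 rounds
  set.seed(7)
  m <- matrix(rpois(256 * 4, 50), nrow = 256,
              dimnames = list(circrip:::all_kmers(4L), paste0("R", 1:4)))
  enr <- kmer_zscores(m)
  zo <- oracle_zscores(m)
  for (r in paste0("R", 1:4)) {
    zi <- setNames(enr[[paste0("z_", r)]], enr$motif)
    expect_equal(zi[rownames(m)], zo[, r], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_lt(abs(sum(zi)), 1e-9 * 256)
  }
  expect_equal(enr$z_cumulative,
               rowSums(zo)[enr$motif], ignore_attr = TRUE)

  ## degenerate: equal counts in a round -> all z zero
  eq <- matrix(5, nrow = 4, ncol = 1,
               dimnames = list(c("AA", "AC", "AG", "AT"), "R1"))
  expect_message(zeq <- kmer_zscores(eq), "zero variance")
  expect_true(all(zeq$z_R1 == 0))
})

test_that("ranking keeps top 20 + bottom 10 with a lexicographic tiebreak", {
  set.seed(8)
  m <- matrix(rpois(256 * 4, 50), nrow = 256,
              dimnames = list(circrip:::all_kmers(4L), paste0("R", 1:4)))
  enr <- kmer_zscores(m)
  tsv <- tempfile(fileext = ".tsv")
  top <- tempfile(fileext = ".txt")
  rk <- rank_and_export(enr, path = tsv, top_motifs_path = top)
  expect_equal(nrow(rk$table), 30L)
  expect_length(rk$top_motifs, 10L)
  expect_identical(readLines(top), rk$top_motifs)
  expect_equal(nrow(data.table::fread(tsv)), 30L)

  ## ties broken lexicographically, deterministically
  tie <- matrix(c(5, 5, 5, 1), ncol = 1,
                dimnames = list(c("AT", "AA", "AG", "AC"), "R1"))
  zt <- kmer_zscores(tie)
  expect_identical(zt$motif, c("AA", "AG", "AT", "AC"))
})
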