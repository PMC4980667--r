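TOP_CA <- c("CACA", "ACAC", "AACA", "ACAA", "CAAC",
            "AACC", "CCAA", "ACCA", "CAAA", "AAAC")

test_that("occurrence counting semantics: overlap, circular, degenerate", {
  expect_equal(motif_occurrences("CACACA", "CACA"), 2L)
  expect_equal(motif_occurrences("CACACA", "CACA", overlapping = FALSE), 1L)
  ## circular wrap: on the 6-nt circle ACACAC, CACA starts at 2, 4 and 6
  expect_equal(motif_occurrences("ACACAC", "CACA"), 1L)
  expect_equal(motif_occurrences("ACACAC", "CACA", circular = TRUE), 3L)
  ## impossible match
  expect_equal(motif_occurrences(strrep("GT", 50), TOP_CA), 0L)
  expect_error(motif_occurrences("", "CACA"), "empty")
  expect_warning(motif_occurrences("ACGTN", "ACGT"), "non-ACGT")
})

test_that("occurrence counts agree with a sliding-window oracle", {
  set.seed(13)
  seqs <- circrip:::random_dna(1000L, 500L, gc = 0.45)
  got <- vapply(seqs, motif_occurrences, integer(1), motifs = TOP_CA,
                USE.NAMES = FALSE)
  want <- vapply(seqs, oracle_occurrences, integer(1), motifs = TOP_CA,
                 USE.NAMES = FALSE)
  expect_equal(got, want)
})

test_that("densities normalize to counts per 100 nt", {
  set.seed(14)
  s500 <- circrip:::random_dna(1L, 500L)
  t <- Biostrings::DNAStringSet(c(a = s500, b = s500))
  n <- Biostrings::DNAStringSet(c(c = s500, d = s500))
  d <- motif_densities(t, n, TOP_CA)
  expect_equal(d$density, d$motif_count_sum / d$length * 100)
  expect_equal(nrow(d), 4L)
  ## exact arithmetic: 15 counts on 500 nt -> 3.0
  expect_equal(unique(15 / 500 * 100), 3)
  planted <- paste0(strrep("G", 470), strrep("CACAGG", 5))
  dp <- motif_densities(Biostrings::DNAStringSet(c(x = planted, y = planted)),
                        n, "CACA")
  expect_equal(dp[group == "target", motif_count_sum], c(5L, 5L))
  expect_equal(dp[group == "target", density], c(1, 1))
  ## vectorized fast path equals per-sequence counting
  slow <- vapply(as.character(t), motif_occurrences, integer(1),
                 motifs = TOP_CA, USE.NAMES = FALSE)
  expect_equal(d[group == "target", motif_count_sum], slow)
  ## empty sequences are a named error
  expect_error(motif_densities(Biostrings::DNAStringSet(""), n, TOP_CA),
               "empty")
})

test_that("Welch comparison matches the textbook oracle", {
  rec <- data.table::data.table(
    group = rep(c("target", "non_target"), each = 5),
    density = c(1, 2, 3, 4, 5, 2, 3, 4, 5, 6))
  cmp <- compare_groups(rec)
  expect_equal(cmp$t_statistic, -1.0, tolerance = 1e-12)
  expect_equal(cmp$dof, 8.0, tolerance = 1e-12)
  expect_equal(cmp$p_value, 0.3466, tolerance = 1e-4)
  o <- oracle_welch(rec[group == "target", density],
                    rec[group == "non_target", density])
  expect_equal(cmp$t_statistic, o$t, tolerance = 1e-12)
  expect_equal(cmp$dof, o$dof, tolerance = 1e-12)
  expect_equal(cmp$p_value, o$p, tolerance = 1e-12)

  ## identical groups: t = 0, p = 1
  same <- data.table::data.table(group = rep(c("target", "non_target"),
                                             each = 4),
                                 density = rep(c(1, 2, 3, 4), 2))
  cmp0 <- compare_groups(same)
  expect_equal(cmp0$t_statistic, 0)
  expect_equal(cmp0$p_value, 1)

  ## symmetry: swapping groups negates t, preserves p
  swapped <- data.table::copy(rec)
  swapped[, group := ifelse(group == "target", "non_target", "target")]
  cmp_s <- compare_groups(swapped)
  expect_equal(cmp_s$t_statistic, -cmp$t_statistic)
  expect_equal(cmp_s$p_value, cmp$p_value)

  ## KDE curves integrate to ~1 on the shared grid
  dg <- diff(cmp$kde$grid[1:2])
  expect_equal(sum(cmp$kde$target) * dg, 1, tolerance = 1e-3)
  expect_equal(sum(cmp$kde$non_target) * dg, 1, tolerance = 1e-3)

  ## degenerate inputs
  expect_error(compare_groups(rec[c(1, 6, 7, 8)]), "at least 2")
  const <- data.table::data.table(group = rep(c("target", "non_target"),
                                              each = 3),
                                  density = rep(2, 6))
  expect_warning(cmp_c <- compare_groups(const), "constant")
  expect_equal(cmp_c$p_value, 1)
})

test_that("doubling a sequence doubles counts, density almost unchanged", {
  set.seed(15)
  s <- circrip:::random_dna(1L, 600L, gc = 0.4)
  c1 <- motif_occurrences(s, TOP_CA)
  c2 <- motif_occurrences(paste0(s, s), TOP_CA)
  ## boundary effect: at most k-1 = 3 new occurrences per motif set join
  expect_gte(c2, 2L * c1)
  expect_lte(c2 - 2L * c1, 3L)
  d1 <- c1 / 600 * 100
  d2 <- c2 / 1200 * 100
  expect_lte(abs(d2 - d1), 4 * 100 / 1200)
})
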