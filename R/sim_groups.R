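#' Simulate target and non-target circRNA sequence groups
#'
#' Non-target sequences are i.i.d. background DNA at the configured GC
#' fraction. Target sequences start from the same background and receive
#' planted motif occurrences: `round(offset * length / 100)` placements per
#' sequence at non-overlapping random positions, raising the expected summed
#' top-motif density by about `offset` counts per 100 nt. Lengths are drawn
#' uniformly from `length_range` (default 200-2000 nt, spanning typical
#' circRNA sizes from ~219 to ~1832 nt). Default group sizes are 34 targets
#' and 117 non-targets, the published design.
#'
#' @param config a [sim_config()] (seed and gc_fraction)
#' @param motifs motifs planted into the target group; default the affinity
#'   motifs of the config
#' @param offset planted density offset, counts per 100 nt (default 5)
#' @param n_target,n_nontarget group sizes
#' @param length_range sequence length range, nt
#' @param target_path,nontarget_path optional FASTA output paths
#' @return list with `target` and `nontarget` `DNAStringSet`s
#' @export
simulate_circ_groups <- function(config,
                                 motifs = names(config$affinity_weights),
                                 offset = 5,
                                 n_target = 34L, n_nontarget = 117L,
                                 length_range = c(200L, 2000L),
                                 target_path = NULL, nontarget_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_target < 2L || n_nontarget < 2L)
    stop("group sizes must be >= 2", call. = FALSE)
  if (offset < 0) stop("density offset must be >= 0", call. = FALSE)
  if (!length(motifs)) stop("motifs must be non-empty", call. = FALSE)
  k <- unique(nchar(motifs))
  stopifnot(length(k) == 1L)
  withr::with_seed(child_seed(config$seed, "circ_groups"), {
    len_t <- resample(seq(length_range[1], length_range[2]), n_target,
                      replace = TRUE)
    len_n <- resample(seq(length_range[1], length_range[2]), n_nontarget,
                      replace = TRUE)
    target <- random_dna(n_target, len_t, config$gc_fraction)
    nontarget <- random_dna(n_nontarget, len_n, config$gc_fraction)
    if (offset > 0) {
      for (i in seq_len(n_target)) {
        L <- len_t[i]
        n_plant <- round(offset * L / 100)
        if (n_plant < 1L) next
        ## non-overlapping placements on a k-spaced grid
        slots <- seq(1L, L - k + 1L, by = k)
        pos <- resample(slots, min(n_plant, length(slots)))
        plant <- sample(motifs, length(pos), replace = TRUE)
        s <- target[i]
        for (j in seq_along(pos)) {
          substr(s, pos[j], pos[j] + k - 1L) <- plant[j]
        }
        target[i] <- s
      }
    }
  })
  tset <- Biostrings::DNAStringSet(target)
  names(tset) <- sprintf("target_circ%03d", seq_len(n_target))
  nset <- Biostrings::DNAStringSet(nontarget)
  names(nset) <- sprintf("nontarget_circ%03d", seq_len(n_nontarget))
  if (!is.null(target_path))
    Biostrings::writeXStringSet(tset, target_path, width = 70L)
  if (!is.null(nontarget_path))
    Biostrings::writeXStringSet(nset, nontarget_path, width = 70L)
  list(target = tset, nontarget = nset)
}
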