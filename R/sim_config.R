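#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator in one validated
#' object. Defaults state the simulated world: a small two-chromosome toy
#' genome, 100-nt junction-spanning fragments (matching 2x100 bp library
#' chemistry collapsed to single junction-spanning records), and a four-round
#' SELEX selection from an N20 random pool with increasing stringency.
#'
#' @param seed integer; master seed. Every generator derives its own child
#'   seed from it, so the same config yields byte-identical outputs.
#' @param n_chrom number of toy chromosomes.
#' @param chrom_length length of each chromosome in nt.
#' @param gc_fraction genomic GC content in \[0, 1\].
#' @param n_genes genes placed per genome (non-overlapping).
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param read_length simulated junction fragment length in nt.
#' @param overhang_min_sim minimum overhang (shorter junction anchor) of
#'   simulated criterion-passing records, in nt.
#' @param rounds number of SELEX selection cycles.
#' @param pool_size tags per SELEX round after amplification.
#' @param affinity_weights named numeric vector, motif -> affinity weight.
#'   Survival odds of a tag scale with the summed weighted occurrence count.
#'   The default encodes a C/A-rich binding preference with CACA strongest
#'   and ACAC/AACA next, the preference the selection experiment is meant to
#'   recover; a single-motif map such as `c(CACA = 1)` is equally valid for
#'   testing monotone enrichment of one motif.
#' @param stringency_schedule numeric vector of length `rounds`; per-round
#'   multiplier of the affinity score inside the logistic survival map
#'   (mirrors increasing wash stringency over selection rounds).
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 100000L,
                       gc_fraction = 0.5,
                       n_genes = 20L,
                       exons_per_gene = c(3L, 5L),
                       read_length = 100L,
                       overhang_min_sim = 20L,
                       rounds = 4L,
                       pool_size = 100000L,
                       affinity_weights = c(CACA = 1.0, ACAC = 0.8,
                                            AACA = 0.8),
                       stringency_schedule = c(0.5, 1, 1.5, 2)) {
  if (!is.numeric(gc_fraction) || gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]", call. = FALSE)
  if (length(stringency_schedule) != rounds)
    stop("stringency_schedule length must equal rounds", call. = FALSE)
  if (length(exons_per_gene) != 2L || exons_per_gene[1] > exons_per_gene[2])
    stop("exons_per_gene must be c(min, max)", call. = FALSE)
  if (length(affinity_weights) && is.null(names(affinity_weights)))
    stop("affinity_weights must be a named vector (motif -> weight)",
         call. = FALSE)
  cfg <- list(
    seed = as.integer(seed),
    n_chrom = as.integer(n_chrom),
    chrom_length = as.integer(chrom_length),
    gc_fraction = gc_fraction,
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    read_length = as.integer(read_length),
    overhang_min_sim = as.integer(overhang_min_sim),
    rounds = as.integer(rounds),
    pool_size = as.integer(pool_size),
    affinity_weights = affinity_weights,
    stringency_schedule = stringency_schedule
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Write / read a simulation config as JSON
#' @param config a [sim_config()] object
#' @param path file path
#' @return `read_sim_config` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, x)
}
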