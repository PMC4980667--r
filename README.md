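# circrip

Tools for discovering the circular RNAs (circRNAs) bound by an RNA-binding
protein, and for explaining that binding by the protein's sequence
preference.

## The problem

Some circRNAs exist in cells as defined circRNA–protein complexes
(circRNPs). Given RNA-seq of RNA co-immunoprecipitated with a protein of
interest (e.g. IMP3/IGF2BP3), the computational questions are:

1. **Which circRNAs are in the IP?** A circRNA is visible only through its
   back-splice junction: a chimeric read whose two segments map to the same
   chromosome and strand *in reverse genomic order*. `circrip` filters
   chimeric alignment records with four criteria — geometry, junction
   overhang ≥ 12 nt, chimeric-vs-linear alignment score margin > 2, and
   annotated-or-canonical (GT/AG) splice sites — counts the surviving
   junction reads per library, and calls candidates with ≥ 30 reads in at
   least one library *high confidence*. An expression-matched **non-target
   group** (junction count ≥ 10, protein-coding host gene, absent from the
   IP) provides the comparison set.
2. **What does the protein like to bind?** From a SELEX-seq experiment
   (four selection rounds from an N20 random pool), reads are
   demultiplexed, primer-trimmed, random-barcode deduplicated and reduced
   to 18–20-nt tags; for each round the number of tags containing each
   k-mer (k = 4 or 6) is converted to a z-score across the 4^k motifs,

   z_m(r) = (c_m(r) − mean_m' c_m'(r)) / sd_pop(c(r)),

   and motifs are ranked by cumulative z over rounds R1–R4.
3. **Does the preference explain the binding?** For each circRNA the summed
   occurrence count of the top-10 motifs, normalized per 100 nt of
   sequence, is compared between target and non-target groups with a Welch
   two-sample t-test plus kernel density estimates.

A seeded synthetic-data generator (toy genome + GTF, chimeric records with
per-criterion decoys and a ground-truth table, SELEX rounds with a planted
C/A-rich binding preference, circRNA sequence groups with a planted density
offset) makes the entire pipeline testable with no external data. RT-qPCR
percent-of-input (ΔΔCt) and density-gradient profile utilities round out
the quantitation used in such studies.

## Worked example

```r
library(circrip)

cfg <- sim_config(seed = 7, pool_size = 20000L)
res <- run_pipeline(cfg, out_dir = "circrip_out")

res$candidates[, .(gene_id, max_count, n_exons, circ_length, status)]
#>    gene_id max_count n_exons circ_length          status
#> 1: gene020        46       2         320 high_confidence
#> 2: gene009        44       2         433 high_confidence
#> 3: gene010        43       3         497 high_confidence
#> 4: gene008        25       2         191        detected

head(res$top_motifs, 4)
#> [1] "CACA" "ACAC" "AACA" "ACAG"

res$comparison$p_value
#> [1] 4.437269e-50
```

Three simulated circRNAs exceed the 30-read threshold in at least one IP
library (`high_confidence`); one stays below it (`detected`). The SELEX
stage recovers the planted C/A-rich preference (CACA/ACAC/AACA at the top
of the cumulative z ranking), and the Welch test on top-10-motif density
rejects decisively because the target group carries a planted density
offset of 5 counts/100 nt. `circrip_out/` contains the BED/TSV junction
tables, the enrichment heatmap table, the top-10 motif list, per-circRNA
densities, the comparison JSON and KDE curves.

Single steps are exposed as ordinary functions (`apply_filters`,
`count_junctions`, `select_targets`, `derive_nontarget_group`,
`demultiplex_and_trim`, `count_kmer_presence`, `kmer_zscores`,
`motif_densities`, `compare_groups`, `primer_efficiency`, `percent_input`,
`profile_stats`), and a small CLI wraps them:

```sh
Rscript inst/cli/circrip.R simulate --seed 1 --out simdir
Rscript inst/cli/circrip.R call --chimeric simdir/chimeric.tsv \
    --genome simdir/genome.fa --gtf simdir/annotation.gtf --out calldir
```

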