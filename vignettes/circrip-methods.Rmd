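---
title: "circrip: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circrip: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package computes

`circrip` implements the computational arm of a circRNP (circRNA--protein
complex) discovery experiment: given RNA-seq of RNA co-immunoprecipitated
with an RNA-binding protein, it identifies the circular RNAs stably bound by
that protein, characterizes the protein's intrinsic sequence preference from
an in vitro SELEX experiment, and asks whether that preference explains the
binding -- are the protein's motifs denser in bound circRNAs than in
expressed-but-unbound ones?

The pipeline has four analysis stages plus a synthetic-data generator that
makes every stage testable offline.

# Back-splice junction calling

A back-splice junction is the head-to-tail splice that closes a circRNA.
Its read signature is a chimeric alignment: the two parts of one read map
to the same chromosome and strand but in reverse genomic order. `circrip`
consumes chimeric alignment records (a 12-column TSV dialect, or SAM with
supplementary alignments) and accepts a record only if all four criteria
hold:

* **C1 geometry** -- both segments on one chromosome and strand, in reverse
  genomic order relative to their order in the read. The reversal test is
  strand-aware: a plus-strand linear read places its first segment
  genomically left of the second, so "reverse" means first-at-right; minus
  strand mirrors.
* **C2 overhang** -- the shorter segment anchoring the junction spans at
  least `min_overhang` nucleotides (default 12). The conservative reading
  of "overhang" as the weaker anchor is deliberate: a junction is only as
  trustworthy as its shorter side.
* **C3 score margin** -- the chimeric alignment score must exceed the best
  linear alignment score of the same read by strictly more than
  `score_margin` (default 2, i.e. accepted iff chimeric − linear ≥ 3 on
  integer scores). When the input carries no linear score, a deterministic
  fallback computes the best ungapped local alignment (match +1, mismatch
  −1) of the read against the genomic window spanning both segments
  ± 500 nt.
* **C4 splice sites** -- both junction boundaries are annotated exon
  boundaries of one gene, or carry canonical splice dinucleotides in
  back-splice orientation: on the plus strand `AG` immediately upstream of
  the acceptor and `GT` immediately downstream of the donor; on the minus
  strand the reverse-complement arrangement (`AC`/`CT` in genome
  coordinates). Only GT/AG is accepted as canonical; minor splice-site
  classes (GC--AG, AT--AC) are not.

For records that fail C1 no single junction exists (the segments may sit on
different chromosomes), so C4 is evaluated side-wise: each segment's
junction-side boundary is tested against its own chromosome and strand.
This reduces to the junction-level test whenever C1 holds, and it is what
lets the simulator build decoys that fail *exactly one* criterion.

Accepted records are grouped by exact junction coordinates -- no fuzz
window; junctions one nucleotide apart are distinct -- and counted per
library, deduplicating by record id only (no positional PCR-duplicate
collapse, which the experimental design did not describe). Candidates reach
`high_confidence` status with ≥ 30 junction reads in at least one library.
The non-target comparison group takes expression-library junctions with
≥ 10 reads, a protein-coding host gene, and strict absence from the IP
(any IP count ≥ 1 disqualifies; whether low background counts should be
tolerated was left open by the source experiment, and strict absence is the
reproducible choice).

Internally all coordinates are 0-based half-open; the TSV and GTF
interfaces are 1-based inclusive and BED output is 0-based half-open.

# SELEX-seq k-mer enrichment

SELEX reads are demultiplexed by exact sample-barcode match (a mismatch
tolerance is exposed but defaults to 0 for reproducibility), trimmed of
constant PCR primers on both ends, deduplicated by identical (random
barcode, insert) pair -- the standard reading of "random-barcode filtered";
barcode-integrity filtering is the alternative reading and is not performed
-- and restricted to tags of 18--20 nt.

For each selection round, the number of tags *containing* each of the 256
tetramers (or 4096 hexamers) is counted -- presence per tag, not occurrence
counts, following the tag-containment phrasing of the assay. Enrichment is
a z-score computed within each round across the motif population:

$$z_m(r) = \frac{c_m(r) - \overline{c(r)}}{\sigma_{\mathrm{pop}}(c(r))}$$

with the population standard deviation (the 4^k motifs are the entire
population, not a sample). Per-round z-scores sum to zero by construction.
Motifs are ranked by the cumulative z-score over rounds R1--R4,
ties broken lexicographically; the top 20 and bottom 10 form the heatmap
table, and the top 10 motifs feed the density comparison. No control-round
subtraction is performed: a control round may be displayed alongside, but
defining a subtraction the source experiment did not describe would
manufacture a statistic.

# Motif density and the group comparison

For every circRNA sequence, the occurrence counts of the top-10 motifs are
summed -- overlapping occurrences by default ("CACACA" contains CACA twice),
with non-overlapping and circular (wrap-around) modes available -- and
normalized to counts per 100 nt. Counting is linear and sense-strand on the
mature sequence by default, since nothing in the source design indicates
circular wrap-around counting was used.

Target and non-target densities are compared with a two-sided Welch
two-sample t-test (unequal variances, Welch--Satterthwaite degrees of
freedom), reported with group medians and Gaussian kernel density estimates
(Silverman's rule-of-thumb bandwidth, shared 512-point grid padded by four
bandwidths so each curve integrates to 1 within 10^-3).

# qPCR and gradient utilities

Primer efficiency comes from the standard-curve fit of Ct against
log10(dilution): efficiency = 10^(−1/slope), so a slope of −3.3219 is
perfect doubling. Percent-of-input follows the ΔΔCt arithmetic

$$100 \cdot f_{\mathrm{input}} \cdot E^{(Ct_{\mathrm{input}} - Ct_{\mathrm{IP}})} / f_{\mathrm{IP}}$$

with defaults f_input = 0.05 (5% of material assayed as input) and
f_IP = 0.90 (90% of the IP eluate assayed). The source experiment did not
write this arithmetic out; both fractions are explicit parameters, and the
IP-aliquot correction defaults on. Gradient profiles over 22 fractions are
normalized to sum 1; the peak is the argmax fraction (lowest index on
ties) and peak shifts are reported in fractions only -- converting shifts
to molecular mass would require a calibration model the data do not
provide.

# The synthetic world

The generator states one fixed world rather than exposing dials to chase
test outcomes:

* **Genome/annotation** -- two 100-kb chromosomes of i.i.d. DNA at GC 0.5;
  20 non-overlapping genes of 3--5 exons (80--300 nt exons, 100--500 nt
  introns), 80% protein-coding / 20% lincRNA. Splice flanks are patched
  into the genome so every exon boundary is both annotated and canonical.
  There is no dinucleotide composition model: composition bias is
  controlled only through the GC fraction.
* **Chimeric records** -- single junction-spanning fragments of 100 nt
  (the paired-end nuance of real 2×100 bp libraries is collapsed because
  the filter operates per junction-spanning alignment), overhangs ≥ 20 nt
  and score margins ≥ 3 for true records. Decoys violate exactly one
  criterion each: class 1 trans-chromosome/opposite-strand/forward-order
  chimeras built on annotated boundaries, class 2 overhang 11, class 3
  margin ≤ 2, class 4 junctions at positions that are neither annotated nor
  canonical (re-drawn until the flanks are genuinely non-canonical).
* **SELEX** -- an N20 pool of 10^5 tags; four selection rounds; survival
  probability `plogis(stringency_r × Σ_m w_m · occurrences_m)` with
  stringency schedule 0.5/1/1.5/2 mirroring increasingly stringent washes,
  followed by resampling with replacement back to pool size (amplification).
  The default affinity weights are CACA 1.0, ACAC 0.8, AACA 0.8: the
  C/A-rich preference the experiment is meant to recover, with CACA
  strongest. A single-motif world (`c(CACA = 1)`) is equally supported and
  is used to test monotone enrichment; note that under single-motif
  selection only motifs overlapping the selected one enrich, so a
  pure-CACA world does not reproduce AACA's high rank.
  Reads are laid out as `[5-nt random barcode][sample barcode][5'
  primer][insert][3' primer]`; the real primer/barcode sequences live in
  unavailable supplementary material, so the layout is configurable and the
  defaults are invented constants. No sequencing-error or quality model is
  simulated.
* **Sequence groups** -- 34 target vs 117 non-target sequences of
  200--2000 nt (spanning typical circRNA sizes, ~219 to ~1832 nt), with
  `round(offset × length/100)` motif occurrences planted at non-overlapping
  positions in each target; the default offset of 5 counts/100 nt gives the
  comparison ≥ 95% power at p < 0.01 at these group sizes.

A green test on this world establishes that the *algorithms* are correct
(exact filter semantics, exact counting, correct statistics); it does not
establish performance on real aligner output, with sequencing errors,
paired-end chimera artifacts, or non-i.i.d. genome composition.

# Numerical and calibration notes

Two intuitive null-model checks are *not* valid for this statistic family,
and the test suite asserts corrected versions:

* The maximum |cumulative z| across tetramers does **not** stay small under
  a no-selection null. K-mer presence probabilities differ systematically
  with self-overlap structure -- a 20-mer contains AAAA less often than a
  non-self-overlapping tetramer of equal frequency -- so homopolymers sit
  at strongly negative z in every round (measured null max |z_cum| ≈ 21--25,
  always at AAAA/TTTT/CCCC/GGGG). The meaningful null property is the
  round-0-centered drift `z_cum − 4·z_R0`, which stays below 6 for the
  affinity motifs under the null and exceeds it by an order of magnitude
  under selection.
* A chi-square test comparing round-4 to round-0 presence counts rejects
  even under the null, because amplification-by-resampling genuinely
  duplicates inserts and overdisperses the counts relative to the
  independence model. The suite instead checks that pool base composition
  is conserved and that affinity-motif drift is absent.

Both effects are properties of any faithful selection + amplification
simulation, not artifacts of this implementation.

Other numerical choices: z-scores use population (not sample) SD; zero
variance across motifs in a round yields all-zero z with a logged message;
ranking ties break lexicographically; `which.max` tie-breaking selects the
lowest gradient fraction; densities with both groups constant and equal
return p = 1 with a warning, and constant-but-unequal groups are an error;
values of percent-of-input above 100% are flagged, never silently clamped.

# Known limitations

* No read alignment: the package consumes aligner output formats and
  simulates them; it never maps reads.
* No isoform-level deconvolution of alternative circle exon usage: a
  candidate's exon composition is "exons of the host gene fully inside the
  circle span".
* No intronic/ciRNA detection, no differential abundance statistics
  between IP and mock libraries, no motif PWM/logo construction, no RNA
  secondary-structure filtering, no amplification-curve or melt-curve
  processing.
* Whether putative circRNAs should be deduplicated across cell lines before
  candidate selection was left open by the source design; junctions here
  are keyed by coordinates, so the union across libraries is deduplicated
  by construction.
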