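---
title: "Measuring transposable-element expression on gene expression microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transposable-element expression on gene expression microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Roughly forty percent of a mammalian genome is repetitive sequence, and LTR
retrotransposons (endogenous retroviruses), LINEs and SINEs remain
transcriptionally active in mouse. Standard expression microarrays were
designed to measure genes, but a minority of their probes happen to fall
inside repeat-masked sequence. If those probes can be identified and oriented
correctly, existing probe-level array data become a free, genome-wide readout
of repetitive-element expression — no resequencing required.

`retroarray` implements that idea as a reusable pipeline:

1. **Probe re-annotation** — align every probe to the genome, take its top
   hit, and call it a repeat probe when the hit overlaps a repeat-masked
   interval sufficiently and in the orientation that detects sense
   transcripts.
2. **Probe-level preprocessing** — background correction, log2 transform,
   quantile normalisation, present/absent filtering; probeset summarisation
   is deliberately skipped so repeat probes are analysed individually.
3. **Differential expression** — per-probe two-group contrasts with
   empirical-Bayes moderated t statistics and Benjamini-Hochberg correction,
   then fold-change-plus-significance calls summarised per repeat element.
4. **Population statistics** — rank-sum comparisons of a repeat element's
   probe fold changes against non-repeat probes and against its enclosing
   family/class, MA tables, kernel density estimates.
5. **Locus dissection** — assembly of RepeatMasker genomic hits into
   per-copy contigs, LTR-flank detection, consensus coverage, recurrent
   deletion clustering, and matching of responsive probes (or primers, by
   in-silico PCR) to individual genomic copies.
6. **Synthetic data** — a deterministic generator for genomes with planted
   repeat structure, probe sets and spiked expression matrices, so each
   stage is validated against known truth.

## Probe re-annotation

A probe of length $L$ is aligned ungapped to both strands of the genome,
keeping every placement with at least $L - k$ matching bases. The defaults
$k = 2$ for 50-mer bead-array probes (48/50 identity) and $k = 1$ for 25-mer
probes (24/25) reflect measured hybridisation tolerance of two mismatches in
a 50-mer. The search is *complete*: candidates are enumerated by an exact
shift-or scan and re-scored by a base-wise match count in which `N` never
matches, so no placement at or below the mismatch budget can be missed.
Gapped alignments are not considered — at a 48/50 cut-off an indel cannot
survive the identity threshold anyway.

The *top hit* is the placement with the most matching bases; ties are broken
deterministically by (chromosome, start, strand). Heuristic genome aligners
leave top-hit ties unspecified, which makes annotation irreproducible; a
fixed lexicographic rule removes that ambiguity. A probe becomes a repeat
probe when its top hit overlaps a repeat-masked interval by at least 48 nt
(24 nt for 25-mers); among several overlapping intervals the largest overlap
wins. Orientation: commercial expression probes are complementary to the
transcript, so a probe detects a repeat's *sense* transcript when its
alignment strand equals the repeat's annotated strand. The chemistry is an
explicit flag for unusual platforms. Classification uses the single top hit
only; a lower-scoring sense-orientation hit never overrides an antisense top
hit.

Coordinates are 0-based half-open internally, converted at I/O boundaries
(UCSC rmsk tables are already half-open; RepeatMasker `.out` rows are
1-based inclusive). Consensus coordinates are stored 1-based inclusive with
`cons_start <= cons_end` on both strands, normalised at read time so
coverage arithmetic is strand-agnostic. The genomic coordinate convention is
a package design choice, made once to avoid off-by-one drift.

## Preprocessing

* Bead arrays: vendor background subtraction is assumed done; intensities
  get `log2(x + offset)` with a default offset of 16 to guard
  background-subtracted values near zero, then quantile normalisation.
  Probes called *absent in every sample* (detection p at or above 0.01, a
  configurable vendor-style default) are removed.
* 25-mer arrays: normal+exponential background correction of perfect-match
  intensities (posterior mean of the signal under Gaussian background and
  exponential signal; parameters per array, user-supplied or estimated by a
  simple moments fit), log2, quantile normalisation. A probe is *present*
  when it exceeds the per-array median (strictly) in at least half the
  arrays of some condition, half rounded up for odd counts.

Quantile normalisation forces each column to the rank-wise mean across
columns; ties receive the mean of the reference values they span, which
makes the operation idempotent and exactly reproducible.

## Differential expression

For two conditions with $n_1, n_2$ replicates, each probe gets
$M = \bar{x}_{case} - \bar{x}_{control}$ (log2 fold change),
$A$ (grand mean), and pooled variance $s^2$ with $d = n_1 + n_2 - 2$ degrees
of freedom. Variances are shrunk toward a prior $s_0^2$ with $d_0$ degrees
of freedom, estimated by matching the mean and variance of $\log s^2$ to a
scaled-F distribution ($\mathrm{trigamma}$ moment inversion). The posterior
variance is $\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and the moderated
statistic $t = M / \sqrt{\tilde{s}^2 (1/n_1 + 1/n_2)}$ is referred to a t
distribution with $d + d_0$ degrees of freedom. Estimated $d_0$ above 500 is
declared infinite (all probes then share $s_0^2$); $d_0 = 0$ recovers the
ordinary pooled t exactly. Probes with zero residual degrees of freedom get
p = 1 rather than being dropped.

Calls are made on the model fold change: *up* means
$M \ge \log_2(\text{fold})$ (inclusive, "at least f-fold") **and** adjusted
p below $\alpha$; *down* is symmetric. The default is fold 2, $\alpha$ 0.01
with a strict `<`; the strictness is switchable (`alpha_inclusive`) because
the two natural readings "p < 0.01" and "adjusted p of at most 0.01" differ
at the boundary. Element-level summaries count sense-detecting repeat probes
only, and report the changed/expressed fractions that headline this kind of
analysis.

## Population statistics

The rank-sum test uses midranks for ties. For pooled sizes up to 30 the
two-sided p is exact, computed by dynamic-programming enumeration of the
permutation distribution of the rank sum (valid under ties, and equal to
full enumeration — this is checked against a `combn()` oracle for all small
splits). Beyond 30 a normal approximation with tie correction and continuity
correction takes over; at 15 vs 15 the two agree within ten percent. Tests
are two-sided by default; sidedness is a parameter. Kernel density estimates
use a Gaussian kernel on a grid spanning the data ± 3 bandwidths, with
Silverman's rule of thumb as the automatic bandwidth. Each element group is
compared against expressed non-repeat probes and, where applicable, against
its enclosing family and class populations with the element itself excluded.

## Contig assembly of repeat genomic hits

RepeatMasker reports a fragmented view of each genomic repeat copy. Hits of
one element are scanned in genomic order and merged into a contig when they
are on the same chromosome and strand, separated by a genomic gap strictly
smaller than the consensus length (overlapping or book-ended hits always
qualify), and collinear on the consensus — ascending on the plus strand,
descending on the minus strand, with up to 20 nt of consensus overlap
tolerated because adjacent RepeatMasker fragments frequently overlap
slightly. Every hit lands in exactly one contig.

Derived per-contig quantities (all consensus arithmetic 1-based inclusive):

* **coverage** — union of consensus intervals over segments, divided by the
  consensus length; *full length* means coverage strictly above 0.95;
* **LTR flanking** — an internal-region contig is LTR-flanked when a partner
  LTR hit of at least 250 bp ends within 50 bp upstream *and* another begins
  within 50 bp downstream; LTR orientation is recorded but not required to
  match the contig (the flanking rule in the field is distance-based, and
  requiring strand agreement would silently drop rearranged loci);
* **deletions** — consensus gaps of at least 50 nt; gaps touching a
  consensus end are flagged terminal (truncations) and excluded from
  recurrent-deletion clustering, which single-links internal deletions whose
  start and end breakpoints each differ by at most 10 nt and reports median
  breakpoints and the fraction of contigs carrying the cluster;
* **ORF intactness** — covered fraction of a consensus ORF interval,
  strictly above 0.90;
* **probe matching** — a probe matches a contig when *any* qualifying
  placement (not only the top hit, which is arbitrary among near-identical
  loci) falls within the contig span widened by one probe length; contigs
  are then classified as matching only upregulated probes, only unaffected
  probes, both, or neither.

Nested hits of *other* elements inside a contig are ignored: only
same-element records participate in assembly.

## The synthetic-data generator

`sim_config()` describes a genome of planted repeat copies: per element a
consensus length, copy number, per-nt substitution rate, recurrent-deletion
specification (interval + fraction of copies carrying it), and optional
flanking LTRs placed within 0-10 bp of the copy ends. Copies sit on random
strands, separated by background spacers longer than any consensus so each
planted copy reassembles into its own contig. Probes are drawn from the
element consensus at footprints containing at most the mismatch budget of
planted substitutions (rejection sampling), making repeat/element/orientation
truth labels unambiguous; non-repeat probes are exact background substrings.
Expression is Gaussian on the log2 scale around per-probe baselines, with
spiked elements adding a constant log2 shift to case samples of their sense
probes, and absent calls concentrated in the lowest-baseline decile.

The default scenario mirrors the structure of the pipeline's headline
analyses at desk scale: eight elements (ERVK/ERV1/ERVL LTR elements, a LINE
and a SINE), one spiked at +2 log2 on its ten sense probes, 3 vs 3 arrays,
noise sd 0.25, and one element carrying a 399-870 consensus deletion in a
third of its six copies. These values are fixed study conditions, not tuning
knobs. What the generator does *not* emulate: phylogenetic divergence
structure among copies, indels other than the specified deletions,
cross-hybridisation, intensity-dependent (MA-curved) bias, and array spatial
artifacts. Passing the recovery tests therefore demonstrates correctness of
the pipeline's logic under a clean noise model, not robustness to every
failure mode of real arrays.

## Numerical choices and problem sizes

* Strict vs inclusive boundaries follow the definitions above ("at least"
  fold inclusive; overlap threshold inclusive; `>95%`, `>90%`, `p<0.01`
  strict; LTR distance `<= 50` inclusive; genomic gap `< consensus length`
  strict).
* Deletion-cluster breakpoint tolerance compares plain absolute differences
  (`<= 10` nt by default).
* Exact rank-sum enumeration switches to the normal approximation at a
  pooled size of 30.
* The moments estimate of $d_0$ inverts the trigamma function by Newton
  iteration; non-positive excess variance of $\log s^2$ yields
  $d_0 = \infty$.
* Test and validation workloads are sized for a desk machine: alignment
  oracles run 100 probes against a 50 kb genome; contig oracles 200 random
  hit sets; null calibration 50 simulated 2,000-probe matrices; spike
  recovery 20 simulated experiments. All random draws flow from a single
  seed, and identical inputs give byte-identical outputs.

## Limitations

Only two-group contrasts are supported (the analyses this package targets
are all mutant vs control); multi-factor designs, duplicate-correlation and
probeset-level statistics are out of scope, as are gapped/spliced probe
alignment, cross-species annotation, sequence-level realignment of loci to
the consensus, and insertion-age estimation. Population tests report raw
rank-sum p-values without multiplicity correction across groups, matching
how such comparisons are conventionally quoted.
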