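---
title: "Methods: satellite quantification, k-mer homogenization and CENH3 profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite quantification, k-mer homogenization and CENH3 profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centsat)
```

# The problem

Centromeres in maize and its wild relatives come in two genomic flavours. A
*satellite centromere* sits in a long tandem array of the 156-bp CentC
monomer; because the array copies resemble each other, short reads from
inside it cannot be placed uniquely, and the centromere is invisible to
unique-mapping ChIP-seq. A *complex centromere* occupies unique-mappable
sequence (typically nested retroelements) and shows up as a broad plateau of
CENH3 (the centromeric histone H3 variant, CENP-A in animals) ChIP
enrichment. `centsat` implements the complete short-read analysis around
this dichotomy:

1. read preprocessing (3' quality trimming, adapter removal, fixed-length
   trimming),
2. satellite quantification and per-copy polymorphism via local alignment of
   reads to a circular consensus,
3. k-mer copy-number spectra with an analytic homogeneous-array baseline,
4. binned ChIP/input enrichment with zero-coverage and satellite masking,
   complex-centromere calling, and
5. positional-drift statistics between samples,

plus a synthetic genome/read simulator that provides ground truth for all of
the above.

# Circular consensus alignment

A satellite monomer is circular: a read can begin at any rotation and may
span the junction between adjacent copies. We therefore align reads to the
*dimer* (the monomer concatenated with itself): every rotation of the
monomer is a contiguous substring of the dimer, so any junction-spanning
read aligns over its full length. Alignment is local (Smith–Waterman) with
BLASTN-style unit scores: match +1, mismatch −1, gap open −2, gap extend −1
per position. A read counts as a satellite hit when its best alignment, on
either strand, spans at least `min_aln = 125` columns (alignment columns
include gaps; identity = matches / columns, the BLAST convention).

Two implementation notes:

* **Seed prefilter.** Aligning every read against the dimer is wasteful when
  most reads are genomic background. Reads are prefiltered by exact shared
  12-mers with the dimer (either strand) before alignment. At the
  polymorphism levels modelled here (~4% per base) the probability that a
  150-nt satellite read carries no error-free 12-mer window is negligible,
  while ~99% of random background reads are discarded before the O(nm)
  step. The test suite verifies that the prefiltered path returns a subset
  of the full-alignment hits with identical scores, and that the
  full-alignment path agrees exactly with an exhaustive dynamic-programming
  oracle.
* **Score threshold.** An E-value-style significance cutoff is re-expressed
  as a raw-score threshold: random reads of the query length are aligned to
  the dimer, a Gumbel distribution is fitted to the best scores by the
  method of moments, and the threshold is the score exceeded with
  probability 1e-5 under the fit. This preserves the intent of the filter
  without re-deriving Karlin–Altschul statistics. In practice the 125-column
  length filter dominates; the score threshold is a secondary guard.

A read can be quantified against several consensuses (CentC, knob180, a
CRM-family element) independently; per-family fractions are not a partition
of the read set.

# K-mer homogenization spectra

If a satellite array were perfectly homogeneous, all reads drawn from it
would be rotations of one circular sequence, and the number of distinct
k-mers would be bounded by the monomer length. Sampling `n` reads of length
`L` and counting k-mers gives the analytic baseline

$$ \mathbb{E}[\text{copies per distinct k-mer}] = \frac{(L - k + 1)\,n}{m}, $$

where `m` is the monomer length (the number of distinct k-mer start
positions on the circle). At the analysis defaults — 30,000 sampled reads,
trimmed to 100 nt, k = 50, m = 156 — the baseline is 51 × 30000 / 156 ≈
9808 copies per distinct 50-mer. Polymorphic arrays spread the same total
k-mer mass (which is fixed at `n (L − k + 1)`) over many more distinct
k-mers, collapsing observed copy numbers orders of magnitude below the
baseline; the copy-number histogram (fractions below 100 and 2000 copies)
summarizes this collapse.

```{r baseline}
expected_homogeneous_copy(read_len = 100, n_reads = 30000, k = 50,
                          monomer_len = centc_consensus()$monomer_len)
```

**Orientation.** By default, reads assigned to the minus strand are
reverse-complemented before counting ("consensus" orientation). On a
circular repeat, mixing strands splits each repeat k-mer across two apparent
k-mers and halves apparent homogenization; an "as-read" mode is provided
for sensitivity analysis, and neither mode is asserted to be uniquely
correct. Sampling is uniform without replacement and requires the full
sample size — a shortfall is an explicit error, not a silent smaller
sample — because spectra are only comparable at matched depth. k-mers
containing N are skipped and tallied.

# Enrichment profiling and complex-centromere calling

Reads are mapped with BWA-MEM and filtered to uniquely mapping records,
operationally defined as primary alignments with MAPQ ≥ 20; the same filter
is applied to externally supplied SAM/BAM. Unique read starts are counted in
fixed bins (default 20 kb — a width at which a multi-hundred-kb centromere
spans tens of bins) and enrichment is the library-size-normalized ratio

$$ E_i = \frac{c_i / \sum_j c_j}{t_i / \sum_j t_j} $$

of ChIP (`c`) to input (`t`) counts. Two masks protect the ratio: bins with
zero input coverage (undefined ratio), and bins overlapping annotated
satellite positions, where the unique-mapping assumption fails and apparent
enrichment is unreliable. Satellite positions are annotated directly from
the reference by exact-word seeding against the consensus dimer on both
strands, merging seeds closer than one monomer, and verifying each merged
interval by local alignment.

A *complex centromere* is an enrichment peak spanning more than 500 kb.
Peaks are maximal runs of unmasked bins with enrichment at least
`min_enrich` (default 2.0), tolerating up to `max_gap_bins = 2` consecutive
interior sub-threshold or masked bins (so that a satellite island inside an
otherwise unique centromere does not split the call); the reported span
includes tolerated gaps and must exceed 500,000 bp strictly. Per chromosome,
multiple qualifying peaks — which can arise from heterozygosity — count as a
single complex centromere. The enrichment threshold is a declared free
parameter: the defining span rule is the >500-kb cut, while `min_enrich`
and `max_gap_bins` are configuration-exposed with defaults chosen for
plateaus that stand visibly above the ratio-1 baseline.

Satellite abundance across samples is related to complex-centromere counts
by Spearman rank correlation with midranks for ties (`stats::cor.test`; the
test suite cross-checks the coefficient against a brute-force midrank
computation).

# Drift statistics

Positional variation of a centromere between genetically identical
individuals is quantified by three complementary, deliberately simple
statistics computed on profiles normalized to unit mass over jointly
unmasked bins in a window: the centroid shift in bp (signed), the L1
distance between the normalized profiles (0 identical, 2 disjoint), and the
asymmetry delta (mass right of the window midpoint minus mass left, sample
B minus sample A). These are artifact-level definitions — minimal sufficient
summaries of "the profile moved", "the profiles differ" and "coverage
shifted from one flank to the other" — not estimates of a published
statistic. Their noise floor is measured, not assumed: splitting one ChIP
sample into halves and comparing the half-sample tracks against the same
input yields the pure-sampling distance against which between-individual
drift is judged. The statistics are symmetric, scale invariant, and default
to a window of the called peaks ± 500 kb.

# The simulator: what it emulates and what it does not

The generator builds genomes with i.i.d. uniform background sequence and
planted tandem arrays whose copies deviate independently from a shared
circular consensus:

* **Substitution-only copies.** Each base of each copy is substituted with
  probability `sub_rate`, always to a different base, so expected copy
  identity is exactly `1 − sub_rate`; the default `sub_rate = 0.04` models
  the observed ~96% identity of CentC copies to their consensus. An indel
  knob is deliberately absent from the default model: length-preserving
  copies keep the 125-bp alignment-length filter directly interpretable.
* **Uniform background.** i.i.d. background guarantees that non-array
  sequence is unique-mappable at desk scale, so the MAPQ-based uniqueness
  filter behaves as intended; `sub_rate = 0` arrays conversely produce
  strictly multi-mapping interiors, reproducing the satellite-centromere
  null pattern.
* **ChIP enrichment.** Read starts are sampled with weight
  `fold_enrichment` inside CENH3 domains and 1 outside; `fold_enrichment =
  1` reproduces input statistics exactly. No published generative model of
  ChIP efficiency exists for this system, so the fold is a free parameter
  (default 20, which puts domain bins far above threshold at the read
  depths used while leaving background flat).
* **Reads.** 150-nt single-end reads, uniform strand, i.i.d. substitution
  sequencing errors (default 0.2%), constant base quality (default Q35)
  with an optional low-quality 3' tail to exercise quality trimming.

Not emulated: unequal-crossover array evolution, diploid/heterozygous
genomes, realistic quality-score models, GC bias, PCR duplicates. Passing
tests therefore demonstrate correct recovery of planted structure under the
stated statistical model, not robustness to every artefact of real
libraries.

All randomness flows from one root seed through named per-stage substreams
(`stage_seed`), making every simulation byte-reproducible while keeping
stages decoupled.

# Numerical and design choices

* Coordinates are 0-based half-open in all user-facing tables and BED
  output; 1-based closed only inside Biostrings/IRanges calls.
* The 3' quality trimmer removes bases while the *terminal* base quality is
  below the threshold — the simplest rule consistent with a trim-threshold
  parameter; retained bases are never altered, and an all-low-quality read
  is discarded rather than returned empty.
* Adapter matching is a substitution-only semi-global suffix alignment:
  full internal occurrences and suffix overlaps down to `min_overlap = 1`
  are considered, N counts as a mismatch, the most-matching acceptable
  occurrence wins and ties go to the longest removed suffix. At
  `min_overlap = 1` single-base chance matches at the read end are removed,
  as in standard adapter trimmers; the minimum-length filter (100 nt) is
  applied to every read after trimming.
* The display-binning parameter inherited from genome-browser practice is
  read as 20-kb bins; hundreds of bins per chromosome are needed to resolve
  multi-hundred-kb centromeres, and the value is configurable.
* Consensus refinement is an iterative majority vote over monomer columns
  with the rotation fixed by each read's alignment start on the dimer;
  the result is reported in canonical (lexicographically minimal) rotation,
  and columns with fewer than `min_support = 3` voting reads keep the seed
  base and carry a low-support flag. The monomer length is fixed by the
  seed (substitution-only model).
* Zero-hit sides make identity-distribution comparisons an explicit error;
  a constant vector makes rank correlation an explicit error; an
  insufficient satellite pool makes sampling an explicit error naming the
  deficit.

# Problem sizes in the test suite

The suite exercises the methods at sizes chosen to keep full runs fast
while leaving no estimator data-starved: 2-Mb single-chromosome genomes for
parameter recovery (satellite fractions 0.2–2%, 60,000–100,000 input
reads), 30,000-read spectra for the homogeneous-limit check, ten replicate
seeds for boundary-recovery and null-distribution properties, and 100-read
oracle comparisons for the aligner. Statistical assertions use 3-standard-
error bands derived from the binomial sampling model of the quantity under
test.

# Known limitations

* The unique mapper is BWA-MEM; MAPQ ≥ 20 is a proxy for "exactly one best
  locus" and inherits BWA's tie-breaking behaviour.
* Consensus refinement assumes the monomer length of its seed; it corrects
  substitutions, not length variants.
* The enrichment ratio is undefined (masked) rather than smoothed in
  zero-input bins; no shrinkage is applied at low counts.
* In-memory k-mer counting targets desk-scale inputs (tens of millions of
  k-mer instances), not billions.
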