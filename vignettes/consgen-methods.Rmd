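---
title: "Methods: windowed ROH, MHC supertyping and reading-frame screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed ROH, MHC supertyping and reading-frame screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`consgen` implements the genome screens that recur in conservation
genetics of severely bottlenecked populations: how much of a genome is
autozygous (runs of homozygosity, ROH), whether the functional diversity
of the major histocompatibility complex (MHC) is shared with related
species (functional supertypes), whether candidate gene predictions are
intact (reading-frame screening), and how a phased long-read assembly is
summarised (N50, phased fraction). This vignette explains the models,
the tunable parameters, and the design decisions taken where the
methods literature leaves choices open.

## Runs of homozygosity and fROH

### Model

SNPs called against a diploid assembly are binned into non-overlapping
fixed windows (default 100 kb) laid over every contig of at least
500 kb, so each retained contig holds at least five consecutive
windows. A window *qualifies* under a heterozygosity threshold `t`
(SNP/kb) when its SNP count is at most `t * window_size / 1000`,
inclusively; for 100-kb windows the standard thresholds are perfect
autozygosity (0 SNPs) and at most 1 SNP per 100, 50, 25 and 10 kb
(1, 2, 4, 10 SNPs per window). An ROH segment is a maximal run of
qualifying windows within one contig. The autozygous genome fraction is

    fROH = sum of ROH segment lengths / cumulative window length,

with both numerator and denominator counted in whole windows. The final
partial window of a contig is kept and counted as a full window in the
denominator, which is why the cumulative window length can exceed the
summed contig length; this matches the rounding behaviour of the
window-based density tools this analysis descends from, and it is the
only reading under which the two lengths can differ in that direction.

Windowed ROH calling deliberately trades segment-boundary resolution
(100 kb granularity) for robustness to single spurious SNP calls, which
only break a run when they tip a whole window over threshold.

### Conventions

* Coordinates are 0-based half-open internally; VCF input is 1-based
  and converted on read.
* VCF filtering keeps biallelic SNPs (single-base REF and ALT) with
  FILTER `PASS` or `.`; indels, multi-allelic records and records with
  a missing genotype call are dropped. This is the narrowest reading of
  "SNPs called on the primary contigs" that a VCF supports.
* Threshold comparison is inclusive (`<=`), matching how the thresholds
  are quoted.
* Percentages are reported to one decimal with halves rounded up
  (574/10338 prints as 5.6%). Base R's round-half-even would disagree
  on exact-half cases.
* Per-contig fROH uses each contig's own windows; the median of an even
  number of contigs is the mean of the two middle values.
* `snp_encounter_rate()` is the plain quotient bp/SNPs. Applied to the
  published totals (413,114 SNPs in 1.02 Gb) it returns about 2469 bp,
  not the 2477 bp sometimes quoted; the discrepancy is the rounding of
  the 1.02 Gb figure, and the function does not try to reproduce it.

### A caution on thresholded fROH

fROH under a relaxed threshold is computed with the same window-count
formula as the perfect-autozygosity case. Published analyses sometimes
report relaxed-threshold fROH values that cannot be reconstructed from
their own window counts by this formula; `consgen` makes no attempt to
reproduce such values and reports the window-count ratio only.

## MHC functional supertypes

### Pipeline

1. **Trim** an in-frame exon-2 codon alignment to the positively
   selected sites (PSS), the antigen-binding codons. PSS are an input
   (one 1-based codon index per line); the shipped nine-position default
   only matches the synthetic generator's layout and must be replaced
   for real alignments.
2. **Translate** with the standard genetic code. Sequences with an
   alignment gap, a stop, or an unresolvable ambiguity at a selected
   codon are dropped with a warning: a single bad codon among nine
   leaves too little signal to impute.
3. **Deduplicate** identical peptides, keeping back-references to the
   member sequences and their species. All downstream clustering is on
   unique peptides; species tabulations count member sequences.
4. **Encode** each peptide as 5 values per position: the z1
   (hydrophobicity), z2 (steric bulk), z3 (polarity), z4 and z5
   (electronic effects) descriptors of Sandberg et al. (1998,
   *J. Med. Chem.* 41:2481), shipped both in code and as
   `extdata/zscales_sandberg1998.tsv` with a checksum test. Columns are
   position-major, descriptor-minor (`p1_z1..p1_z5, p2_z1..`).
5. **Cluster** with k-means: Lloyd's algorithm, k-means++
   initialisation, 25 restarts per candidate k (best total
   within-cluster sum of squares kept), at most 300 iterations.
6. **Describe** the clusters with discriminant analysis of principal
   components (DAPC) and tabulate species representation per supertype.

### Choosing the number of supertypes

In automatic mode the number of clusters minimises

    BIC(k) = n * ln(W_k / n) + k * ln(n)

over k = 2..15, where `W_k` is the total within-cluster sum of squares
over the n unique peptides. On peptide data the BIC curve is typically
flat to well under 2 units across the minimum and its neighbours:
peptide variants sit at discrete distances from their cluster's core,
and isolating one such variant changes the spherical-variance BIC by
less than the conventional evidence threshold. Following the usual
reading of BIC differences below 2 as negligible evidence (Kass &
Raftery 1995), the reported k is the **smallest candidate within 2
units of the minimum**. This parsimony tie-break is what makes the
selection stable run-to-run; `bic_tol = 0` restores the literal argmin,
and a fixed `k` bypasses selection entirely. Clustering can optionally
be run on a PCA reduction of the z-matrix (`pca_pcs`); the default
clusters the raw z-columns, and both modes are exposed because the
method literature is silent on which was used.

### DAPC details

Columns are centred, the leading `n_pcs` (default 10) principal
components retained, and linear discriminant axes computed from the
between/within scatter of the retained components via a Cholesky
whitening of the within matrix. At most k − 1 axes carry
discrimination, so `min(n_da, k - 1)` are kept. Two numerical choices:

* a singular within-cluster scatter (identical peptides per cluster, or
  more clusters than effective dimensions) gets a ridge of 1e-8 on the
  diagonal, with a warning;
* each axis is oriented so that its largest-magnitude loading on the
  original z-columns is positive. Orienting on original-variable
  loadings rather than PC-space coefficients makes coordinates
  invariant to input row order, because PC sign flips cancel out of the
  composite loading.

`MASS::lda` on the same retained components reproduces the axes up to
scaling; the test suite uses it as an independent cross-check.

## Reading-frame screening

A coding prediction is classified by frame integrity:

* **functional** — starts with ATG, ends with a stop, length divisible
  by three, no internal stop;
* **ambiguous** — not functional, but some single-nucleotide deletion
  or insertion (any base, any position) yields a functional frame: the
  signature of one sequencing error. The search is exhaustive;
  deletions are scanned left to right before insertions and the first
  recovering edit is reported. When several equivalent edits exist
  (deleting any base of a homopolymer run), the leftmost is reported.
* **pseudogene** — everything else. One edit is allowed per sequence.

The recovery search runs before any fragmentary-sequence rule:
an edit inside the start codon still counts as recoverable. Sequences
that fail recovery are described as *fragmentary* when no ATG occurs in
the first 30 nt or the longest open frame covers under half the
sequence (both thresholds configurable; the source analyses give no
number), and as frame-disrupted otherwise. Codons containing N match
neither the start nor any stop codon, so Ns never fabricate an internal
stop but do disqualify a start/stop position they fall in.

## Assembly and read statistics

* `n50()`: the smallest length L such that pieces of length at least L
  hold at least half the total bases; ties resolve to the boundary
  piece itself.
* `read_stats()`: removes reads strictly shorter than `min_len`
  (default 500 bp) and reports kept-read statistics. The mean length is
  floored to an integer bp, the convention under which
  128,622,819,749 bp over 9,859,413 reads prints as 13,045.
* `phased_fraction()`: secondary (haplotig) over primary assembly total
  size — in a phased diploid assembly the haplotigs cover the regions
  heterozygous enough to split into two haplotypes, so the size ratio
  estimates the phased genome fraction. No internal rounding; values
  above 1 are legitimate for fully phased genomes.

## Synthetic data: what it emulates and what it does not

The generators exist so that every pipeline stage can be scored against
planted ground truth; they are tested code, not fixtures.

### Diploid SNP landscapes

`simulate_genome()` alternates exponential autozygous tracts (SNP rate
`rate_in_tract`, usually 0) with background sequence, and lays SNPs
down as a Poisson process. The background rate is either uniform or
drawn per 100-kb window from a two-component gamma mixture. Outputs are
a VCF v4.2 (heterozygous biallelic SNPs, `PASS`, `GT 0/1`), a
contig-length TSV and a truth BED of exact tract coordinates; output is
byte-identical given the spec and seed.

Two ready profiles, both 10 × 100 Mb (10,000 windows) by default:

* `inbred_profile()` targets the SNP landscape of a severely inbred
  bird genome: window-density median ≈ 0.05 and mean ≈ 0.40 SNP/kb.
  The right skew comes from the mixture — 88% of windows at
  Gamma(shape 15, mean 0.045 SNP/kb), 12% at Gamma(shape 3, mean
  3.07 SNP/kb) — so most of the genome is depauperate while a minority
  of windows carries most of the variation. The autozygous fraction is
  0.02 with a 250-kb mean tract length: numerous short tracts, the
  pattern expected when inbreeding is old enough for recombination to
  have fragmented identical-by-descent segments, and short enough that
  the realised tract fraction is stable across seeds. Under this
  profile perfect-autozygosity fROH sits at a few percent while the
  ≤ 0.02 SNP/kb threshold lifts it several-fold — the qualitative
  signature of an inbred genome's threshold sensitivity.
* `outbred_profile()` is uniform 1.95 SNP/kb background with a 4.4%
  autozygous fraction; at ~195 expected SNPs per window essentially no
  background window qualifies under any threshold, so fROH barely moves
  when the threshold is relaxed.

Not emulated: linkage disequilibrium, recombination maps, coalescent
ancestry, sequencing error, genotyping bias and reference artefacts.
Passing recovery tests therefore shows that the estimators measure what
they claim on a genome whose SNP process matches the stated densities —
not that variant calling on real data is unbiased.

### Supertype-structured alignments

`simulate_supertype_alignment()` plants k centroid peptides with
pairwise z-space distance at least `min_z_separation` (default 10),
generates members per species and cluster, back-translates with random
synonymous codons, and embeds the selected codons in a padded alignment
whose non-PSS columns are conserved, so the trimming step is genuinely
exercised. Within-cluster variation is conservative by construction:
a mutated residue is replaced by its nearest z-space neighbour, and
centroid residues are drawn from the amino acids whose nearest
neighbour lies at a moderate distance (2–3.2). Two reasons: supertypes
are by definition clusters of alleles with *similar physiochemical
properties*, so members that wander to arbitrary residues would not be
members of a functional supertype at all; and homogeneous within-
cluster spread is what makes the planted k recoverable at the stated
separation rather than an artefact of a lucky seed. Defaults (k = 8,
4 species, 4 sequences per species per cluster, mutation rate 0.05)
give on the order of 40–60 unique variants, a deliberately scaled-down
analogue of a multi-species corvid exon-2 set.

Not emulated: recombination between alleles, allele-frequency
structure, alignment error, and real PSS geometry — the default PSS
layout is a placeholder.

## Problem sizes in the test suite

The suite scores oracle equivalence on 1000 random window tables,
parameter recovery on three 2-Gb genomes (planted fractions 0.05, 0.2,
0.5; 2-Mb tracts; uniform 0.5 SNP/kb background), the threshold-
sensitivity contrast on one 1-Gb inbred and one 100-Mb outbred genome,
and supertype recovery over 100 seeded generator/pipeline runs. These
sizes keep every statistical check comfortably away from its tolerance
while the whole suite runs in a few minutes on one core; all seeds are
fixed in the tests.

## Known limitations

* Window-count fROH has 100-kb resolution: tracts shorter than a
  window are invisible, and tract edges are truncated to whole windows.
* The BIC tie-break trades a small risk of under-splitting for
  stability; genuinely overlapping supertypes (separation comparable to
  within-cluster spread) are not resolvable by any k selection.
* The supertype stage assumes a correct, in-frame input alignment and
  externally supplied PSS; neither is validated biologically.
* `classify_orf` allows exactly one recovery edit per sequence;
  two sequencing errors classify as pseudogene.
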