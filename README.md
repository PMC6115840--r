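# consgen

Genome screens for conservation genetics of small, inbred populations:
windowed runs-of-homozygosity (ROH) and the autozygous genome fraction
(fROH) from VCF SNP calls, MHC class II B functional supertyping from
physiochemical z-descriptors, reading-frame integrity screening of
coding predictions, and descriptive statistics for phased long-read
assemblies — plus seeded synthetic-data generators that plant ground
truth for every stage.

The package targets the situation of a critically endangered species
sequenced as a single high-quality diploid genome: no population
panel, no SNP chip, just one assembly and its heterozygous SNP calls,
from which one wants defensible statements about inbreeding and immune
gene diversity.

## The core quantities

**fROH.** Contigs ≥ 500 kb are tiled with non-overlapping 100-kb
windows. A window qualifies as ROH under threshold *t* SNP/kb when its
SNP count ≤ *t* · 100 (perfect autozygosity: 0 SNPs; presets 0.01,
0.02, 0.04, 0.1 SNP/kb). ROH segments are maximal runs of qualifying
windows within a contig, and

&nbsp;&nbsp;&nbsp;&nbsp;fROH = Σ segment lengths / cumulative window length,

both counted in whole windows. Comparing fROH across thresholds
separates genomes whose low diversity is genome-wide (inbred: fROH
jumps when a little heterozygosity is allowed) from outbred genomes
(fROH barely moves).

**Supertypes.** Exon-2 sequences are trimmed to the positively
selected antigen-binding codons, translated, deduplicated, and encoded
as five physiochemical descriptors per position (z1 hydrophobicity, z2
steric bulk, z3 polarity, z4–z5 electronic effects; Sandberg et al.
1998). Unique peptides are clustered by k-means (Lloyd + k-means++,
25 restarts), the number of supertypes chosen by BIC(k) = n·ln(W_k/n) +
k·ln(n) with a parsimony tie-break, and described by DAPC (10 PCs,
up to 3 discriminant axes).

**Gene status.** A prediction is *functional* (complete reading
frame), *ambiguous* (one single-nucleotide insertion or deletion away
from functional — the signature of a sequencing error), or
*pseudogene* (anything else), via an exhaustive single-edit search.

## Worked example

Simulate an inbred-profile genome (3 × 100 Mb here), scan it, and
supertype a planted 8-cluster peptide set:

```r
library(consgen)

d <- tempfile()
sim  <- simulate_genome(inbred_profile(n_contigs = 3, contig_length = 1e8,
                                       seed = 11), d)
scan <- roh_scan(sim$vcf, sim$contigs)
scan
#> Windowed ROH scan
#>   3 contigs retained (3e+08 bp), 3000 windows of 100000 bp, 125156 SNPs
#>   SNP encounter rate: 1 per 2397 bp
#>   fROH [perfect]: 68/3000 windows = 2.3%
#>   fROH [0.01]: 245/3000 windows = 8.2%
#>   fROH [0.02]: 579/3000 windows = 19.3%
#>   fROH [0.04]: 1440/3000 windows = 48.0%
#>   fROH [0.1]: 2609/3000 windows = 87.0%
scan$per_contig
#> per-contig fROH over 3 contigs: min 1.6%, max 2.8%, median 2.4%, mean 2.3%
```

2.3% of windows are SNP-free, but allowing just 2 SNPs per window
(≤ 0.02 SNP/kb) lifts fROH to 19.3% — an eight-fold jump, the
threshold sensitivity characteristic of an inbred genome whose
background diversity is very low (the profile's window median is
0.05 SNP/kb). An outbred profile (`outbred_profile()`, ~1.95 SNP/kb)
shows essentially no jump.

```r
d2  <- tempfile()
st  <- simulate_supertype_alignment(supertype_spec(k = 8, seed = 11), d2)
fit <- supertype(st$fasta, pss = st$pss, species = st$species, seed = 1)
fit
#> MHC functional supertype model
#>   52 unique peptide variants (9 positions) from 128 sequences
#>   8 supertypes (BIC-selected)
#>   DAPC: 10 PCs, 3 discriminant axes; eigenvalues 669, 443, 338

classify_orf("ATGAAAATAA")   # one extra base in a lysine run
#> ambiguous (deleting 1 nt at position 4 recovers a complete frame)
```

The eight planted supertypes are recovered from the 52 unique peptide
variants, and `fit$species_table` tabulates how many sequences each
species contributes per supertype (the stacked-bar view of repertoire
sharing).

A command-line interface over all stages ships as `inst/cli/consgen`
(subcommands `roh`, `supertype`, `gene-screen`, `stats`, `simulate`;
every run writes a provenance record and is byte-identical given the
same seed).

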