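---
title: "Mapping gene-usage QTLs in immunoglobulin light-chain repertoires"
author: "guqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gene-usage QTLs in immunoglobulin light-chain repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guqtl)
```

## The model

Antibody light chains are assembled by V(D)J recombination from the IGK and
IGL loci, and the frequency with which each V or J gene appears among a
person's unique B-cell receptor (BCR) sequences — its *usage* — is a
heritable, genetically structured trait. `guqtl` maps *cis* variants
associated with usage (guQTLs) by ordinary least squares of the per-sample
usage frequency on alternate-allele dosage:

$$ c_{gs} = \alpha_g + \beta_{gv} \, d_{vs} + \varepsilon, $$

where $c_{gs}$ is the usage frequency of gene $g$ in sample $s$ (counts
over the per-sample partition total) and $d_{vs} \in \{0, 1, 2\}$ the
dosage of variant $v$. The additive coding covers SNVs and copy-number SVs
alike: for a deletion SV, dosage is the number of deleted haplotypes, so a
usage that falls with each lost haploid gene copy appears as a negative
slope. Significance is two-sided from the slope's t statistic; the variance
explained is reported as adjusted $R^2 = 1 - (1 - R^2)(n-1)/(n-2)$.

Usage frequencies are regressed untransformed. Usage effects in this size
range are approximately linear in dosage, and the plain model keeps the
slope interpretable as "usage change per allele copy"; a transform hook
exists for sensitivity analyses but is off by default. No covariates enter
the baseline model; a covariate hook is present but empty by default.

### Multiple testing and leads

Correction is per trait (per gene, or per CDR3 property). Variants in
perfect LD carry no independent information, so the Bonferroni denominator
is the number of *perfect-LD classes*: connected components of the graph
joining pairs with genotype $r^2 = 1$ (tolerance $10^{-12}$ on $1 - r^2$).
Untestable variants (constant dosage on the usable samples) are excluded
from the denominator — they represent no hypothesis test. The *lead* for a
trait is the LD class containing the smallest p-value; all members of that
class are co-leads (they are statistically one signal), and the reported
class representative is the lowest genomic position, breaking ties
lexicographically by id. Genotype $r^2$ (squared Pearson correlation of
dosage vectors over pairwise-complete samples) is used rather than
haplotype $r^2$; a haplotype-based alternative can be computed from the
phased matrices the containers carry.

### Repertoire partitions

Sequences with 100% identity to their assigned germline V *and* J alleles
are "unmutated" (enriched for antigen-naive BCRs); any mismatch in either
segment makes a sequence "mutated" (enriched for somatic hypermutation).
The partition is exhaustive and disjoint, and identities are compared
exactly — they are ratios of integer match counts upstream, so no rounding
tolerance is applied. Usage matrices are computed per partition with two
filters: samples need at least 100 sequences in the partition, and genes
need a count of at least 10 in at least one retained sample. Frequencies
stay relative to the full per-sample partition total — the gene filter only
trims rows, it does not renormalize columns — so values remain
interpretable as "fraction of all unique sequences in the partition".

Proximal/distal paralog pairs whose allele sequences cannot be
distinguished are collapsed to a single "ambi" unit before counting (the
shipped default map covers the five IGK pairs and the IGLJ2/IGLJ3
cassettes). Collapsing rewrites only the gene portion of a call and
preserves the allele suffix, so coding-allele analyses can still recover
allele frequencies downstream; it is idempotent. For pairs that *can* be
separated in some individuals, `assess_paralog_disambiguation()` applies
the set-disjointness rule (every proximal allele distinct from every distal
allele) per sample, so analyses can be restricted to the disambiguable
subset.

### CDR3 properties

The CDR3 is the junction minus its first and last residue (the conserved
cysteine and phenylalanine/tryptophan). Nine per-sequence properties are
averaged per sample, one vote per unique sequence: length; GRAVY
(Kyte–Doolittle mean); bulkiness (Zimmerman mean); aliphatic index on mole
fractions with coefficients 1 (Ala), 2.9 (Val), 3.9 (Ile/Leu); polarity
(Grantham mean); net side-chain charge at pH 7.4 via Henderson–Hasselbalch
with EMBOSS pKa values, termini excluded; and acidic (D/E), basic (R/H/K)
and aromatic (F/W/H/Y) fractions. Each scale is a named, swappable table
(`aa_scales`). Sequences with non-standard residues or an empty trimmed
CDR3 are excluded from the means and counted. Whether real pipelines weight
these means by duplicate counts is ambiguous; we deliberately weight each
unique sequence once, and a dedup switch is available upstream.

### LD blocks

Pairwise D′ is computed from two-locus haplotype counts — directly where
genotypes are phased, otherwise via a two-locus EM (50 iterations or
$\Delta < 10^{-8}$). The 90% confidence interval comes from the likelihood
of $|D'|$ on a 101-point grid with allele marginals fixed at their observed
values and a flat prior; the 5th/95th percentiles of the normalized
posterior give the bounds. Pairs are classified per the Gabriel rules:
strong LD when CI low $\ge 0.70$ and CI high $\ge 0.98$; strong
recombination when CI high $< 0.90$; otherwise non-informative. A candidate
block is any run of consecutive SNVs in which at least 95% of informative
pairs are strong; non-overlapping blocks are selected greedily, longest
span first with ties to the left — the original thresholds are kept
unmodified, and the greedy order is fixed for determinism since the
reference tools leave it unspecified. Coordinates are 1-based inclusive
internally; BED input/output converts at the boundary.

### Networks, cliques, allele linkage, enrichment

Each gene's significant variants form a set; genes sharing at least one
variant are joined by an edge labeled with the shared count and the Jaccard
similarity. Maximal cliques (size $\ge 2$, Bron–Kerbosch with pivoting) mark
groups of genes all pairwise co-associated — maximal cliques rather than
all cliques, since subclique structure is recoverable from the edge list.
Coding-allele linkage to the lead genotype is a two-way Fisher's exact
test on an alleles-by-genotype-group table; cells count diploid allele
copies by default (a carrier-based mode exists — the counting unit is a
genuine ambiguity, and copies are the more informative default). Genes with
a major-allele frequency above 95% are labeled as lacking appreciable
allelic variation and skipped. Tables beyond 5x5 or 200 counts switch to
Monte Carlo with a fixed, logged seed. Track enrichment is a one-sided
(greater) Fisher test of guQTL membership against track overlap.

## The synthetic locus

The simulator is first-class, tested code: it generates the cohort that the
rest of the package is verified against.

* **Layout** — `n_blocks` non-overlapping 10-kbp blocks tile a pseudo-locus.
  V-like genes carry leader (L-Part1), intron, V-exon and an RSS
  (heptamer/spacer/nonamer); J-like genes a single exon plus RSS — the two
  anatomies found at these loci.
* **Haplotype pools** — each block has a pool of `haplotypes_per_block`
  haplotypes built on a random genealogy under an infinite-sites,
  recombination-free model: each SNV mutates once on a clade, so no
  within-block pair shows all four gametes and $|D'| = 1$ within blocks,
  which is exactly the structure the Gabriel caller is designed to detect.
  Blocks are drawn independently, so between-block LD is at equilibrium in
  expectation. The first two SNVs of every block co-segregate exactly — a
  planted $r^2 = 1$ pair that must always collapse to one effective test.
* **Usage model** — per sample and gene, the log propensity is
  $\log w = \log b_g + \beta_g d_{vs} + \eta_{gs} + \log(\mathrm{cn}/2)$,
  with baseline $b_g$ (geometric decay, 2-fold per 6 genes, mimicking
  skewed real usage), planted effect $\beta_g$ at the causal variant,
  per-sample log-normal noise $\eta$ (sd 0.25 — biological variability that
  keeps single-variant $R^2$ realistic rather than degenerate), and diploid
  copy number from any deletion SV. V and J propensities are normalized
  separately (every sequence uses one of each); counts are multinomial.
  This multiplicative model is a stand-in — its $\beta$ is on the
  log-propensity scale and is *not* unit-comparable to the regression beta,
  but for small effects usage is approximately linear in dosage, matching
  the additive copy-number behavior seen in real data. The mutated
  partition re-draws counts with $\beta$ attenuated (default halved),
  emulating the blunting of genetic effects after antigen experience.
* **Repertoires** — junctions are built as conserved C + germline V-end +
  a Poisson(3)-length N region of uniform residues + germline J-start +
  conserved F. Allele catalogs give each gene two coding alleles tagged to
  the block haplotype at the block's first SNV (coding variation in LD with
  non-coding SNVs); a subset of V genes get aromatic-rich V-ends so usage
  shifts propagate into CDR3 composition. Somatic hypermutation is emulated
  by recording identities below 1 on a `mutated_fraction` of sequences
  without simulating base changes — sufficient for the partition rule,
  deliberately not a nucleotide-level SHM model.
* **Defaults as study conditions** — 160 donors, 20 genes, 5 blocks of 12
  SNVs from 4-haplotype pools, $10^4$ sequences per repertoire, 6 planted
  effects of $|\beta| = 0.6$ with alternating sign, one gene-deletion SV at
  carrier frequency 0.2, mutated fraction 0.3. These emulate a
  population-scale light-chain cohort at a tractable sequence depth (real
  repertoires run $10^4$–$3\times10^4$ unique sequences).

What the simulator does *not* emulate — and what passing tests therefore do
not show about real data: read-level errors and UMI consensus artifacts,
nucleotide-level SHM and its gene-composition biases, clonal expansion
(sequences are drawn independently), ancestry stratification, heavy-chain
pairing, and recombination *within* blocks. Inference on real cohorts
additionally faces annotation error from incomplete germline references,
which the simulator sidesteps by emitting pre-annotated tables.

## Numerical choices and degenerate inputs

* Perfect-LD tolerance $10^{-12}$ on $1 - r^2$; dosage vectors are small
  integers, so exact duplicates (or exact complements) are the only pairs
  that qualify.
* A monomorphic variant pair is *undefined* for LD — reported missing, not
  zero; constant-dosage variants are untestable and leave the Bonferroni
  denominator; a constant trait gives $\beta = 0$, $p = 1$.
* Fold change uses homozygous groups (0 vs 2) when both exist, else the
  extreme observed dosage groups; a zero smaller-group mean reports `Inf`.
* D′ grid: 101 points is well below the CI's 5-percentile granularity at
  the sample sizes involved; the observed-sign branch of $D_{max}$ is used
  for the constrained likelihood.
* Missing genotypes drop samples pairwise per variant (vcftools
  convention).
* All stage randomness derives from one seed with fixed offsets, so every
  output file is byte-identical across runs; the AIRR manifest stores paths
  relative to the run directory to keep runs relocatable.

## Verification strategy and problem sizes

The test suite checks each stage against an independent route: the Gabriel
caller against exhaustive interval enumeration (200 random instances of up
to 8 SNVs by 40 samples), clique finding against brute-force subset
checking (100 graphs up to 12 nodes), Fisher p-values against direct
hypergeometric enumeration (every 2x2 table with $N \le 30$, both
alternatives), and the OLS scan against closed-form normal equations.
Simulation studies use 160-donor cohorts: planted effects with marginal
$R^2 \ge 0.3$ must be recovered as the lead LD class in at least 90% of
replicates (sign in 99%), null cohorts must keep the per-gene family-wise
error within its binomial band of 0.05, and planted block boundaries must
be recovered within one SNV for at least 80% of blocks. These replicate
counts (100–200) and cohort sizes were chosen to make the binomial bands
tight enough to be informative while keeping the default suite fast.

## Known limitations

* Single-variant models only: no conditional/secondary QTL analysis, no
  mixed models or ancestry covariates in the baseline.
* The two-locus EM is the only phasing machinery; fully unphased cohorts
  get EM-based D′ but no long-range haplotypes.
* SV genotypes are consumed, not discovered; paralog collapsing relies on
  the provided ambiguity map being correct for the cohort's annotation.
* The usage matrix treats input rows as unique BCRs; duplicate collapsing
  is assumed to have happened upstream (an optional dedup switch exists).
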