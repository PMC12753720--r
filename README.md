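# guqtl

Gene-usage QTL mapping for immunoglobulin light-chain repertoires.

## The problem

The composition of the expressed antibody repertoire differs widely between
people, and a large part of that variation is germline-genetic: variants in
the immunoglobulin kappa (IGK) and lambda (IGL) loci shift how often
individual V and J genes are selected during V(D)J recombination. A variant
whose genotype associates with the usage frequency of a gene in the
repertoire is a **gene-usage QTL (guQTL)**. `guqtl` implements the full
analysis chain for mapping such loci from AIRR-seq rearrangement tables and
cohort variant genotypes, for immunogenetics researchers who want a tested,
reusable, and fully simulatable version of this analysis:

1. **Repertoire processing** — AIRR Rearrangement TSVs are ingested,
   indistinguishable gene paralogs are collapsed to single "ambi" units
   (e.g. `IGKV1-39`/`IGKV1D-39` → `IGKV1-39ambi`), sequences are partitioned
   into unmutated (`v_identity == 1` and `j_identity == 1`, naive-enriched)
   and mutated (antigen-experienced) sets, and an m genes x n samples usage
   matrix C is computed per partition, with `c[g, s] = count(g, s) /
   total(s)`. Nine CDR3 physicochemical properties (length, GRAVY,
   bulkiness, aliphatic index, polarity, net charge, acidic/basic/aromatic
   fractions) are averaged per sample.
2. **Variant genotypes** — multi-sample VCFs are loaded (multiallelics
   split), filtered to common variants (MAF >= 5%), and annotated against
   feature tracks (V-exon, intron, leader, RSS heptamer/spacer/nonamer).
3. **Association** — each trait (gene usage or CDR3 property mean) is
   regressed on allele dosage (additive 0/1/2 coding) per variant:
   `trait = alpha + beta * dosage + eps`. Bonferroni correction is applied
   per trait over the *effective* number of tests: variants in perfect LD
   (genotype r² = 1) count as a single test. The lead is the smallest-p LD
   class; fold change between extreme genotype groups is attached.
4. **LD structure** — pairwise D′ with likelihood-based 90% confidence
   intervals and Gabriel-style haplotype blocks (strong LD: CI low >= 0.70
   and high >= 0.98; strong recombination: CI high < 0.90; block: >= 95% of
   informative pairs strong).
5. **Co-regulation** — genes sharing significant variants form a network
   (edges weighted by shared counts and Jaccard similarity); maximal cliques
   mark co-regulated gene groups. Coding-allele linkage to lead genotypes is
   tested by Fisher's exact test; feature-track enrichment by one-sided
   Fisher.
6. **Synthetic locus** — a seeded simulator generates a diploid cohort with
   block-structured LD (haplotype pools drawn from per-block genealogies, so
   blocks are Gabriel-detectable), common SNVs, gene-deletion SVs, coding
   alleles in LD with non-coding haplotypes, and AIRR repertoires whose gene
   usage follows a log-linear dosage model — with machine-readable ground
   truth, so every stage is verifiable without external data.

## Worked example

```r
library(guqtl)

cfg <- sim_config(n_samples = 60, n_genes = 12, n_blocks = 3,
                  snvs_per_block = 8, sequences_per_sample = 4000,
                  seed = 777)
pc <- pipeline_config(simulation = cfg, out_dir = "demo_run", seed = 777,
                      min_gene_count = 5, min_sample_sequences = 50)
res <- run_pipeline(pc)

res$assoc$unmutated$thresholds[1:2]
#>     trait alpha n_effective   threshold
#>    <char> <num>       <int>       <num>
#> 1: simV01  0.05          12 0.004166667
#> 2: simV02  0.05          12 0.004166667

gu <- res$assoc$unmutated$results
gu[gu$trait == "simV03" & gu$is_lead,
   c("variant_id", "beta", "p_value", "adjusted_r2", "ld_class",
     "fold_change")]
#>    variant_id        beta      p_value adjusted_r2 ld_class fold_change
#> 1:  snv_b1_03 -0.04613817 9.182833e-13   0.5808232        2    3.988896
#> 2:  snv_b1_04 -0.04613817 9.182833e-13   0.5808232        2    3.988896
```

Reading: the 25 common variants collapse into 12 effective tests
(perfect-LD classes), so each gene's Bonferroni threshold is 0.05 / 12.
Gene `simV03` has two *co-lead* variants — `snv_b1_04` is the planted
causal variant and `snv_b1_03` is in perfect LD with it, so they are
statistically one signal (one LD class, identical regression output). Each
alternate-allele copy lowers `simV03` usage by ~4.6 percentage points,
explaining ~58% of the usage variance, with a 4.0-fold mean usage
difference between the extreme genotype groups. `demo_run/` additionally
contains the LD block table, the shared-guQTL network and cliques,
CDR3-property QTLs, and the unmutated/mutated comparison.

A thin CLI wrapper ships at `inst/cli/guqtl-pipeline.R`:

```sh
Rscript inst/cli/guqtl-pipeline.R run-all --seed 42 --out-dir run42
```

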