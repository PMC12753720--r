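# Synthetic locus generator: determinism, planted LD, genotype sampling and
# the genotype-dependent usage model.

test_that("locus simulation is deterministic and lays out blocks correctly", {
  cfg <- sim_config(n_samples = 20, n_genes = 8, n_blocks = 3,
                    snvs_per_block = 5, seed = 5)
  t1 <- simulate_locus(cfg)
  t2 <- simulate_locus(cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$variants), 15L)
  expect_true(all(diff(t1$variants$pos) > 0))
  # blocks tile the locus without overlap
  expect_true(all(t1$variants$pos[t1$variants$block == 1] <= 10000))
  expect_true(all(t1$variants$pos[t1$variants$block == 2] > 10000))
  # feature sub-intervals nest inside gene intervals
  for (i in seq_len(nrow(t1$genes))) {
    f <- t1$features[t1$features$gene == t1$genes$gene[i], ]
    expect_true(all(f$start >= t1$genes$start[i]))
    expect_true(all(f$end <= t1$genes$end[i]))
  }
  # every causal variant exists; every gene has alleles
  expect_true(all(t1$causal_map$variant %in% t1$variants$id))
  expect_true(all(t1$genes$gene %in% t1$alleles$gene))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_samples = 0), "positive")
  expect_error(sim_config(haplotypes_per_block = 1), ">= 2")
  expect_error(sim_config(mutated_fraction = 1.2), "mutated_fraction")
  expect_error(sim_config(baseline_usage = c(1, -1, rep(1, 18))),
               "positive")
})

test_that("a two-haplotype pool forces r2 = 1 between its SNVs", {
  cfg <- sim_config(n_samples = 60, n_genes = 4, n_blocks = 1,
                    snvs_per_block = 4, haplotypes_per_block = 2, seed = 3)
  truth <- simulate_locus(cfg)
  geno <- simulate_cohort_genotypes(truth, cfg)
  ids <- truth$variants$id
  for (a in 2:length(ids)) {
    expect_equal(pool_r2(truth, ids[1], ids[a]), 1, tolerance = 1e-12)
    expect_equal(genotype_r2(geno$dosage[1, ], geno$dosage[a, ]), 1,
                 tolerance = 1e-12)
  }
})

test_that("planted co-segregating pair keeps r2 = 1 in sampled cohorts", {
  for (seed in c(2, 9, 31)) {
    cfg <- tiny_config(seed = seed)
    truth <- simulate_locus(cfg)
    geno <- simulate_cohort_genotypes(truth, cfg)
    for (b in seq_len(cfg$n_blocks)) {
      ids <- truth$variants$id[truth$variants$block == b][1:2]
      expect_equal(genotype_r2(geno$dosage[ids[1], ], geno$dosage[ids[2], ]),
                   1, tolerance = 1e-12)
    }
  }
})

test_that("cohort genotypes: phasing, dosage, MAF and SV carriers", {
  cfg <- tiny_config(seed = 17)
  truth <- simulate_locus(cfg)
  vcf <- tempfile(fileext = ".vcf")
  geno <- simulate_cohort_genotypes(truth, cfg, vcf_path = vcf)
  expect_identical(geno$dosage, geno$hap1 + geno$hap2)

  # VCF round trip preserves phased dosages
  vs <- load_variants(vcf)
  snv <- vs$variants$type == "SNV"
  expect_true(all(vs$phased))
  common <- intersect(rownames(geno$dosage), vs$variants$id[snv])
  expect_identical(unname(vs$dosage[common, geno$samples]),
                   unname(geno$dosage[common, ]))

  # observed MAF close to pool expectation: binomial interval on 2n draws
  for (b in 1:2) {
    H <- truth$haplotype_pool[[b]]
    ids <- truth$variants$id[truth$variants$block == b]
    pool_f <- colMeans(H)
    for (k in seq_along(ids)) {
      f_obs <- mean(geno$dosage[ids[k], ]) / 2
      se <- sqrt(pool_f[k] * (1 - pool_f[k]) / (2 * cfg$n_samples))
      expect_lt(abs(f_obs - pool_f[k]), 4 * se + 1e-9)
    }
  }
})

test_that("SV carrier frequency zero means diploid copy number everywhere", {
  cfg <- tiny_config(seed = 23,
                     sv_spec = data.frame(genes = "simV08",
                                          carrier_freq = 0))
  truth <- simulate_locus(cfg)
  geno <- simulate_cohort_genotypes(truth, cfg)
  expect_true(all(geno$copy_number == 2L))
})

test_that("homozygous deletion yields zero usage for the gene", {
  cfg <- tiny_config(seed = 29,
                     sv_spec = data.frame(genes = "simV08",
                                          carrier_freq = 0.5))
  truth <- simulate_locus(cfg)
  geno <- simulate_cohort_genotypes(truth, cfg)
  cn0 <- geno$copy_number["simV08", ] == 0L
  expect_gt(sum(cn0), 0)  # carrier freq 0.5 -> ~25% homozygous deleted
  uc <- simulate_usage_counts(truth, geno, cfg)
  expect_true(all(uc$unmutated$counts["simV08", cn0] == 0L))
  expect_true(all(uc$mutated$counts["simV08", cn0] == 0L))
})

test_that("null effects give genotype-independent expected usage", {
  cfg <- tiny_config(seed = 41,
                     causal_map = data.frame(gene = character(),
                                             variant = character(),
                                             beta = numeric()),
                     sample_noise_sd = 0)
  truth <- simulate_locus(cfg)
  geno <- simulate_cohort_genotypes(truth, cfg)
  uc <- simulate_usage_counts(truth, geno, cfg)
  # with no planted effect or noise, multinomial probabilities depend only
  # on copy number; undeleted genes have identical probs across samples
  probs <- uc$unmutated$probs
  intact <- rownames(probs)[apply(geno$copy_number == 2L, 1, all)]
  intact_v <- intersect(intact, truth$genes$gene[truth$genes$class == "V"])
  del_gene <- truth$svs$genes[1]
  keep <- setdiff(intact_v, del_gene)
  # probabilities vary only through the deleted gene's copy number
  for (g in keep) {
    expect_lt(diff(range(probs[g, ])) / mean(probs[g, ]), 0.30)
  }
})

test_that("mutated fraction follows its binomial expectation", {
  cfg <- tiny_config(seed = 47, mutated_fraction = 0.3,
                     sequences_per_sample = 10000L, n_samples = 4L)
  truth <- simulate_locus(cfg)
  geno <- simulate_cohort_genotypes(truth, cfg)
  out <- simulate_repertoires(truth, geno, cfg, tempfile("airr"))
  recs <- load_rearrangements(out$manifest$path, out$manifest$sample_id)
  n_mut <- sum(recs$v_identity < 1 | recs$j_identity < 1)
  n_tot <- nrow(recs)
  se <- sqrt(0.3 * 0.7 * n_tot)
  expect_lt(abs(n_mut - 0.3 * n_tot), 4 * se)
  # mutated rows always have at least one identity < 1; unmutated both == 1
  expect_true(all(recs$v_identity <= 1 & recs$j_identity <= 1))
})

test_that("downstream usage converges to the propensity expectation", {
  cfg <- sim_config(n_samples = 12, n_genes = 10, n_blocks = 2,
                    snvs_per_block = 5, sequences_per_sample = 10000L,
                    seed = 53)
  truth <- simulate_locus(cfg)
  geno <- simulate_cohort_genotypes(truth, cfg)
  out <- simulate_repertoires(truth, geno, cfg, tempfile("airr"))
  recs <- load_rearrangements(out$manifest$path, out$manifest$sample_id)
  parts <- partition_by_mutation(recs)
  um <- compute_usage_matrix(parts$unmutated, axis = "V",
                             min_gene_count = 1, min_sample_sequences = 1)
  probs <- out$counts$unmutated$probs
  totals <- out$counts$unmutated$totals
  names(totals) <- colnames(probs)
  v_genes <- truth$genes$gene[truth$genes$class == "V"]
  n_ok <- 0L; n_cells <- 0L
  for (g in intersect(v_genes, rownames(um$values))) {
    for (s in um$samples) {
      p <- probs[g, s]
      se <- sqrt(p * (1 - p) / totals[s])
      n_cells <- n_cells + 1L
      if (abs(um$values[g, s] - p) <= 3 * se + 1e-12) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / n_cells, 0.95)
})

test_that("repertoire files are byte-identical across runs with one seed", {
  cfg <- sim_config(n_samples = 6, n_genes = 8, n_blocks = 2,
                    snvs_per_block = 4, sequences_per_sample = 500,
                    seed = 59)
  run <- function(dir) {
    truth <- simulate_locus(cfg)
    geno <- simulate_cohort_genotypes(truth, cfg,
                                      vcf_path = file.path(dir, "c.vcf"))
    simulate_repertoires(truth, geno, cfg, file.path(dir, "airr"))
    write_truth(truth, file.path(dir, "truth.json"))
  }
  d1 <- tempfile("runA"); d2 <- tempfile("runB")
  dir.create(d1); dir.create(d2)
  run(d1); run(d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("truth JSON round-trips losslessly", {
  cfg <- tiny_config(seed = 61)
  truth <- simulate_locus(cfg)
  path <- tempfile(fileext = ".json")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_equal(back$causal_map, truth$causal_map)
  expect_equal(back$haplotype_pool, truth$haplotype_pool)
  expect_equal(back$variants, truth$variants)
  expect_equal(back$baseline_usage, truth$baseline_usage)
  expect_equal(back$svs$carrier_freq, truth$svs$carrier_freq)

  # empty causal map round-trips too
  cfg2 <- tiny_config(seed = 67,
                      causal_map = data.frame(gene = character(),
                                              variant = character(),
                                              beta = numeric()))
  t2 <- simulate_locus(cfg2)
  p2 <- tempfile(fileext = ".json")
  write_truth(t2, p2)
  expect_equal(nrow(read_truth(p2)$causal_map), 0L)
})

test_that("genes without planted effects have slopes centered at zero", {
  slopes <- c()
  for (seed in 1:8) {
    cfg <- sim_config(n_samples = 80, n_genes = 10, n_blocks = 2,
                      snvs_per_block = 5, sequences_per_sample = 3000,
                      seed = 100 + seed,
                      causal_map = data.frame(gene = "simV01",
                                              variant = NA_character_,
                                              beta = 0.6))
    truth <- simulate_locus(cfg)
    geno <- simulate_cohort_genotypes(truth, cfg)
    uc <- simulate_usage_counts(truth, geno, cfg)
    usage <- sweep(uc$unmutated$counts, 2, pmax(uc$unmutated$totals, 1), "/")
    # a null gene in a different block than the causal one
    v <- truth$variants$id[truth$variants$block == 2][3]
    fit <- regress_trait_on_dosage(usage["simV05", ], geno$dosage[v, ])
    slopes <- c(slopes, fit$beta)
  }
  expect_lt(abs(mean(slopes)), 2 * sd(slopes) / sqrt(length(slopes)) + 0.02)
})
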