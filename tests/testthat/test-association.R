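# Association mapping: perfect-LD classes, Bonferroni, OLS, lead selection
# and fold change.

test_that("perfect-LD classes are connected components of r2 = 1 pairs", {
  d <- rbind(v1 = c(0, 1, 2, 0, 1),
             v2 = c(0, 1, 2, 0, 1),    # identical to v1
             v3 = c(2, 1, 0, 2, 1),    # perfect negative correlate of v1
             v4 = c(0, 0, 1, 2, 2))
  cl <- perfect_ld_classes(d)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(cl[["v1"]], cl[["v2"]])
  expect_equal(cl[["v1"]], cl[["v3"]])  # transitive through components
  expect_false(cl[["v1"]] == cl[["v4"]])

  # no perfect pairs -> every variant its own class
  d2 <- rbind(a = c(0, 1, 2, 0), b = c(0, 0, 1, 2), c = c(2, 0, 1, 0))
  expect_equal(length(unique(perfect_ld_classes(d2))), 3L)
})

test_that("Bonferroni threshold is alpha over effective tests", {
  expect_equal(bonferroni_threshold(0.05, 1000), 5e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 1351), 0.05 / 1351)
  expect_error(bonferroni_threshold(0.05, 0), "n_effective")
})

test_that("OLS on dosage matches the closed-form example and lm oracle", {
  fit <- regress_trait_on_dosage(c(0.1, 0.1, 0.2, 0.2, 0.3, 0.3),
                                 c(0, 0, 1, 1, 2, 2))
  expect_equal(fit$beta, 0.1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # constant trait -> beta 0, p 1; constant dosage -> untestable
  expect_equal(regress_trait_on_dosage(rep(0.2, 5),
                                       c(0, 1, 2, 1, 0))$p_value, 1)
  expect_false(regress_trait_on_dosage(runif(5), rep(2, 5))$testable)

  # random instances against stats::lm
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- sample(0:2, n, replace = TRUE)
    if (length(unique(x)) < 2) next
    y <- 0.3 * x + rnorm(n)
    fit <- regress_trait_on_dosage(y, x)
    lmfit <- summary(lm(y ~ x))
    expect_equal(fit$beta, unname(coef(lmfit)[2, 1]), tolerance = 1e-10)
    expect_equal(fit$p_value, unname(coef(lmfit)[2, 4]), tolerance = 1e-10)
    expect_equal(fit$adjusted_r2, lmfit$adj.r.squared, tolerance = 1e-10)
  }
})

test_that("regression is sample-order invariant and sign-flips with coding", {
  set.seed(33)
  x <- sample(0:2, 30, replace = TRUE)
  y <- 0.1 * x + rnorm(30, sd = 0.2)
  f1 <- regress_trait_on_dosage(y, x)
  ord <- sample(30)
  f2 <- regress_trait_on_dosage(y[ord], x[ord])
  expect_equal(f1, f2)
  f3 <- regress_trait_on_dosage(y, 2 - x)  # ref/alt flip
  expect_equal(f3$beta, -f1$beta)
  expect_equal(f3$p_value, f1$p_value, tolerance = 1e-12)
})

test_that("fold change uses homozygous groups and handles edge cases", {
  tr <- c(0.01, 0.01, 0.02, 0.037, 0.037)
  ds <- c(0, 0, 1, 2, 2)
  expect_equal(fold_change(tr, ds), 3.7, tolerance = 1e-12)
  expect_equal(fold_change(c(1, 1, 1, 1), c(0, 0, 2, 2)), 1)
  expect_equal(fold_change(c(0, 0, 0.5, 0.5), c(0, 0, 2, 2)), Inf)
  # no homozygous-alt group: extreme observed dosage groups are used
  expect_equal(fold_change(c(0.1, 0.1, 0.3, 0.3), c(0, 0, 1, 1)), 3)
  expect_true(is.na(fold_change(c(0.1, 0.2), c(1, 1))))
})

test_that("guQTL scan finds the planted causal class and reports leads", {
  cfg <- sim_config(n_samples = 120, n_genes = 10, n_blocks = 3,
                    snvs_per_block = 6, sequences_per_sample = 4000,
                    seed = 83,
                    causal_map = data.frame(gene = "simV02",
                                            variant = "snv_b1_04",
                                            beta = 0.7))
  truth <- simulate_locus(cfg)
  geno <- simulate_cohort_genotypes(truth, cfg)
  uc <- simulate_usage_counts(truth, geno, cfg)
  usage <- structure(list(
    genes = rownames(uc$unmutated$counts),
    samples = geno$samples,
    values = sweep(uc$unmutated$counts, 2,
                   pmax(uc$unmutated$totals, 1), "/"),
    partition = "unmutated", axis = "V"), class = "usage_matrix")
  vs <- as_variant_set(geno)
  res <- run_guqtl(usage, vs)
  r <- res$results
  lead <- r[r$trait == "simV02" & r$is_lead]
  expect_gt(nrow(lead), 0)
  causal_class <- r$ld_class[r$trait == "simV02" &
                               r$variant_id == "snv_b1_04"]
  expect_equal(unique(lead$ld_class), causal_class)
  expect_true(all(lead$significant))
  # beta sign matches the planted positive effect at the causal variant
  expect_gt(r$beta[r$trait == "simV02" & r$variant_id == "snv_b1_04"], 0)

  # significance counts are monotone in threshold stringency
  n_sig_strict <- sum(r$p_value < res$thresholds$threshold[1] / 10,
                      na.rm = TRUE)
  expect_lte(n_sig_strict, sum(r$significant))

  # effective tests <= testable variants
  expect_lte(res$thresholds$n_effective[1], nrow(vs$variants))
})

test_that("scan errors on disjoint samples and skips absent genes", {
  d <- rbind(v1 = c(0, 1, 2, 0, 1))
  vs <- vs_from_haps(d, d * 0L)
  usage <- structure(list(genes = "g1", samples = c("X1", "X2"),
                          values = matrix(0.5, 1, 2,
                                          dimnames = list("g1",
                                                          c("X1", "X2"))),
                          partition = "unmutated", axis = "V"),
                     class = "usage_matrix")
  expect_error(run_guqtl(usage, vs), "overlapping")
})

test_that("property QTLs recover a planted composition shift", {
  # aromatic-rich gene simV01 under genetic control shifts sample-mean CDR3
  # aromaticity with genotype
  cfg <- sim_config(n_samples = 60, n_genes = 8, n_blocks = 2,
                    snvs_per_block = 5, sequences_per_sample = 3000,
                    seed = 97, mutated_fraction = 0.2,
                    causal_map = data.frame(gene = "simV01",
                                            variant = "snv_b1_03",
                                            beta = 1.2))
  truth <- simulate_locus(cfg)
  geno <- simulate_cohort_genotypes(truth, cfg)
  out <- simulate_repertoires(truth, geno, cfg, tempfile("airr"))
  recs <- load_rearrangements(out$manifest$path, out$manifest$sample_id)
  parts <- partition_by_mutation(recs)
  props <- compute_cdr3_properties(parts$unmutated)
  vs <- as_variant_set(geno)
  res <- run_property_qtl(props, vs)
  r <- res$results
  arom <- r[r$trait == "aromatic" & r$significant]
  expect_gt(nrow(arom), 0)
  # two planted routes shift aromaticity: the usage effect at snv_b1_03 and
  # the coding-allele composition tagged by snv_b1_01; the causal variant
  # must be significant and the lead must be one of the two planted classes
  causal_class <- r$ld_class[r$trait == "aromatic" &
                               r$variant_id == "snv_b1_03"]
  tag_class <- r$ld_class[r$trait == "aromatic" &
                            r$variant_id == "snv_b1_01"]
  expect_true("snv_b1_03" %in% arom$variant_id)
  lead_class <- unique(r$ld_class[r$trait == "aromatic" & r$is_lead])
  expect_true(lead_class %in% c(causal_class, tag_class))

  # cross-reference: the property lead is also a guQTL for the driving gene
  um <- compute_usage_matrix(parts$unmutated, axis = "V",
                             min_gene_count = 5, min_sample_sequences = 50)
  gu <- run_guqtl(um, vs)
  xref <- property_guqtl_overlap(res, gu)
  row <- xref[xref$trait == "aromatic"]
  expect_gt(row$n_guqtl_genes, 0)
  expect_true(grepl("simV01", row$guqtl_genes))
})
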