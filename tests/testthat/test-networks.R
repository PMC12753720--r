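# Shared-guQTL networks, cliques, coding-allele linkage and feature
# enrichment.

test_that("guQTL sets keep only genes with significant variants", {
  res <- data.table::data.table(
    trait = c("gA", "gA", "gB", "gB", "gC"),
    variant_id = c("v1", "v2", "v1", "v3", "v4"),
    significant = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  sets <- build_guqtl_sets(res)
  expect_setequal(names(sets), c("gA", "gB"))
  expect_setequal(sets$gA, c("v1", "v2"))
  expect_equal(sets$gB, "v1")
})

test_that("Jaccard index matches enumeration", {
  expect_equal(jaccard_index(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(jaccard_index(c("1", "2", "3"), c("3", "4")), 0.25)
  expect_equal(jaccard_index(c("a"), c("b")), 0)
  expect_true(is.na(jaccard_index(character(0), character(0))))
  # symmetry
  set.seed(3)
  for (i in 1:10) {
    A <- sample(letters, sample(0:8, 1))
    B <- sample(letters, sample(1:8, 1))
    expect_equal(jaccard_index(A, B), jaccard_index(B, A))
  }
})

test_that("network edges reflect shared-variant counts", {
  sets <- list(gA = c("v1", "v2"), gB = c("v1", "v3"), gC = c("v1"),
               gD = c("v9"))
  net <- build_network(sets)
  expect_setequal(net$nodes, c("gA", "gB", "gC", "gD"))
  expect_equal(nrow(net$edges), 3L)  # triangle among gA, gB, gC
  e <- net$edges
  key <- paste(e$gene_a, e$gene_b)
  expect_true(all(e$shared >= 1L))
  expect_true(all(e$jaccard > 0 & e$jaccard <= 1))
  # gD isolated
  expect_equal(igraph::degree(net$graph)[["gD"]], 0)
  # one shared variant across 9 genes -> complete subgraph
  sets9 <- setNames(rep(list("v1"), 9), paste0("g", 1:9))
  net9 <- build_network(sets9)
  expect_equal(nrow(net9$edges), choose(9, 2))
  cl9 <- find_cliques(net9)
  expect_equal(length(cl9), 1L)
  expect_equal(length(cl9[[1]]), 9L)
})

test_that("maximal cliques match brute-force subset enumeration", {
  # canonical small cases
  tri <- list(gA = "v", gB = "v", gC = "v")
  expect_equal(find_cliques(build_network(tri)),
               list(c("gA", "gB", "gC")))
  path <- list(a = c("v1"), b = c("v1", "v2"), c = c("v2"))
  expect_equal(find_cliques(build_network(path)),
               list(c("a", "b"), c("b", "c")))

  # random graphs vs brute force
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    adj <- matrix(FALSE, n, n,
                  dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
    for (a in 2:n) for (b in 1:(a - 1)) {
      adj[a, b] <- adj[b, a] <- runif(1) < 0.4
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    got <- find_cliques(g)
    want <- bf_max_cliques(adj)
    expect_equal(got, want)
    # every reported clique is complete and maximal
    for (cl in got) {
      expect_true(all(adj[cl, cl][upper.tri(diag(length(cl)))]))
      outside <- setdiff(rownames(adj), cl)
      expect_false(any(vapply(outside, function(o) all(adj[o, cl]), TRUE)))
    }
  }
})

test_that("coding-allele linkage Fisher test matches enumeration", {
  tab <- matrix(c(5, 0, 0, 5), 2, byrow = TRUE)
  res <- coding_allele_linkage_test(tab, n_genes_tested = 1)
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$p_value, bf_fisher_2x2(tab), tolerance = 1e-12)

  # identical distributions across genotype groups: p = 1
  res2 <- coding_allele_linkage_test(matrix(c(4, 4, 6, 6), 2))
  expect_equal(res2$p_value, 1)

  # Bonferroni family of 26 genes reproduces the 0.002 threshold scale
  res3 <- coding_allele_linkage_test(tab, n_genes_tested = 26)
  expect_equal(res3$threshold, 0.05 / 26)
  expect_equal(round(res3$threshold, 3), 0.002)

  # untestable margins
  res4 <- coding_allele_linkage_test(matrix(c(5, 0, 5, 0), 2))
  expect_false(res4$testable)

  # r x c exact path agrees with fisher.test; Monte Carlo path is seeded
  tab_rc <- matrix(c(8, 1, 0, 1, 7, 2, 0, 2, 9), 3)
  r5 <- coding_allele_linkage_test(tab_rc)
  expect_equal(r5$p_value, stats::fisher.test(tab_rc)$p.value)
  big <- matrix(rpois(36, 30) + 1, 6)
  m1 <- coding_allele_linkage_test(big)
  m2 <- coding_allele_linkage_test(big)
  expect_equal(m1$p_value, m2$p_value)  # fixed seed -> reproducible
})

test_that("allele-by-genotype tables count copies or carriers", {
  alleles <- cbind(c("01", "01", "02", NA), c("01", "02", "02", "01"))
  genotype <- c(0, 1, 2, 2)
  tab <- allele_genotype_table(alleles, genotype)
  expect_equal(sum(tab), 7)  # one NA haplotype dropped
  expect_equal(tab["01", "0"], 2)
  expect_equal(tab["02", "2"], 2)
  tabc <- allele_genotype_table(alleles, genotype, unit = "carriers")
  expect_equal(sum(tabc), 5)  # only sample 2 carries two distinct alleles

  expect_true(lacks_allelic_variation(c(`01` = 97, `02` = 3)))
  expect_false(lacks_allelic_variation(c(`01` = 80, `02` = 20)))
})

test_that("feature enrichment matches the hypergeometric tail", {
  # guQTLs all inside the track
  bg <- paste0("v", 1:40)
  gu <- paste0("v", 1:10)
  in_track <- paste0("v", c(1:10, 11:20))
  res <- feature_enrichment(gu, bg, in_track)
  # P(X >= 10) with N=40, K=20 in-track, n=10 drawn
  p_tail <- sum(dhyper(10:10, 20, 20, 10))
  expect_equal(res$p_value, p_tail, tolerance = 1e-12)
  expect_true(is.infinite(res$odds_ratio) || res$odds_ratio > 50)

  # equal overlap fractions: no enrichment
  res2 <- feature_enrichment(paste0("v", 1:10), bg,
                             paste0("v", c(1:5, 11:25)))
  expect_gte(res2$p_value, 0.5)

  # empty track untestable
  res3 <- feature_enrichment(gu, bg, character(0))
  expect_true(is.na(res3$p_value))

  # invariant to shuffling variant order
  set.seed(4)
  res4 <- feature_enrichment(sample(gu), sample(bg), sample(in_track))
  expect_equal(res4$p_value, res$p_value)
})

test_that("linked coding alleles are detected on simulated cohorts", {
  cfg <- tiny_config(seed = 101)
  truth <- simulate_locus(cfg)
  geno <- simulate_cohort_genotypes(truth, cfg)
  # alleles of simV01 are tagged by snv_b1_01 by construction
  tag <- "snv_b1_01"
  a1 <- geno$hap1[tag, ] + 1L
  a2 <- geno$hap2[tag, ] + 1L
  alleles <- cbind(sprintf("%02d", a1), sprintf("%02d", a2))
  genotype <- geno$dosage[tag, ]
  if (length(unique(genotype)) >= 2) {
    tab <- allele_genotype_table(alleles, genotype)
    res <- coding_allele_linkage_test(tab, n_genes_tested = 1)
    expect_true(res$testable)
    expect_lt(res$p_value, 1e-6)  # perfect linkage by construction
  }
})
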