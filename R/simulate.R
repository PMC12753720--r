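# Synthetic pseudo-locus cohort: phased genotypes with planted block LD
# structure, gene-deletion SVs, per-gene coding allele catalogs linked to
# non-coding haplotypes, and AIRR repertoires whose gene usage follows an
# additive (log-linear in dosage) genotype model.

#' Simulation configuration
#'
#' Defines the study conditions of a synthetic cohort. Defaults emulate a
#' cohort of 160 donors with repertoires of 10^4 unique sequences, a locus of
#' 5 independent LD blocks of 12 common SNVs drawn from 4-haplotype pools,
#' a handful of planted usage effects, and one gene-deletion SV.
#'
#' @param n_samples number of diploid donors.
#' @param n_genes total genes on the pseudo-locus (V-like plus J-like; at
#'   least 15% and no fewer than 2 are J-like).
#' @param n_blocks number of LD blocks tiling the locus.
#' @param snvs_per_block common SNVs per block.
#' @param haplotypes_per_block haplotype pool size per block (>= 2); smaller
#'   pools give stronger within-block LD.
#' @param causal_map data.frame with columns `gene`, `variant` (SNV id or NA
#'   to let the simulator pick one in the gene's block) and `beta` (effect on
#'   log usage propensity per alternate-allele dosage). `NULL` plants the
#'   default effects (6 V genes, |beta| 0.6, alternating sign).
#' @param baseline_usage positive per-gene propensity weights; `NULL` gives a
#'   geometric decay (2-fold per 6 genes) mimicking skewed real usage.
#' @param sv_spec data.frame with columns `genes` (comma-separated gene
#'   names) and `carrier_freq` (per-haplotype deletion frequency); `NULL`
#'   plants one deletion of the last V gene at frequency 0.2.
#' @param mutated_fraction expected fraction of sequences bearing somatic
#'   hypermutation (identity < 1); default 0.3.
#' @param mutated_beta_scale attenuation of planted effects in the mutated
#'   partition (default 0.5, emulating blunted genetic effects after antigen
#'   experience).
#' @param sequences_per_sample unique sequences per repertoire (default 1e4).
#' @param sample_noise_sd standard deviation of per-sample log-normal noise
#'   on gene propensities (biological variability; default 0.25).
#' @param seed integer seed; all stages derive their RNG stream from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 160L, n_genes = 20L, n_blocks = 5L,
                       snvs_per_block = 12L, haplotypes_per_block = 4L,
                       causal_map = NULL, baseline_usage = NULL,
                       sv_spec = NULL, mutated_fraction = 0.3,
                       mutated_beta_scale = 0.5,
                       sequences_per_sample = 10000L,
                       sample_noise_sd = 0.25, seed = 42L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_blocks = as.integer(n_blocks),
              snvs_per_block = as.integer(snvs_per_block),
              haplotypes_per_block = as.integer(haplotypes_per_block),
              causal_map = causal_map, baseline_usage = baseline_usage,
              sv_spec = sv_spec, mutated_fraction = mutated_fraction,
              mutated_beta_scale = mutated_beta_scale,
              sequences_per_sample = as.integer(sequences_per_sample),
              sample_noise_sd = sample_noise_sd, seed = as.integer(seed))
  counts <- c("n_samples", "n_genes", "n_blocks", "snvs_per_block",
              "sequences_per_sample")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L) stop("invalid config: ", f,
                                                " must be a positive count")
  }
  if (cfg$haplotypes_per_block < 2L) {
    stop("invalid config: haplotypes_per_block must be >= 2")
  }
  if (is.na(cfg$mutated_fraction) || cfg$mutated_fraction < 0 ||
      cfg$mutated_fraction > 1) {
    stop("invalid config: mutated_fraction must be in [0, 1]")
  }
  if (!is.null(cfg$baseline_usage) && any(cfg$baseline_usage <= 0)) {
    stop("invalid config: baseline_usage weights must be strictly positive")
  }
  structure(cfg, class = "sim_config")
}

# deterministic substreams: each stage reseeds from the config seed plus a
# fixed offset so stages are independently reproducible
stage_seed <- function(config, offset) (config$seed + offset) %% .Machine$integer.max

sim_gene_names <- function(n_genes) {
  n_j <- max(2L, as.integer(round(0.15 * n_genes)))
  n_v <- n_genes - n_j
  list(v = sprintf("simV%02d", seq_len(n_v)),
       j = sprintf("simJ%d", seq_len(n_j)),
       n_v = n_v, n_j = n_j)
}

BLOCK_SPAN <- 10000L

# proper sub-clades of a random bifurcating genealogy over pool haplotypes
# 1..P (every internal edge defines the carrier set of mutations placed on
# it); guarantees pairwise four-gamete compatibility within a block
pool_clades <- function(P) {
  out <- list()
  recurse <- function(members) {
    if (length(members) < 2L) return(invisible(NULL))
    k <- sample.int(length(members) - 1L, 1L)
    left <- sort(sample(members, k))
    right <- setdiff(members, left)
    out[[length(out) + 1L]] <<- left
    out[[length(out) + 1L]] <<- right
    recurse(left)
    recurse(right)
  }
  recurse(seq_len(P))
  unique(out)
}

#' Simulate the pseudo-locus layout and ground truth
#'
#' Lays out `n_blocks` non-overlapping blocks of `BLOCK_SPAN` bp, places V-like
#' genes (leader, intron, exon, RSS heptamer/spacer/nonamer) and J-like genes
#' (single exon plus RSS) across them, assigns SNV positions and a haplotype
#' pool per block, plants the causal map, the SV deletions and a per-gene
#' coding-allele catalog tagged to the block haplotypes. Within each block the
#' first two SNVs are forced to co-segregate on every pool haplotype, planting
#' an exact r-squared = 1 pair.
#'
#' @param config a [sim_config()].
#' @return object of class `locus_truth`.
#' @export
simulate_locus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, 0L))
  gn <- sim_gene_names(config$n_genes)
  genes <- c(gn$v, gn$j)
  gene_class <- c(rep("V", gn$n_v), rep("J", gn$n_j))
  n_blocks <- config$n_blocks

  # genes spread evenly over blocks, laid out at fixed slots inside each
  gene_block <- ceiling(seq_along(genes) * n_blocks / length(genes))
  gene_tab <- data.frame(gene = genes, class = gene_class, block = gene_block,
                         start = NA_integer_, end = NA_integer_,
                         stringsAsFactors = FALSE)
  feat_list <- list()
  for (b in seq_len(n_blocks)) {
    idx <- which(gene_block == b)
    if (!length(idx)) next
    slot_width <- BLOCK_SPAN %/% (length(idx) + 1L)
    for (k in seq_along(idx)) {
      i <- idx[k]
      gstart <- (b - 1L) * BLOCK_SPAN + k * slot_width - slot_width %/% 2L
      if (gene_class[i] == "V") {
        # L-Part1, intron, V-exon, RSS heptamer/spacer/nonamer
        widths <- c(`L-Part1` = 60L, intron = 90L, `V-exon` = 300L,
                    `RSS-heptamer` = 7L, `RSS-spacer` = 12L,
                    `RSS-nonamer` = 9L)
      } else {
        widths <- c(`RSS-nonamer` = 9L, `RSS-spacer` = 12L,
                    `RSS-heptamer` = 7L, `V-exon` = 60L)
      }
      starts <- gstart + c(0L, cumsum(widths))[seq_along(widths)]
      ends <- starts + widths - 1L
      feat_list[[length(feat_list) + 1L]] <- data.frame(
        gene = genes[i], feature = names(widths), start = starts, end = ends,
        stringsAsFactors = FALSE)
      gene_tab$start[i] <- gstart
      gene_tab$end[i] <- max(ends)
    }
  }
  features <- do.call(rbind, feat_list)
  rownames(features) <- NULL

  # SNV positions: unique, sorted within block, away from block edges
  nt <- c("A", "C", "G", "T")
  var_list <- list()
  pool <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    pos <- sort(sample((b - 1L) * BLOCK_SPAN + seq(50L, BLOCK_SPAN - 50L),
                       config$snvs_per_block))
    ref <- sample(nt, config$snvs_per_block, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), "")
    var_list[[b]] <- data.frame(
      id = sprintf("snv_b%d_%02d", b, seq_len(config$snvs_per_block)),
      block = b, pos = pos, ref = ref, alt = unname(alt),
      stringsAsFactors = FALSE)
    # haplotype pool under an infinite-sites, recombination-free genealogy:
    # each SNV mutates once on a clade of a random tree over the pool, so
    # within-block pairs never show four gametes (|D'| = 1) and blocks are
    # Gabriel-detectable; SNVs 1 and 2 co-segregate exactly (planted r2 = 1)
    P <- config$haplotypes_per_block
    clades <- pool_clades(P)
    H <- matrix(0L, P, config$snvs_per_block)
    for (s in seq_len(config$snvs_per_block)) {
      H[clades[[sample.int(length(clades), 1L)]], s] <- 1L
    }
    if (config$snvs_per_block >= 2L) H[, 2L] <- H[, 1L]
    pool[[b]] <- H
  }
  variants <- do.call(rbind, var_list)
  rownames(variants) <- NULL

  # causal map: default plants effects on up to 6 V genes spread over blocks
  causal <- config$causal_map
  if (is.null(causal)) {
    n_causal <- min(6L, gn$n_v)
    cg <- gn$v[unique(as.integer(round(seq(1L, gn$n_v,
                                           length.out = n_causal))))]
    causal <- data.frame(gene = cg, variant = NA_character_,
                         beta = 0.6 * rep_len(c(1, -1), length(cg)),
                         stringsAsFactors = FALSE)
  }
  causal <- as.data.frame(causal, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(causal))) {
    if (is.na(causal$variant[i])) {
      b <- gene_tab$block[match(causal$gene[i], gene_tab$gene)]
      # pick a mid-block SNV (not one of the planted duplicate pair)
      k <- min(config$snvs_per_block, max(3L, config$snvs_per_block %/% 2L))
      causal$variant[i] <- sprintf("snv_b%d_%02d", b, k)
    }
  }
  if (!all(causal$variant %in% variants$id)) {
    stop("causal_map references unknown variant id(s)")
  }
  if (!all(causal$gene %in% genes)) {
    stop("causal_map references unknown gene(s)")
  }

  # SV spec: default one deletion of the last V gene
  svs <- config$sv_spec
  if (is.null(svs)) {
    svs <- data.frame(genes = gn$v[gn$n_v], carrier_freq = 0.2,
                      stringsAsFactors = FALSE)
  }
  svs <- as.data.frame(svs, stringsAsFactors = FALSE)
  svs$sv_id <- sprintf("sv_%02d", seq_len(nrow(svs)))
  svs$start <- NA_integer_
  svs$end <- NA_integer_
  for (i in seq_len(nrow(svs))) {
    gs <- strsplit(svs$genes[i], ",", fixed = TRUE)[[1]]
    if (!all(gs %in% genes)) stop("sv_spec references unknown gene(s)")
    m <- match(gs, gene_tab$gene)
    svs$start[i] <- min(gene_tab$start[m]) - 25L
    svs$end[i] <- max(gene_tab$end[m]) + 25L
  }

  # baseline usage: geometric decay within each class unless supplied
  baseline <- config$baseline_usage
  if (is.null(baseline)) {
    baseline <- c(2^(-(seq_len(gn$n_v) - 1L) / 6),
                  2^(-(seq_len(gn$n_j) - 1L) / 6))
  }
  stopifnot(length(baseline) == length(genes), all(baseline > 0))
  names(baseline) <- genes

  # coding allele catalog: each gene has 2 alleles tagged by the haplotype
  # allele at the first SNV of its block (coding variation in LD with
  # non-coding haplotypes); V-end amino acids differ by gene so usage shifts
  # propagate into CDR3 composition. Gene simV01 (and every 4th V gene) gets
  # an aromatic-rich V end.
  allele_rows <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    b <- gene_tab$block[i]
    tag <- sprintf("snv_b%d_%02d", b, 1L)
    aromatic_rich <- gene_class[i] == "V" && (i %% 4L == 1L)
    pool_letters <- if (aromatic_rich) c("Y", "W", "F", "S", "G") else
      c("S", "G", "A", "L", "T", "N")
    core <- paste(sample(pool_letters, 4L, replace = TRUE), collapse = "")
    # allele *02 carries a missense change that preserves the residue's
    # aromatic/charge class, so CDR3 aromaticity differs between genes (via
    # usage) but not between alleles of one gene
    swap <- c(Y = "W", W = "F", F = "Y", S = "G", G = "S", A = "T",
              L = "V", T = "A", N = "S", V = "L")
    alt_core <- paste0(substr(core, 1L, 3L),
                       swap[[substr(core, 4L, 4L)]])
    j_start <- paste(sample(c("V", "T", "G", "L"), 3L, replace = TRUE),
                     collapse = "")
    for (a in 1:2) {
      allele_rows[[length(allele_rows) + 1L]] <- data.frame(
        gene = g, allele = sprintf("%02d", a), tag_variant = tag,
        tag_allele = a - 1L,
        v_end_aa = if (gene_class[i] == "V") c(core, alt_core)[a] else "",
        j_start_aa = if (gene_class[i] == "J") j_start else "",
        stringsAsFactors = FALSE)
    }
  }
  alleles <- do.call(rbind, allele_rows)
  rownames(alleles) <- NULL

  structure(list(
    genes = gene_tab, features = features, variants = variants,
    haplotype_pool = pool, causal_map = causal, svs = svs,
    baseline_usage = baseline, alleles = alleles,
    locus_length = n_blocks * BLOCK_SPAN,
    block_span = BLOCK_SPAN, seed = config$seed
  ), class = "locus_truth")
}

#' @export
print.locus_truth <- function(x, ...) {
  cat(sprintf(paste0("locus_truth: %d genes, %d SNVs in %d blocks, %d SV(s),",
                     " %d planted effect(s)\n"),
              nrow(x$genes), nrow(x$variants), length(x$haplotype_pool),
              nrow(x$svs), nrow(x$causal_map)))
  invisible(x)
}

#' Pool-level r-squared of two SNVs
#'
#' Squared allele-dosage correlation implied by the haplotype pool (uniform
#' haplotype weights). Pairs equal on every pool haplotype (or complementary)
#' have r-squared exactly 1 in every cohort drawn from the pool.
#'
#' @param truth a `locus_truth`.
#' @param id_a,id_b SNV ids in the same block.
#' @return squared correlation, or `NA` across blocks.
#' @export
pool_r2 <- function(truth, id_a, id_b) {
  va <- truth$variants[match(id_a, truth$variants$id), ]
  vb <- truth$variants[match(id_b, truth$variants$id), ]
  if (va$block != vb$block) return(NA_real_)
  H <- truth$haplotype_pool[[va$block]]
  ia <- which(truth$variants$id[truth$variants$block == va$block] == id_a)
  ib <- which(truth$variants$id[truth$variants$block == vb$block] == id_b)
  stats::cor(H[, ia], H[, ib])^2
}

#' Simulate cohort genotypes from a locus truth
#'
#' Each sample receives two haplotypes per block drawn independently and
#' uniformly from the block's pool; SV deletion carriers are drawn per
#' haplotype at the configured frequency. Optionally writes a phased VCF v4.2.
#'
#' @param truth from [simulate_locus()].
#' @param config the same [sim_config()].
#' @param vcf_path optional path for a VCF of the cohort (SNVs plus symbolic
#'   `<DEL>` records).
#' @return object of class `genotype_set`: `samples`, `variants` (id, pos,
#'   type, ref, alt), `dosage` (variants x samples), `hap1`/`hap2` allele
#'   matrices, `block_h1`/`block_h2` pool indices (blocks x samples),
#'   `copy_number` (genes x samples), `sv_hap1`/`sv_hap2` deletion indicators.
#' @export
simulate_cohort_genotypes <- function(truth, config, vcf_path = NULL) {
  stopifnot(inherits(truth, "locus_truth"), inherits(config, "sim_config"))
  set.seed(stage_seed(config, 1L))
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  n_blocks <- length(truth$haplotype_pool)
  P <- nrow(truth$haplotype_pool[[1L]])
  block_h1 <- matrix(sample.int(P, n_blocks * n, replace = TRUE), n_blocks, n)
  block_h2 <- matrix(sample.int(P, n_blocks * n, replace = TRUE), n_blocks, n)
  nv <- nrow(truth$variants)
  hap1 <- matrix(0L, nv, n, dimnames = list(truth$variants$id, samples))
  hap2 <- hap1
  for (b in seq_len(n_blocks)) {
    vi <- which(truth$variants$block == b)
    H <- truth$haplotype_pool[[b]]
    hap1[vi, ] <- t(H[block_h1[b, ], , drop = FALSE])
    hap2[vi, ] <- t(H[block_h2[b, ], , drop = FALSE])
  }
  dosage <- hap1 + hap2

  n_sv <- nrow(truth$svs)
  sv_hap1 <- matrix(0L, n_sv, n, dimnames = list(truth$svs$sv_id, samples))
  sv_hap2 <- sv_hap1
  for (i in seq_len(n_sv)) {
    f <- truth$svs$carrier_freq[i]
    sv_hap1[i, ] <- stats::rbinom(n, 1L, f)
    sv_hap2[i, ] <- stats::rbinom(n, 1L, f)
  }
  copy_number <- matrix(2L, nrow(truth$genes), n,
                        dimnames = list(truth$genes$gene, samples))
  for (i in seq_len(n_sv)) {
    gs <- strsplit(truth$svs$genes[i], ",", fixed = TRUE)[[1]]
    for (g in gs) {
      copy_number[g, ] <- copy_number[g, ] - sv_hap1[i, ] - sv_hap2[i, ]
    }
  }

  vars <- data.frame(id = truth$variants$id, pos = truth$variants$pos,
                     type = "SNV", ref = truth$variants$ref,
                     alt = truth$variants$alt, stringsAsFactors = FALSE)
  geno <- structure(list(
    samples = samples, variants = vars, dosage = dosage,
    hap1 = hap1, hap2 = hap2, block_h1 = block_h1, block_h2 = block_h2,
    copy_number = copy_number, sv_hap1 = sv_hap1, sv_hap2 = sv_hap2,
    svs = truth$svs
  ), class = "genotype_set")
  if (!is.null(vcf_path)) write_cohort_vcf(geno, truth, vcf_path)
  geno
}

#' Write a phased multi-sample VCF v4.2 for a simulated cohort
#'
#' SNVs are written as ordinary biallelic records, SV deletions as symbolic
#' `<DEL>` records with `SVTYPE` and `END` INFO fields; all GT fields are
#' phased (`a|b`).
#'
#' @param geno a `genotype_set`.
#' @param truth the matching `locus_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(geno, truth, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=guqtl-simulator",
           sprintf("##contig=<ID=chrSim,length=%d>", truth$locus_length),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", geno$samples), collapse = "\t"))
  gt_snv <- matrix(paste0(geno$hap1, "|", geno$hap2),
                   nrow = nrow(geno$hap1))
  snv_rows <- paste("chrSim", truth$variants$pos, truth$variants$id,
                    truth$variants$ref, truth$variants$alt, ".", "PASS", ".",
                    "GT", apply(gt_snv, 1L, paste, collapse = "\t"),
                    sep = "\t")
  sv_rows <- character(0)
  if (nrow(truth$svs)) {
    gt_sv <- matrix(paste0(geno$sv_hap1, "|", geno$sv_hap2),
                    nrow = nrow(geno$sv_hap1))
    sv_rows <- paste("chrSim", truth$svs$start, truth$svs$sv_id, "N", "<DEL>",
                     ".", "PASS",
                     sprintf("SVTYPE=DEL;END=%d", truth$svs$end), "GT",
                     apply(gt_sv, 1L, paste, collapse = "\t"), sep = "\t")
  }
  body <- c(snv_rows, sv_rows)
  ord <- order(c(truth$variants$pos, truth$svs$start))
  writeLines(c(hdr, body[ord]), path)
  invisible(path)
}

#' Write feature annotations as BED (0-based half-open)
#'
#' One row per gene feature with the feature class in the name column.
#'
#' @param truth a `locus_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_bed <- function(truth, path) {
  f <- truth$features
  lines <- sprintf("chrSim\t%d\t%d\t%s\t0\t+", f$start - 1L, f$end,
                   f$feature)
  writeLines(lines, path)
  invisible(path)
}

#' Write the allele catalog as FASTA
#'
#' Synthetic per-gene coding alleles; headers carry the gene, allele and the
#' tagging non-coding variant.
#'
#' @param truth a `locus_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(truth, path) {
  a <- truth$alleles
  seqs <- ifelse(a$v_end_aa != "", a$v_end_aa, a$j_start_aa)
  lines <- as.vector(rbind(
    sprintf(">%s*%s tag=%s:%d", a$gene, a$allele, a$tag_variant,
            a$tag_allele),
    seqs))
  writeLines(lines, path)
  invisible(path)
}

# ---- usage model ----------------------------------------------------------

# per-sample, per-gene multinomial probabilities for one partition.
# log w = log baseline + beta * dosage(causal) + noise + log(cn / 2);
# V and J classes are normalized separately (every sequence uses one V and
# one J gene).
usage_probabilities <- function(truth, geno, config, noise,
                                beta_scale = 1) {
  genes <- truth$genes$gene
  n <- length(geno$samples)
  logw <- matrix(log(truth$baseline_usage[genes]), length(genes), n,
                 dimnames = list(genes, geno$samples))
  for (i in seq_len(nrow(truth$causal_map))) {
    g <- truth$causal_map$gene[i]
    v <- truth$causal_map$variant[i]
    beta <- truth$causal_map$beta[i] * beta_scale
    logw[g, ] <- logw[g, ] + beta * geno$dosage[v, ]
  }
  logw <- logw + noise
  w <- exp(logw) * (geno$copy_number[genes, , drop = FALSE] / 2)
  probs <- w
  for (cls in c("V", "J")) {
    rows <- truth$genes$class == cls
    tot <- colSums(w[rows, , drop = FALSE])
    probs[rows, ] <- sweep(w[rows, , drop = FALSE], 2L, tot, "/")
  }
  probs
}

#' Simulate per-sample gene usage counts
#'
#' Fast path used by replicate studies: draws multinomial V-gene and J-gene
#' counts per sample and partition without materializing per-sequence AIRR
#' rows. The mutated partition uses planted effects attenuated by
#' `mutated_beta_scale`; both partitions share the per-sample propensity
#' noise.
#'
#' @param truth,config,geno locus truth, configuration, genotypes.
#' @return list with elements `unmutated` and `mutated`, each a list of
#'   `counts` (genes x samples), `probs` (the multinomial probabilities
#'   actually used) and `totals` (per-sample partition sizes).
#' @export
simulate_usage_counts <- function(truth, geno, config) {
  set.seed(stage_seed(config, 2L))
  genes <- truth$genes$gene
  n <- length(geno$samples)
  noise <- matrix(stats::rnorm(length(genes) * n, 0, config$sample_noise_sd),
                  length(genes), n, dimnames = list(genes, geno$samples))
  probs_u <- usage_probabilities(truth, geno, config, noise, 1)
  probs_m <- usage_probabilities(truth, geno, config, noise,
                                 config$mutated_beta_scale)
  n_mut <- stats::rbinom(n, config$sequences_per_sample,
                         config$mutated_fraction)
  n_unm <- config$sequences_per_sample - n_mut
  draw <- function(probs, totals) {
    cnt <- matrix(0L, length(genes), n, dimnames = dimnames(probs))
    for (cls in c("V", "J")) {
      rows <- which(truth$genes$class == cls)
      for (s in seq_len(n)) {
        cnt[rows, s] <- stats::rmultinom(1L, totals[s], probs[rows, s])
      }
    }
    cnt
  }
  list(
    unmutated = list(counts = draw(probs_u, n_unm), probs = probs_u,
                     totals = n_unm),
    mutated = list(counts = draw(probs_m, n_mut), probs = probs_m,
                   totals = n_mut)
  )
}

# sample's two coding alleles of a gene (one per haplotype), via the pool
# haplotype allele at the gene's tag variant; haplotypes deleted by an SV
# carry no allele
sample_gene_alleles <- function(truth, geno, gene) {
  gi <- match(gene, truth$genes$gene)
  b <- truth$genes$block[gi]
  tag <- truth$alleles$tag_variant[match(gene, truth$alleles$gene)]
  tag_row <- match(tag, truth$variants$id)
  a1 <- geno$hap1[tag_row, ] + 1L   # 1 -> *01, 2 -> *02
  a2 <- geno$hap2[tag_row, ] + 1L
  del1 <- rep(FALSE, length(geno$samples))
  del2 <- del1
  for (i in seq_len(nrow(truth$svs))) {
    gs <- strsplit(truth$svs$genes[i], ",", fixed = TRUE)[[1]]
    if (gene %in% gs) {
      del1 <- del1 | geno$sv_hap1[i, ] == 1L
      del2 <- del2 | geno$sv_hap2[i, ] == 1L
    }
  }
  list(a1 = a1, a2 = a2, del1 = del1, del2 = del2)
}

#' Simulate AIRR repertoires and write per-sample rearrangement tables
#'
#' Draws gene usage counts from the genotype-dependent propensity model, then
#' materializes one AIRR Rearrangement TSV per sample: every sequence gets a
#' V call and J call (gene*allele, the allele drawn from the sample's diploid
#' alleles of the chosen gene), a junction built from the germline V end, a
#' Poisson(3)-length N region of uniform residues and the germline J start,
#' flanked by the conserved C and F; `v_identity`/`j_identity` are 1 except
#' for the mutated fraction, where at least one of them is < 1. Genes with
#' zero copy number in every sample are excluded with a warning.
#'
#' @param truth,geno,config locus truth, genotypes, configuration.
#' @param out_dir directory for the TSV files (created if needed).
#' @return list with `manifest` (data.frame sample_id, path), `counts`
#'   (the [simulate_usage_counts()] result) and `excluded_genes`.
#' @export
simulate_repertoires <- function(truth, geno, config, out_dir) {
  counts <- simulate_usage_counts(truth, geno, config)
  set.seed(stage_seed(config, 3L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  excluded <- truth$genes$gene[rowSums(geno$copy_number) == 0L]
  if (length(excluded)) {
    warning("gene(s) with zero copy number in all samples excluded: ",
            paste(excluded, collapse = ", "))
  }
  genes <- truth$genes$gene
  v_genes <- genes[truth$genes$class == "V"]
  j_genes <- genes[truth$genes$class == "J"]
  allele_info <- lapply(setNames(genes, genes), sample_gene_alleles,
                        truth = truth, geno = geno)
  v_end <- matrix("", length(genes), 2L, dimnames = list(genes, NULL))
  j_start <- v_end
  for (i in seq_len(nrow(truth$alleles))) {
    a <- truth$alleles[i, ]
    v_end[a$gene, as.integer(a$allele)] <- a$v_end_aa
    j_start[a$gene, as.integer(a$allele)] <- a$j_start_aa
  }
  manifest <- data.frame(sample_id = geno$samples,
                         path = file.path(out_dir,
                                          paste0(geno$samples, ".tsv")),
                         stringsAsFactors = FALSE)
  for (s in seq_along(geno$samples)) {
    rows <- list()
    for (part in c("unmutated", "mutated")) {
      cnt <- counts[[part]]$counts[, s]
      n_seq <- sum(cnt[v_genes])
      if (n_seq == 0L) next
      v_of_seq <- rep(v_genes, cnt[v_genes])
      j_of_seq <- rep(j_genes, cnt[j_genes])
      j_of_seq <- sample(j_of_seq)   # random V-J pairing
      pick_allele <- function(gene_vec) {
        out <- integer(length(gene_vec))
        for (g in unique(gene_vec)) {
          ai <- allele_info[[g]]
          opts <- c(if (!ai$del1[s]) ai$a1[s], if (!ai$del2[s]) ai$a2[s])
          idx <- which(gene_vec == g)
          out[idx] <- if (length(opts)) sample(opts, length(idx),
                                               replace = TRUE) else 1L
        }
        out
      }
      v_allele <- pick_allele(v_of_seq)
      j_allele <- pick_allele(j_of_seq)
      n_len <- stats::rpois(n_seq, 3)
      n_res <- strsplit(paste(sample(AA_LETTERS, sum(n_len) + 1L,
                                     replace = TRUE), collapse = ""), "")[[1]]
      n_region <- character(n_seq)
      if (sum(n_len) > 0L) {
        ends <- cumsum(n_len)
        starts <- ends - n_len + 1L
        full <- paste(n_res[seq_len(sum(n_len))], collapse = "")
        n_region <- substr(rep(full, n_seq), starts, ends)
      }
      junction <- paste0("C", v_end[cbind(match(v_of_seq, genes), v_allele)],
                         n_region,
                         j_start[cbind(match(j_of_seq, genes), j_allele)],
                         "F")
      v_id <- rep(1, n_seq)
      j_id <- rep(1, n_seq)
      if (part == "mutated") {
        which_mut <- sample(c("v", "j", "vj"), n_seq, replace = TRUE,
                            prob = c(0.4, 0.3, 0.3))
        mut_val <- function(k) round(stats::runif(k, 0.90, 0.995), 4)
        v_id[which_mut != "j"] <- mut_val(sum(which_mut != "j"))
        j_id[which_mut != "v"] <- mut_val(sum(which_mut != "v"))
      }
      rows[[part]] <- data.table::data.table(
        sequence_id = paste0(geno$samples[s], "_", part, "_",
                             seq_len(n_seq)),
        v_call = paste0(v_of_seq, "*", sprintf("%02d", v_allele)),
        j_call = paste0(j_of_seq, "*", sprintf("%02d", j_allele)),
        junction_aa = junction, v_identity = v_id, j_identity = j_id)
    }
    tab <- data.table::rbindlist(rows)
    data.table::fwrite(tab, manifest$path[s], sep = "\t")
  }
  list(manifest = manifest, counts = counts, excluded_genes = excluded)
}

# ---- truth serialization --------------------------------------------------

#' Write / read locus ground truth as JSON
#'
#' `write_truth()` serializes a `locus_truth` losslessly;
#' `read_truth()` restores it, so `read_truth(write_truth(x)) == x`.
#'
#' @param truth a `locus_truth`.
#' @param path JSON path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` returns
#'   the restored `locus_truth`.
#' @export
write_truth <- function(truth, path) {
  payload <- list(
    genes = truth$genes, features = truth$features, variants = truth$variants,
    # pools as data.frames so JSON round-trips each block independently
    # (lists of equal-shape arrays would otherwise re-simplify to one array)
    haplotype_pool = lapply(truth$haplotype_pool, as.data.frame),
    causal_map = truth$causal_map,
    svs = truth$svs, baseline_usage = as.list(truth$baseline_usage),
    alleles = truth$alleles, locus_length = truth$locus_length,
    block_span = truth$block_span, seed = truth$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  int_cols <- function(df, cols) {
    for (cc in intersect(cols, names(df))) df[[cc]] <- as.integer(df[[cc]])
    df
  }
  p$genes <- int_cols(as.data.frame(p$genes), c("block", "start", "end"))
  p$features <- int_cols(as.data.frame(p$features), c("start", "end"))
  p$variants <- int_cols(as.data.frame(p$variants), c("block", "pos"))
  p$causal_map <- as.data.frame(p$causal_map)
  p$svs <- int_cols(as.data.frame(p$svs), c("start", "end"))
  p$alleles <- int_cols(as.data.frame(p$alleles), "tag_allele")
  p$haplotype_pool <- lapply(p$haplotype_pool, function(m) {
    m <- as.matrix(as.data.frame(m))
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
  })
  p$baseline_usage <- unlist(p$baseline_usage)
  p$locus_length <- as.integer(p$locus_length)
  p$block_span <- as.integer(p$block_span)
  p$seed <- as.integer(p$seed)
  structure(p, class = "locus_truth")
}
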