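# Shared fixtures and independent brute-force oracles.

# expected CDR3-property values for a 10-peptide fixture, computed
# independently (direct per-residue arithmetic on the published
# Kyte-Doolittle, Zimmerman, Grantham and EMBOSS tables)
frozen_props <- read.table(header = TRUE, sep = ",", text = "
pep,length,gravy,bulk,aliphatic,polarity,charge,acidic,basic,aromatic
QQYNSYS,7,-2.1,13.81714286,0,9.057142857,-0.003982578341,0,0,0.2857142857
AAA,3,1.8,11.5,1,8.1,0,0,0,0
FWY,3,0.2,19.83333333,0,5.6,-0.001991289171,0,0,1
ACDEFGHIKL,10,0.09,14.561,0.88,8.49,-0.9613526711,0.2,0.2,0.2
MNPQRSTVWY,10,-1.07,16.174,0.29,8.16,0.9980007676,0,0.1,0.2
KKRRHH,6,-3.866666667,14.56,0,10.73333333,4.222819756,0,1,0.3333333333
DDEE,4,-3.5,12.625,0,12.65,-3.998365872,1,0,0
GGGG,4,-0.4,3.4,0,9,0,0,0,0
VILA,4,3.575,18.9675,2.925,6.025,0,0,0,0
QQYGSSPWT,9,-1.5,13.79333333,0,8.511111111,-0.001991289171,0,0,0.2222222222
", stringsAsFactors = FALSE)

# small, fast simulation configuration for unit tests (fields overridable)
tiny_config <- function(seed = 11L, ...) {
  defaults <- list(n_samples = 40L, n_genes = 10L, n_blocks = 3L,
                   snvs_per_block = 6L, haplotypes_per_block = 4L,
                   sequences_per_sample = 1500L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# write an AIRR TSV from a data.frame of records
write_airr_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

airr_row <- function(seq_id, v = "IGKV1-5*01", j = "IGKJ1*01",
                     junction = "CQQYNSYSF", vid = 1, jid = 1) {
  data.frame(sequence_id = seq_id, v_call = v, j_call = j,
             junction_aa = junction, v_identity = vid, j_identity = jid,
             stringsAsFactors = FALSE)
}

# minimal VCF text fixture
write_vcf_fixture <- function(records, samples,
                              path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

# brute-force maximal cliques by subset enumeration (nodes <= ~15)
bf_max_cliques <- function(adj, min_size = 2L) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  cliques <- list()
  for (mask in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(members) < min_size) next
    complete <- all(adj[members, members][upper.tri(diag(length(members)))])
    if (!complete) next
    # maximal: no outside node connected to all members
    outside <- setdiff(seq_len(n), members)
    maximal <- !any(vapply(outside, function(o) all(adj[o, members]),
                           TRUE))
    if (maximal) cliques[[length(cliques) + 1L]] <- sort(nodes[members])
  }
  keys <- vapply(cliques, paste, "", collapse = ",")
  cliques[order(-vapply(cliques, length, 1L), keys)]
}

# independent Gabriel block caller: naive enumeration of every interval
# using the public pair-CI functions, then greedy longest-first selection
bf_gabriel_blocks <- function(vs, frac_strong = 0.95) {
  idx <- which(vs$variants$type == "SNV")
  idx <- idx[order(vs$variants$pos[idx])]
  m <- length(idx)
  pos <- vs$variants$pos[idx]
  if (m < 2L) return(list())
  pair_class <- function(a, b) {
    ci <- dprime_ci(guqtl:::hap_pair_counts(vs, idx[a], idx[b]))
    if (is.null(ci)) return("skip")
    if (ci$ci_low >= 0.70 && ci$ci_high >= 0.98) return("strong")
    if (ci$ci_high < 0.90) return("recomb")
    "noninformative"
  }
  pc <- matrix("", m, m)
  for (a in 1:(m - 1L)) for (b in (a + 1L):m) {
    pc[a, b] <- pc[b, a] <- pair_class(a, b)
  }
  cand <- list()
  for (i in 1:(m - 1L)) {
    for (j in (i + 1L):m) {
      cls <- character(0)
      for (a in i:(j - 1L)) {
        for (b in (a + 1L):j) cls <- c(cls, pc[a, b])
      }
      inform <- sum(cls %in% c("strong", "recomb"))
      if (inform > 0L && sum(cls == "strong") / inform >= frac_strong) {
        cand[[length(cand) + 1L]] <- c(i = i, j = j)
      }
    }
  }
  if (!length(cand)) return(list())
  cand <- do.call(rbind, cand)
  ord <- order(-(pos[cand[, "j"]] - pos[cand[, "i"]]), pos[cand[, "i"]])
  taken <- rep(FALSE, m)
  blocks <- list()
  for (r in ord) {
    i <- cand[r, "i"]; j <- cand[r, "j"]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    blocks[[length(blocks) + 1L]] <- vs$variants$id[idx[i:j]]
  }
  blocks[order(vapply(blocks, function(b)
    vs$variants$pos[match(b[1], vs$variants$id)], 1L))]
}

# exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration
bf_fisher_2x2 <- function(tab, alternative = "two.sided") {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x, m, n, k)
  if (alternative == "greater") return(sum(probs[support >= x]))
  if (alternative == "less") return(sum(probs[support <= x]))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# build a variant_set directly from phased haplotype matrices
vs_from_haps <- function(hap1, hap2, pos = NULL) {
  nv <- nrow(hap1)
  if (is.null(pos)) pos <- seq_len(nv) * 100L
  ids <- sprintf("v%02d", seq_len(nv))
  rownames(hap1) <- rownames(hap2) <- ids
  n <- ncol(hap1)
  samples <- sprintf("S%03d", seq_len(n))
  colnames(hap1) <- colnames(hap2) <- samples
  vars <- data.frame(id = ids, pos = pos, type = "SNV", ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  vars$maf <- apply(hap1 + hap2, 1, function(d) {
    f <- mean(d) / 2; min(f, 1 - f)
  })
  vars$annotation <- "intergenic"
  structure(list(variants = vars, dosage = hap1 + hap2, hap1 = hap1,
                 hap2 = hap2, phased = rep(TRUE, nv), samples = samples),
            class = "variant_set")
}

# cohort haplotypes drawn from per-block pools: returns vs with planted
# block structure (list of per-block SNV counts)
vs_from_pools <- function(pools, n_samples, gap = 2000L, spacing = 100L,
                          seed = 1L) {
  set.seed(seed)
  hap_rows <- list(); pos <- integer(0); cursor <- 0L
  h1 <- NULL; h2 <- NULL
  for (b in seq_along(pools)) {
    P <- pools[[b]]
    i1 <- sample.int(nrow(P), n_samples, replace = TRUE)
    i2 <- sample.int(nrow(P), n_samples, replace = TRUE)
    h1 <- rbind(h1, t(P[i1, , drop = FALSE]))
    h2 <- rbind(h2, t(P[i2, , drop = FALSE]))
    pos <- c(pos, cursor + seq_len(ncol(P)) * spacing)
    cursor <- cursor + ncol(P) * spacing + gap
  }
  vs_from_haps(h1, h2, pos = pos)
}
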