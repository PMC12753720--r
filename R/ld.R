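# Linkage disequilibrium statistics: genotype r2, haplotype D' with
# likelihood-based confidence intervals, and Gabriel-method haplotype blocks.

#' Genotype r-squared between two variants
#'
#' Squared Pearson correlation of alternate-allele dosage vectors over the
#' samples where both are non-missing (pairwise-complete, the vcftools
#' `--geno-r2` convention). Undefined (NA) when fewer than two shared samples
#' remain or either vector is monomorphic on them.
#'
#' @param a,b numeric dosage vectors (0/1/2, NA allowed).
#' @return squared correlation in \[0, 1\], or `NA`.
#' @export
genotype_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Pairwise genotype r-squared matrix
#'
#' @param vs a `variant_set` (or a dosage matrix, variants x samples).
#' @return symmetric matrix of squared dosage correlations (NA where
#'   undefined).
#' @export
r2_matrix <- function(vs) {
  d <- if (inherits(vs, "variant_set")) vs$dosage else vs
  suppressWarnings(stats::cor(t(d), use = "pairwise.complete.obs")^2)
}

# two-locus haplotype counts (AB, Ab, aB, ab) for a variant pair; phased
# haplotypes are counted directly, otherwise expected counts come from the
# two-locus EM on genotypes
hap_pair_counts <- function(vs, i, j) {
  use_phase <- vs$phased[i] && vs$phased[j]
  if (use_phase) {
    ok <- !is.na(vs$hap1[i, ]) & !is.na(vs$hap1[j, ]) &
      !is.na(vs$hap2[i, ]) & !is.na(vs$hap2[j, ])
    a <- c(vs$hap1[i, ok], vs$hap2[i, ok])
    b <- c(vs$hap1[j, ok], vs$hap2[j, ok])
    counts <- c(n11 = sum(a == 1 & b == 1), n10 = sum(a == 1 & b == 0),
                n01 = sum(a == 0 & b == 1), n00 = sum(a == 0 & b == 0))
    return(counts)
  }
  em <- em_haplotype_freqs(vs$dosage[i, ], vs$dosage[j, ])
  if (is.null(em)) return(NULL)
  em$freqs * em$n_haps
}

#' Two-locus haplotype frequencies by EM from unphased genotypes
#'
#' Standard expectation-maximization over the double-heterozygote phase
#' ambiguity; all other genotype combinations contribute known haplotypes.
#'
#' @param ga,gb dosage vectors (0/1/2; NA dropped pairwise).
#' @param max_iter,tol iteration cap (default 50) and convergence tolerance
#'   on the ambiguous-phase frequency (default 1e-8).
#' @return list with `freqs` (named `n11,n10,n01,n00`) and `n_haps`, or
#'   `NULL` when fewer than 2 complete samples.
#' @export
em_haplotype_freqs <- function(ga, gb, max_iter = 50L, tol = 1e-8) {
  ok <- !is.na(ga) & !is.na(gb)
  if (sum(ok) < 2L) return(NULL)
  ga <- ga[ok]; gb <- gb[ok]
  n <- length(ga)
  dh <- ga == 1L & gb == 1L   # double heterozygotes: phase unknown
  n_dh <- sum(dh)
  # known haplotype contributions from the 8 unambiguous genotype classes
  base <- c(n11 = 0, n10 = 0, n01 = 0, n00 = 0)
  for (s in which(!dh)) {
    a <- ga[s]; b <- gb[s]
    # each sample contributes two haplotypes; with at most one het locus the
    # assignment is unique
    h1a <- if (a >= 1L) 1L else 0L
    h2a <- if (a == 2L) 1L else 0L
    h1b <- if (b >= 1L) 1L else 0L
    h2b <- if (b == 2L) 1L else 0L
    if (a == 1L) { h1a <- 1L; h2a <- 0L }
    if (b == 1L) { h1b <- 1L; h2b <- 0L }
    # pair the het allele with the homozygous background
    add <- function(x, y) paste0("n", x, y)
    base[add(h1a, h1b)] <- base[add(h1a, h1b)] + 1
    base[add(h2a, h2b)] <- base[add(h2a, h2b)] + 1
  }
  f <- rep(0.25, 4)
  names(f) <- names(base)
  for (it in seq_len(max_iter)) {
    # probability a double het is in cis (AB/ab) vs trans (Ab/aB)
    p_cis <- f["n11"] * f["n00"]
    p_trans <- f["n10"] * f["n01"]
    w <- if (p_cis + p_trans > 0) p_cis / (p_cis + p_trans) else 0.5
    cnt <- base + n_dh * c(w, 1 - w, 1 - w, w)
    f_new <- cnt / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  list(freqs = f, n_haps = 2 * n)
}

#' D-prime with likelihood-based confidence interval
#'
#' Computes \eqn{D' = |D| / D_{max}} from two-locus haplotype counts and a
#' 90% confidence interval (5th/95th percentile) from the likelihood of
#' \eqn{|D'|} evaluated on a 101-point grid with the allele marginals fixed
#' at their observed values (flat prior), the approach underlying
#' Gabriel-style haplotype blocks.
#'
#' @param counts named haplotype counts `n11, n10, n01, n00` (may be
#'   fractional, e.g. EM-expected), or `NULL`.
#' @return list `dprime`, `ci_low`, `ci_high`, or `NULL` when either locus is
#'   monomorphic (non-informative pair).
#' @export
dprime_ci <- function(counts) {
  if (is.null(counts)) return(NULL)
  n <- sum(counts)
  pA <- (counts[["n11"]] + counts[["n10"]]) / n
  pB <- (counts[["n11"]] + counts[["n01"]]) / n
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NULL)
  D <- counts[["n11"]] / n - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(NULL)
  dprime <- abs(D) / dmax
  sgn <- if (D >= 0) 1 else -1
  grid <- seq(0, 1, length.out = 101L)
  ll <- vapply(grid, function(d) {
    Dg <- sgn * d * dmax
    p <- c(pA * pB + Dg, pA * (1 - pB) - Dg,
           (1 - pA) * pB - Dg, (1 - pA) * (1 - pB) + Dg)
    p <- pmax(p, 1e-12)
    sum(counts * log(p))
  }, 0)
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  cdf <- cumsum(post)
  ci_low <- grid[which(cdf >= 0.05)[1L]]
  ci_high <- grid[which(cdf >= 0.95)[1L]]
  list(dprime = min(dprime, 1), ci_low = ci_low, ci_high = ci_high)
}

# Gabriel pair classification from a dprime_ci result
classify_pair <- function(ci, strong_low = 0.70, strong_high = 0.98,
                          recomb_high = 0.90) {
  if (is.null(ci)) return("skip")
  if (ci$ci_low >= strong_low && ci$ci_high >= strong_high) return("strong")
  if (ci$ci_high < recomb_high) return("recomb")
  "noninformative"
}

#' Pairwise D-prime table for a variant set
#'
#' @param vs a `variant_set` (SNVs only are used).
#' @return data.frame `id_a, id_b, dprime, ci_low, ci_high, class` for every
#'   informative pair (monomorphic pairs are skipped).
#' @export
dprime_table <- function(vs) {
  idx <- which(vs$variants$type == "SNV")
  out <- list()
  for (a in seq_along(idx)) {
    for (b in seq_len(a - 1L)) {
      i <- idx[b]; j <- idx[a]
      ci <- dprime_ci(hap_pair_counts(vs, i, j))
      if (is.null(ci)) next
      out[[length(out) + 1L]] <- data.frame(
        id_a = vs$variants$id[i], id_b = vs$variants$id[j],
        dprime = ci$dprime, ci_low = ci$ci_low, ci_high = ci$ci_high,
        class = classify_pair(ci), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(id_a = character(), id_b = character(),
                      dprime = numeric(), ci_low = numeric(),
                      ci_high = numeric(), class = character()))
  }
  do.call(rbind, out)
}

#' Gabriel-method haplotype blocks
#'
#' Classifies every SNV pair by its D' confidence interval: strong LD when
#' the lower bound is at least `strong_low` (0.70) and the upper bound at
#' least `strong_high` (0.98); strong recombination when the upper bound is
#' below `recomb_high` (0.90); otherwise non-informative. A candidate block
#' is any run of 2+ consecutive SNVs in which at least `frac_strong` (95%) of
#' informative pairs show strong LD; non-overlapping blocks are then chosen
#' greedily, longest span first (ties: leftmost).
#'
#' @param vs a `variant_set` of common variants, sorted by position (SNVs are
#'   used; SVs ignored).
#' @param strong_low,strong_high,recomb_high,frac_strong Gabriel thresholds.
#' @return data.frame, one row per block: `block`, `start`, `end` (positions
#'   of the outermost member SNVs), `length_bp`, `n_snvs`, and a list column
#'   `snv_ids`.
#' @export
gabriel_blocks <- function(vs, strong_low = 0.70, strong_high = 0.98,
                           recomb_high = 0.90, frac_strong = 0.95) {
  idx <- which(vs$variants$type == "SNV")
  idx <- idx[order(vs$variants$pos[idx])]
  m <- length(idx)
  empty <- data.frame(block = integer(), start = integer(), end = integer(),
                      length_bp = integer(), n_snvs = integer())
  empty$snv_ids <- list()
  if (m < 2L) return(empty)
  # pair classification codes: 1 strong, -1 recomb, 0 noninformative/skip
  cls <- matrix(0L, m, m)
  for (a in 2:m) {
    for (b in 1:(a - 1L)) {
      ci <- dprime_ci(hap_pair_counts(vs, idx[b], idx[a]))
      k <- classify_pair(ci, strong_low, strong_high, recomb_high)
      cls[b, a] <- cls[a, b] <- switch(k, strong = 1L, recomb = -1L, 0L)
    }
  }
  pos <- vs$variants$pos[idx]
  cand <- list()
  for (i in seq_len(m - 1L)) {
    n_strong <- 0L
    n_inform <- 0L
    for (j in (i + 1L):m) {
      add <- cls[i:(j - 1L), j]
      n_strong <- n_strong + sum(add == 1L)
      n_inform <- n_inform + sum(add != 0L)
      if (n_inform > 0L && n_strong / n_inform >= frac_strong) {
        cand[[length(cand) + 1L]] <- c(i = i, j = j)
      }
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  span <- pos[cand[, "j"]] - pos[cand[, "i"]]
  ord <- order(-span, pos[cand[, "i"]])
  taken <- rep(FALSE, m)
  blocks <- list()
  for (r in ord) {
    i <- cand[r, "i"]; j <- cand[r, "j"]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    blocks[[length(blocks) + 1L]] <- list(
      start = pos[i], end = pos[j], n_snvs = j - i + 1L,
      snv_ids = vs$variants$id[idx[i:j]])
  }
  blocks <- blocks[order(vapply(blocks, `[[`, 1L, "start"))]
  out <- data.frame(
    block = seq_along(blocks),
    start = vapply(blocks, `[[`, 1L, "start"),
    end = vapply(blocks, `[[`, 1L, "end"),
    n_snvs = vapply(blocks, `[[`, 1L, "n_snvs"))
  out$length_bp <- out$end - out$start + 1L
  out$snv_ids <- lapply(blocks, `[[`, "snv_ids")
  out[, c("block", "start", "end", "length_bp", "n_snvs", "snv_ids")]
}

#' Summarize LD block coverage and SNV density
#'
#' @param blocks data.frame from [gabriel_blocks()].
#' @param region_length locus length in bp.
#' @param n_snvs number of common SNVs in the region (for density; optional).
#' @param breaks block-length class boundaries in bp.
#' @return list with `coverage` (data.frame: size class, total bp, percent of
#'   locus), `percent_in_blocks` and `snv_per_kbp` (NA when `n_snvs` absent).
#' @export
ld_summary <- function(blocks, region_length,
                       n_snvs = NULL,
                       breaks = c(0, 1000, 5000, 10000, 20000, Inf)) {
  lens <- if (nrow(blocks)) blocks$length_bp else numeric(0)
  cls <- cut(lens, breaks = breaks, include.lowest = TRUE, right = FALSE)
  bp <- tapply(lens, cls, sum, default = 0)
  cov <- data.frame(size_class = levels(cls), total_bp = as.numeric(bp),
                    percent = 100 * as.numeric(bp) / region_length,
                    stringsAsFactors = FALSE)
  list(coverage = cov,
       percent_in_blocks = 100 * sum(lens) / region_length,
       snv_per_kbp = if (is.null(n_snvs)) NA_real_ else
         n_snvs / (region_length / 1000))
}
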