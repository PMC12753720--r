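# guQTL mapping: per-variant OLS of traits on allele dosage with LD-aware
# Bonferroni correction, lead selection and fold-change reporting.

#' Partition variants into perfect-LD classes
#'
#' Connected components of the graph joining variant pairs with genotype
#' r-squared equal to 1 (within `tol`). Variants in one class are
#' statistically a single hypothesis test, so the effective test count for
#' Bonferroni correction is the number of classes.
#'
#' @param vs a `variant_set`, or a dosage matrix (variants x samples) with
#'   rownames.
#' @param tol tolerance on `1 - r2` (default 1e-12).
#' @return integer vector of class ids, named by variant id.
#' @export
perfect_ld_classes <- function(vs, tol = 1e-12) {
  d <- if (inherits(vs, "variant_set")) vs$dosage else vs
  ids <- rownames(d)
  r2 <- r2_matrix(d)
  adj <- !is.na(r2) & r2 >= 1 - tol
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  setNames(as.integer(comp), ids)
}

#' Bonferroni threshold over effective tests
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_effective number of effective (perfect-LD-collapsed) tests.
#' @return per-test p-value threshold `alpha / n_effective`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_effective) {
  if (n_effective < 1L) stop("n_effective must be >= 1")
  alpha / n_effective
}

#' Simple linear regression of a trait on allele dosage
#'
#' Ordinary least squares with additive genotype coding (0/1/2): slope,
#' two-sided p from the slope t statistic, and adjusted R-squared
#' \eqn{1 - (1 - R^2)(n - 1)/(n - 2)}. Samples missing either value are
#' dropped pairwise. A constant dosage (or fewer than 3 complete samples)
#' is untestable; a constant trait returns beta 0, p 1.
#'
#' @param trait,dosage numeric vectors of equal length.
#' @return list `beta, intercept, p_value, r2, adjusted_r2, n, testable`.
#' @export
regress_trait_on_dosage <- function(trait, dosage) {
  ok <- !is.na(trait) & !is.na(dosage)
  x <- dosage[ok]; y <- trait[ok]
  n <- length(x)
  if (n < 3L || stats::var(x) == 0) {
    return(list(beta = NA_real_, intercept = NA_real_, p_value = NA_real_,
                r2 = NA_real_, adjusted_r2 = NA_real_, n = n,
                testable = FALSE))
  }
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (syy == 0) {
    return(list(beta = 0, intercept = mean(y), p_value = 1, r2 = 0,
                adjusted_r2 = 1 - (n - 1) / (n - 2), n = n, testable = TRUE))
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  r2 <- sxy^2 / (sxx * syy)
  tstat <- sign(beta) * sqrt(r2 * (n - 2) / max(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(beta = beta, intercept = mean(y) - beta * mean(x), p_value = p,
       r2 = r2, adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - 2), n = n,
       testable = TRUE)
}

#' Fold change between genotype-group means
#'
#' Ratio of the larger to the smaller mean trait value between the two
#' homozygous dosage groups (0 vs 2); when a homozygous group is empty the
#' two extreme observed dosage groups are used. `Inf` when the smaller mean
#' is exactly 0; `NA` when only one genotype group is observed.
#'
#' @param trait,dosage numeric vectors.
#' @return ratio >= 1, `Inf`, or `NA`.
#' @export
fold_change <- function(trait, dosage) {
  ok <- !is.na(trait) & !is.na(dosage)
  x <- dosage[ok]; y <- trait[ok]
  groups <- sort(unique(x))
  if (length(groups) < 2L) return(NA_real_)
  lo <- if (0 %in% groups && 2 %in% groups) c(0, 2) else range(groups)
  m1 <- mean(y[x == lo[1]])
  m2 <- mean(y[x == lo[2]])
  hi <- max(m1, m2); sm <- min(m1, m2)
  if (sm == 0) return(Inf)
  hi / sm
}

# Vectorized OLS of every trait row on every dosage row (complete data).
# Returns list of g x v matrices: beta, p, r2, adj_r2.
ols_scan <- function(tr, d) {
  n <- ncol(tr)
  tc <- tr - rowMeans(tr)
  dc <- d - rowMeans(d)
  sxx <- rowSums(dc^2)
  syy <- rowSums(tc^2)
  sxy <- tc %*% t(dc)
  beta <- sweep(sxy, 2L, sxx, "/")
  r2 <- sweep(sxy^2, 2L, sxx, "/") / ifelse(syy > 0, syy, NA_real_)
  tstat <- sign(beta) * sqrt(r2 * (n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  const <- syy == 0
  if (any(const)) {
    beta[const, ] <- 0
    r2[const, ] <- 0
    p[const, ] <- 1
  }
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  list(beta = beta, p = p, r2 = r2, adj_r2 = adj, n = n)
}

# core scan shared by gene-usage and CDR3-property QTL mapping
qtl_scan <- function(traits, vs, alpha = 0.05, trait_kind = "usage") {
  shared <- intersect(colnames(traits), vs$samples)
  if (!length(shared)) {
    stop("no overlapping samples between traits (",
         paste(utils::head(colnames(traits), 3), collapse = ","),
         "...) and genotypes (",
         paste(utils::head(vs$samples, 3), collapse = ","), "...)")
  }
  d_all <- vs$dosage[, shared, drop = FALSE]
  tr <- traits[, shared, drop = FALSE]
  v_ok <- apply(d_all, 1L, function(x) {
    x <- x[!is.na(x)]
    length(x) >= 3L && stats::var(x) > 0
  })
  if (!any(v_ok)) {
    return(list(results = NULL, classes = integer(0), thresholds = NULL))
  }
  d <- d_all[v_ok, , drop = FALSE]
  classes <- perfect_ld_classes(d)
  n_eff <- length(unique(classes))
  threshold <- bonferroni_threshold(alpha, n_eff)
  vinfo <- vs$variants[v_ok, , drop = FALSE]

  complete <- !anyNA(d) && !anyNA(tr)
  res_rows <- vector("list", nrow(tr))
  for (g in seq_len(nrow(tr))) {
    if (complete) {
      if (g == 1L) sc <- ols_scan(tr, d)
      beta <- sc$beta[g, ]; p <- sc$p[g, ]; adj <- sc$adj_r2[g, ]
      nn <- rep(sc$n, nrow(d))
    } else {
      fits <- lapply(seq_len(nrow(d)), function(v)
        regress_trait_on_dosage(tr[g, ], d[v, ]))
      beta <- vapply(fits, `[[`, 0, "beta")
      p <- vapply(fits, `[[`, 0, "p_value")
      adj <- vapply(fits, `[[`, 0, "adjusted_r2")
      nn <- vapply(fits, `[[`, 0L, "n")
    }
    testable <- !is.na(p)
    sig <- testable & p < threshold
    lead_class <- NA_integer_
    is_lead <- rep(FALSE, nrow(d))
    if (any(testable)) {
      pmin_idx <- which(testable)[which.min(p[testable])]
      lead_class <- classes[pmin_idx]
      is_lead <- testable & classes == lead_class
    }
    fc <- rep(NA_real_, nrow(d))
    if (any(is_lead) && trait_kind == "usage") {
      rep_idx <- which(is_lead)
      rep_idx <- rep_idx[order(vinfo$pos[rep_idx], vinfo$id[rep_idx])][1L]
      fc[is_lead] <- fold_change(tr[g, ], d[rep_idx, ])
    }
    res_rows[[g]] <- data.table::data.table(
      trait = rownames(tr)[g], variant_id = vinfo$id, position = vinfo$pos,
      type = vinfo$type, annotation = vinfo$annotation,
      beta = beta, p_value = p, adjusted_r2 = adj, n = nn,
      significant = sig, ld_class = as.integer(classes),
      is_lead = is_lead, fold_change = fc)
  }
  results <- data.table::rbindlist(res_rows)
  thresholds <- data.table::data.table(
    trait = rownames(tr), alpha = alpha, n_effective = n_eff,
    threshold = threshold)
  list(results = results, classes = classes, thresholds = thresholds)
}

#' Map gene-usage QTLs
#'
#' Regresses every gene's usage frequency on the dosage of every common
#' variant over the shared samples, applies a per-gene Bonferroni threshold
#' over the effective (perfect-LD-collapsed) number of tests, flags
#' significant variants, marks the lead LD class (smallest p; all members of
#' that class are co-leads) and attaches the fold change in mean usage
#' between extreme genotype groups at the lead.
#'
#' @param usage a `usage_matrix`.
#' @param vs a common-filtered `variant_set`.
#' @param alpha family-wise error rate per gene (default 0.05).
#' @return list with `results` (data.table: trait, variant_id, position,
#'   type, annotation, beta, p_value, adjusted_r2, n, significant, ld_class,
#'   is_lead, fold_change), `thresholds` (per-trait effective test counts)
#'   and `classes`.
#' @export
run_guqtl <- function(usage, vs, alpha = 0.05) {
  stopifnot(inherits(usage, "usage_matrix"), inherits(vs, "variant_set"))
  qtl_scan(usage$values, vs, alpha, trait_kind = "usage")
}

#' Map CDR3-property QTLs
#'
#' Same machinery as [run_guqtl()] with sample-level CDR3 property means as
#' traits and a per-property Bonferroni threshold.
#'
#' @param properties data.frame from [compute_cdr3_properties()].
#' @param vs a common-filtered `variant_set`.
#' @param alpha family-wise error rate per property.
#' @return as [run_guqtl()] (no fold change for property traits).
#' @export
run_property_qtl <- function(properties, vs, alpha = 0.05) {
  prop_cols <- c("length", "gravy", "bulk", "aliphatic", "polarity",
                 "charge", "acidic", "basic", "aromatic")
  pm <- t(as.matrix(as.data.frame(properties)[, prop_cols]))
  colnames(pm) <- properties$sample_id
  keep <- colSums(is.na(pm)) == 0
  qtl_scan(pm[, keep, drop = FALSE], vs, alpha, trait_kind = "property")
}

#' Cross-reference property-QTL leads with gene-usage QTLs
#'
#' For each property's lead variant (class representative), counts the genes
#' for which that same variant is a significant gene-usage QTL.
#'
#' @param property_results results from [run_property_qtl()].
#' @param guqtl_results results from [run_guqtl()].
#' @return data.table `trait, lead_variant, n_guqtl_genes, guqtl_genes`.
#' @export
property_guqtl_overlap <- function(property_results, guqtl_results) {
  pr <- property_results$results
  gr <- guqtl_results$results
  out <- list()
  for (tr in unique(pr$trait)) {
    sub <- pr[pr$trait == tr & pr$is_lead]
    if (!nrow(sub) || !any(sub$significant)) next
    sub <- sub[order(sub$position, sub$variant_id)]
    lead <- sub$variant_id[1L]
    genes <- unique(gr$trait[gr$significant &
                               gr$variant_id %in% sub$variant_id])
    out[[length(out) + 1L]] <- data.table::data.table(
      trait = tr, lead_variant = lead, n_guqtl_genes = length(genes),
      guqtl_genes = paste(sort(genes), collapse = ","))
  }
  if (!length(out)) {
    return(data.table::data.table(trait = character(),
                                  lead_variant = character(),
                                  n_guqtl_genes = integer(),
                                  guqtl_genes = character()))
  }
  data.table::rbindlist(out)
}
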