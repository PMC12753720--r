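# Shared-guQTL gene networks and cliques, coding-allele linkage tests, and
# feature-track enrichment.

#' Per-gene significant-variant sets
#'
#' Compiles, for each trait (gene), the set of variant ids significantly
#' associated with its usage after Bonferroni correction. Genes with no
#' significant variants are omitted.
#'
#' @param results the `results` data.table from [run_guqtl()] (or the list
#'   returned by it).
#' @return named list of character vectors (gene -> significant variant ids).
#' @export
build_guqtl_sets <- function(results) {
  if (is.list(results) && !is.data.frame(results) &&
      "results" %in% names(results)) {
    results <- results$results
  }
  sig <- results[results$significant, , drop = FALSE]
  if (!nrow(sig)) return(list())
  sets <- split(sig$variant_id, sig$trait)
  lapply(sets, function(v) sort(unique(v)))
}

#' Jaccard similarity of two variant sets
#'
#' Ratio of shared variants to total unique variants across the two sets;
#' 0 when disjoint, undefined (NA) when both sets are empty.
#'
#' @param set_a,set_b character vectors.
#' @return fraction in \[0, 1\], or `NA` for two empty sets.
#' @export
jaccard_index <- function(set_a, set_b) {
  u <- length(union(set_a, set_b))
  if (u == 0L) return(NA_real_)
  length(intersect(set_a, set_b)) / u
}

#' Build the shared-guQTL gene network
#'
#' Nodes are genes with non-empty significant-variant sets; an edge joins
#' every gene pair sharing at least one variant, labeled with the shared
#' count and the Jaccard similarity.
#'
#' @param sets named list from [build_guqtl_sets()].
#' @return object of class `gene_network`: list with `nodes`, `edges`
#'   (data.frame gene_a, gene_b, shared, jaccard) and `graph` (igraph).
#' @export
build_network <- function(sets) {
  sets <- sets[vapply(sets, length, 1L) > 0L]
  genes <- names(sets)
  edges <- list()
  if (length(genes) >= 2L) {
    for (a in seq_along(genes)) {
      for (b in seq_len(a - 1L)) {
        shared <- length(intersect(sets[[a]], sets[[b]]))
        if (shared >= 1L) {
          edges[[length(edges) + 1L]] <- data.frame(
            gene_a = genes[b], gene_b = genes[a], shared = shared,
            jaccard = jaccard_index(sets[[a]], sets[[b]]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(gene_a = character(), gene_b = character(),
               shared = integer(), jaccard = numeric())
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = genes))
  structure(list(nodes = genes, edges = edges, graph = g),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n", length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Enumerate maximal cliques of size >= 2
#'
#' Maximal cliques of the shared-guQTL network (Bron-Kerbosch with pivoting,
#' via \pkg{igraph}), sorted by size descending then lexicographically by
#' members.
#'
#' @param network a `gene_network` (or an igraph graph).
#' @param min_size smallest clique size to report (default 2).
#' @return list of character vectors of gene names.
#' @export
find_cliques <- function(network, min_size = 2L) {
  g <- if (inherits(network, "gene_network")) network$graph else network
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  keys <- vapply(cl, paste, "", collapse = ",")
  cl[order(-vapply(cl, length, 1L), keys)]
}

#' Coding-allele linkage to lead guQTL genotype
#'
#' Two-way Fisher's exact test of a contingency table of coding-allele counts
#' (rows) by lead-guQTL genotype group (columns). 2x2 tables are exact via
#' the hypergeometric distribution; larger tables use the exact network
#' algorithm when feasible and otherwise Monte Carlo with a fixed seed.
#' Significance is assessed at `0.05 / n_genes_tested` (Bonferroni across
#' genes).
#'
#' @param table matrix of non-negative counts (alleles x genotype groups).
#' @param n_genes_tested number of genes in the Bonferroni family.
#' @param mc_cutoff_cells,mc_cutoff_n table size (rows x cols) and margin
#'   total above which Monte Carlo is used.
#' @param mc_draws,mc_seed Monte Carlo replicate count and seed.
#' @return list `p_value, significant, threshold, testable`.
#' @export
coding_allele_linkage_test <- function(table, n_genes_tested = 1L,
                                       mc_cutoff_cells = 25L,
                                       mc_cutoff_n = 200L,
                                       mc_draws = 1e5, mc_seed = 20260101L) {
  table <- as.matrix(table)
  table <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
  if (nrow(table) < 2L || ncol(table) < 2L) {
    return(list(p_value = NA_real_, significant = FALSE,
                threshold = 0.05 / n_genes_tested, testable = FALSE))
  }
  use_mc <- prod(dim(table)) > mc_cutoff_cells || sum(table) > mc_cutoff_n
  if (nrow(table) == 2L && ncol(table) == 2L) use_mc <- FALSE
  p <- if (use_mc) {
    set.seed(mc_seed)
    stats::fisher.test(table, simulate.p.value = TRUE, B = mc_draws)$p.value
  } else {
    stats::fisher.test(table)$p.value
  }
  thr <- 0.05 / n_genes_tested
  list(p_value = p, significant = p < thr, threshold = thr, testable = TRUE)
}

#' Label genes lacking appreciable allelic variation
#'
#' Genes whose major coding allele exceeds `maf_major` frequency in the
#' cohort are excluded from the allele-linkage Fisher tests.
#'
#' @param allele_counts named numeric vector of cohort allele-copy counts.
#' @param maf_major major-allele frequency cutoff (default 0.95).
#' @return TRUE when the gene lacks appreciable allelic variation.
#' @export
lacks_allelic_variation <- function(allele_counts, maf_major = 0.95) {
  tot <- sum(allele_counts)
  if (tot == 0) return(TRUE)
  max(allele_counts) / tot > maf_major
}

#' Feature-track enrichment of guQTL variants
#'
#' One-sided (greater) Fisher's exact test of the 2x2 table crossing guQTL
#' membership with track overlap among background variants.
#'
#' @param guqtl_ids variant ids of the guQTL set (must be a subset of the
#'   background).
#' @param background_ids all tested variant ids.
#' @param in_track logical (named by variant id) or character vector of ids
#'   overlapping the track.
#' @return list `odds_ratio, p_value, table`; untestable (NA) when the track
#'   is empty on the background.
#' @export
feature_enrichment <- function(guqtl_ids, background_ids, in_track) {
  stopifnot(all(guqtl_ids %in% background_ids))
  if (is.character(in_track)) {
    in_track <- setNames(background_ids %in% in_track, background_ids)
  }
  hit <- in_track[background_ids]
  is_gu <- background_ids %in% guqtl_ids
  tab <- matrix(c(sum(is_gu & hit), sum(is_gu & !hit),
                  sum(!is_gu & hit), sum(!is_gu & !hit)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("guQTL", "background"),
                                c("in_track", "out_track")))
  if (sum(tab[, "in_track"]) == 0L) {
    return(list(odds_ratio = NA_real_, p_value = NA_real_, table = tab))
  }
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Count coding-allele copies by genotype group
#'
#' Builds the contingency table for [coding_allele_linkage_test()]: rows are
#' coding alleles, columns are genotype groups at the lead guQTL, cells are
#' diploid allele copies (default) or carrier counts.
#'
#' @param alleles character matrix or data.frame with two columns (the two
#'   allele copies per sample; NA for deleted haplotypes).
#' @param genotype per-sample dosage group at the lead variant (0/1/2).
#' @param unit `"copies"` (each haplotype contributes one count) or
#'   `"carriers"` (each sample counts once per allele it carries).
#' @return contingency matrix.
#' @export
allele_genotype_table <- function(alleles, genotype, unit = c("copies",
                                                              "carriers")) {
  unit <- match.arg(unit)
  alleles <- as.matrix(alleles)
  stopifnot(nrow(alleles) == length(genotype))
  rows <- list()
  for (s in seq_along(genotype)) {
    if (is.na(genotype[s])) next
    a <- alleles[s, ]
    a <- a[!is.na(a)]
    if (unit == "carriers") a <- unique(a)
    if (length(a)) {
      rows[[length(rows) + 1L]] <- data.frame(
        allele = unname(a), group = unname(genotype[s]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(matrix(0L, 0L, 0L))
  df <- do.call(rbind, rows)
  as.matrix(table(df$allele, df$group))
}
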