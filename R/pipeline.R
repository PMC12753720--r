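# End-to-end orchestration: simulate (or ingest) -> usage -> genotypes ->
# LD -> guQTL -> property QTL -> networks -> reports, with seeded
# reproducibility and per-stage record accounting.

#' Pipeline configuration
#'
#' Exactly one of `simulation` (a [sim_config()]) or `inputs` (paths to real
#' data) must be supplied.
#'
#' @param simulation a [sim_config()] describing a synthetic cohort, or NULL.
#' @param inputs list with `airr_manifest` (TSV: sample_id, path), `vcf`,
#'   `feature_bed`; or NULL.
#' @param partitions repertoire partitions to analyze.
#' @param maf_min,min_gene_count,min_sample_sequences,alpha pipeline
#'   thresholds (common-variant MAF, gene count filter, sample sequence
#'   filter, per-trait family-wise error rate).
#' @param out_dir output directory.
#' @param seed integer seed driving every stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            partitions = c("unmutated", "mutated"),
                            maf_min = 0.05, min_gene_count = 10L,
                            min_sample_sequences = 100L, alpha = 0.05,
                            out_dir = "guqtl_run", seed = 42L) {
  if (is.null(simulation) == is.null(inputs)) {
    stop("exactly one of `simulation` and `inputs` must be supplied")
  }
  stopifnot(all(partitions %in% c("unmutated", "mutated")))
  if (maf_min <= 0 || min_gene_count <= 0 || min_sample_sequences <= 0 ||
      alpha <= 0) {
    stop("thresholds must be positive")
  }
  if (!is.null(simulation)) {
    stopifnot(inherits(simulation, "sim_config"))
    simulation$seed <- as.integer(seed)
  }
  structure(list(simulation = simulation, inputs = inputs,
                 partitions = partitions, maf_min = maf_min,
                 min_gene_count = as.integer(min_gene_count),
                 min_sample_sequences = as.integer(min_sample_sequences),
                 alpha = alpha, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# combine V and J usage matrices into one trait matrix on shared samples
combine_usage <- function(uv, uj) {
  shared <- intersect(uv$samples, uj$samples)
  rbind(uv$values[, shared, drop = FALSE], uj$values[, shared, drop = FALSE])
}

write_tsv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE)
  path
}

#' Run the full guQTL pipeline
#'
#' Executes the analysis stages in order, writing per-stage TSV/JSON outputs
#' and a run manifest into `config$out_dir`: simulation (when configured),
#' repertoire ingestion and usage/CDR3 computation per partition, variant
#' loading/filtering/annotation, LD (pairwise D', Gabriel blocks, locus
#' summary), gene-usage and CDR3-property QTL mapping per partition,
#' shared-QTL networks and cliques, feature enrichment, and a partition
#' comparison. All randomness derives from `config$seed`; two runs with the
#' same configuration produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list of in-memory stage results; files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- "setup"
  result <- list()
  tryCatch({
    # ---- stage: simulate -------------------------------------------------
    if (!is.null(config$simulation)) {
      stage <- "simulate"
      sc <- config$simulation
      truth <- simulate_locus(sc)
      geno <- simulate_cohort_genotypes(truth, sc,
                                        vcf_path = file.path(out,
                                                             "cohort.vcf"))
      rep_out <- simulate_repertoires(truth, geno, sc,
                                      file.path(out, "airr"))
      write_truth(truth, file.path(out, "truth.json"))
      write_feature_bed(truth, file.path(out, "features.bed"))
      write_allele_fasta(truth, file.path(out, "alleles.fasta"))
      # manifest on disk uses paths relative to the run directory so runs
      # are relocatable (and byte-identical across output locations)
      rel_manifest <- rep_out$manifest
      rel_manifest$path <- file.path("airr", basename(rel_manifest$path))
      write_tsv(rel_manifest, file.path(out, "airr_manifest.tsv"))
      airr_manifest <- rep_out$manifest
      vcf_path <- file.path(out, "cohort.vcf")
      bed_path <- file.path(out, "features.bed")
      region_length <- truth$locus_length
      note("simulate: %d samples, %d genes, %d SNVs, %d SVs",
           sc$n_samples, nrow(truth$genes), nrow(truth$variants),
           nrow(truth$svs))
      result$truth <- truth
      result$geno <- geno
    } else {
      stage <- "inputs"
      airr_manifest <- utils::read.delim(config$inputs$airr_manifest,
                                         stringsAsFactors = FALSE)
      # relative paths in a manifest are taken relative to its location
      rel <- !grepl("^(/|[A-Za-z]:)", airr_manifest$path)
      airr_manifest$path[rel] <-
        file.path(dirname(config$inputs$airr_manifest),
                  airr_manifest$path[rel])
      vcf_path <- config$inputs$vcf
      bed_path <- config$inputs$feature_bed
      region_length <- config$inputs$region_length
    }

    # ---- stage: repertoire ----------------------------------------------
    stage <- "repertoire"
    records <- load_rearrangements(airr_manifest$path,
                                   airr_manifest$sample_id)
    note("repertoire: %d records from %d samples", nrow(records),
         length(unique(records$sample_id)))
    records <- collapse_ambiguous_genes(records)
    parts <- partition_by_mutation(records)
    note("partition: %d unmutated / %d mutated", nrow(parts$unmutated),
         nrow(parts$mutated))

    usage <- list()
    cdr3 <- list()
    for (p in config$partitions) {
      uv <- compute_usage_matrix(parts[[p]], p, axis = "V",
                                 min_gene_count = config$min_gene_count,
                                 min_sample_sequences =
                                   config$min_sample_sequences)
      uj <- compute_usage_matrix(parts[[p]], p, axis = "J",
                                 min_gene_count = config$min_gene_count,
                                 min_sample_sequences =
                                   config$min_sample_sequences)
      usage[[p]] <- list(V = uv, J = uj, traits = combine_usage(uv, uj))
      cdr3[[p]] <- compute_cdr3_properties(parts[[p]], p)
      write_tsv(cbind(gene = rownames(usage[[p]]$traits),
                      as.data.frame(usage[[p]]$traits)),
                file.path(out, paste0("usage_", p, ".tsv")))
      write_tsv(cdr3[[p]], file.path(out, paste0("cdr3_", p, ".tsv")))
      note("usage[%s]: %d genes x %d samples", p,
           nrow(usage[[p]]$traits), ncol(usage[[p]]$traits))
    }
    result$usage <- usage
    result$cdr3 <- cdr3

    # ---- stage: variants -------------------------------------------------
    stage <- "variants"
    vs <- load_variants(vcf_path)
    n_loaded <- nrow(vs$variants)
    vs <- filter_common(vs, config$maf_min)
    vs <- annotate_variants(vs, bed_path)
    note("variants: %d loaded, %d common (MAF >= %g)", n_loaded,
         nrow(vs$variants), config$maf_min)
    write_tsv(vs$variants, file.path(out, "variants_common.tsv"))
    result$variants <- vs

    # ---- stage: LD -------------------------------------------------------
    stage <- "ld"
    ld_pairs <- dprime_table(vs)
    blocks <- gabriel_blocks(vs)
    n_snv <- sum(vs$variants$type == "SNV")
    ldsum <- ld_summary(blocks, region_length, n_snvs = n_snv)
    write_tsv(ld_pairs, file.path(out, "ld_pairs.tsv"))
    btab <- blocks[, c("block", "start", "end", "length_bp", "n_snvs")]
    btab$snv_ids <- vapply(blocks$snv_ids, paste, "", collapse = ",")
    write_tsv(btab, file.path(out, "ld_blocks.tsv"))
    write_tsv(ldsum$coverage, file.path(out, "ld_coverage.tsv"))
    note("ld: %d blocks covering %.1f%% of locus; %.2f SNVs/kbp",
         nrow(blocks), ldsum$percent_in_blocks, ldsum$snv_per_kbp)
    result$blocks <- blocks
    result$ld_summary <- ldsum

    # ---- stage: association ---------------------------------------------
    stage <- "association"
    assoc <- list()
    prop_assoc <- list()
    for (p in config$partitions) {
      um <- usage[[p]]$V
      um$values <- usage[[p]]$traits
      um$genes <- rownames(usage[[p]]$traits)
      assoc[[p]] <- run_guqtl(um, vs, alpha = config$alpha)
      write_tsv(assoc[[p]]$results,
                file.path(out, paste0("guqtl_", p, ".tsv")))
      write_tsv(assoc[[p]]$thresholds,
                file.path(out, paste0("guqtl_thresholds_", p, ".tsv")))
      props <- cdr3[[p]]
      pmat_ok <- sum(stats::complete.cases(as.data.frame(props))) >= 3
      if (pmat_ok) {
        prop_assoc[[p]] <- run_property_qtl(props, vs, alpha = config$alpha)
        write_tsv(prop_assoc[[p]]$results,
                  file.path(out, paste0("cdr3_qtl_", p, ".tsv")))
      }
      note("guqtl[%s]: %d significant variant-gene pairs", p,
           sum(assoc[[p]]$results$significant))
    }
    result$assoc <- assoc
    result$prop_assoc <- prop_assoc

    # ---- stage: networks -------------------------------------------------
    stage <- "networks"
    p0 <- config$partitions[1L]
    sets <- build_guqtl_sets(assoc[[p0]])
    net <- build_network(sets)
    cliques <- find_cliques(net)
    write_tsv(net$edges, file.path(out, "network_edges.tsv"))
    ctab <- data.frame(
      clique = seq_along(cliques),
      size = vapply(cliques, length, 1L),
      members = vapply(cliques, paste, "", collapse = ","))
    write_tsv(ctab, file.path(out, "cliques.tsv"))
    note("network: %d nodes, %d edges, %d cliques (largest %d)",
         length(net$nodes), nrow(net$edges), length(cliques),
         if (length(cliques)) max(vapply(cliques, length, 1L)) else 0L)
    result$sets <- sets
    result$network <- net
    result$cliques <- cliques

    # feature enrichment of guQTL SNVs against each annotation class
    guqtl_ids <- unique(assoc[[p0]]$results$variant_id[
      assoc[[p0]]$results$significant])
    snv_ids <- vs$variants$id[vs$variants$type == "SNV"]
    enr_rows <- list()
    for (feat in setdiff(unique(vs$variants$annotation), "intergenic")) {
      ids_in <- vs$variants$id[vs$variants$annotation == feat]
      er <- feature_enrichment(intersect(guqtl_ids, snv_ids), snv_ids,
                               ids_in)
      enr_rows[[feat]] <- data.frame(track = feat,
                                     odds_ratio = er$odds_ratio,
                                     p_value = er$p_value)
    }
    if (length(enr_rows)) {
      write_tsv(do.call(rbind, enr_rows),
                file.path(out, "feature_enrichment.tsv"))
    }

    # cross-reference of property leads with guQTLs
    if (!is.null(prop_assoc[[p0]])) {
      xref <- property_guqtl_overlap(prop_assoc[[p0]], assoc[[p0]])
      write_tsv(xref, file.path(out, "cdr3_guqtl_overlap.tsv"))
      result$property_overlap <- xref
    }

    # ---- stage: partition comparison ------------------------------------
    if (all(c("unmutated", "mutated") %in% names(assoc))) {
      stage <- "compare"
      cmp <- compare_partitions(assoc$unmutated, assoc$mutated)
      write_tsv(cmp$per_gene, file.path(out, "partition_comparison.tsv"))
      result$comparison <- cmp
      note("compare: %d genes significant in both partitions",
           cmp$n_both_significant)
    }

    # ---- manifest --------------------------------------------------------
    stage <- "manifest"
    files <- sort(setdiff(list.files(out, recursive = TRUE),
                          c("manifest.json", "run.log")))
    manifest <- list(seed = config$seed,
                     partitions = config$partitions,
                     thresholds = list(
                       maf_min = config$maf_min,
                       min_gene_count = config$min_gene_count,
                       min_sample_sequences = config$min_sample_sequences,
                       alpha = config$alpha),
                     files = files)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(out, "run.log"))
  }, error = function(e) {
    writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s", stage,
                                    conditionMessage(e))),
               file.path(out, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Compare guQTL results between repertoire partitions
#'
#' Per-gene table of lead p-value and adjusted R-squared in each partition,
#' counts of genes significant in both, and the direction of the paired
#' difference (genetic effects are expected to be stronger in the unmutated,
#' naive-enriched repertoire).
#'
#' @param results_unmutated,results_mutated outputs of [run_guqtl()].
#' @return list with `per_gene` (data.table), `n_both_significant`,
#'   `genes_both`, `mean_lead_r2` per partition.
#' @export
compare_partitions <- function(results_unmutated, results_mutated) {
  lead_tab <- function(res, suffix) {
    r <- res$results
    leads <- r[r$is_lead, , drop = FALSE]
    leads <- leads[order(leads$trait, leads$position, leads$variant_id)]
    leads <- leads[!duplicated(leads$trait)]
    sig_genes <- unique(r$trait[r$significant])
    out <- data.table::data.table(trait = leads$trait,
                                  p = leads$p_value,
                                  adj_r2 = leads$adjusted_r2,
                                  significant = leads$trait %in% sig_genes)
    data.table::setnames(out, c("p", "adj_r2", "significant"),
                         paste0(c("p_", "adj_r2_", "significant_"), suffix))
    out
  }
  tu <- lead_tab(results_unmutated, "unmutated")
  tm <- lead_tab(results_mutated, "mutated")
  per_gene <- merge(tu, tm, by = "trait", all = FALSE)
  if (!nrow(per_gene)) {
    warning("no genes shared between partitions")
  }
  both <- per_gene$trait[per_gene$significant_unmutated &
                           per_gene$significant_mutated]
  list(per_gene = per_gene,
       n_both_significant = length(both),
       genes_both = both,
       mean_lead_r2 = c(
         unmutated = mean(per_gene$adj_r2_unmutated),
         mutated = mean(per_gene$adj_r2_mutated)))
}
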