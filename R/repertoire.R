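# AIRR rearrangement ingestion, paralog-ambiguity collapsing, mutation
# partitioning, usage matrices and CDR3 property means.

AIRR_REQUIRED <- c("sequence_id", "v_call", "j_call", "junction_aa",
                   "v_identity", "j_identity")

#' Default paralog ambiguity map
#'
#' IGK proximal/distal paralog pairs whose allele sequences cannot be told
#' apart are collapsed to a single "ambi" analysis unit, and IGLJ gene calls
#' corresponding to an IGLJ2 or IGLJ3 cassette are collapsed to
#' \code{IGLJ2-3ambi}.
#'
#' @return data.frame with columns `member` (gene name as it appears in
#'   rearrangement calls) and `collapsed` (the ambi name it maps to).
#' @export
default_ambiguity_map <- function() {
  kv <- c("IGKV1-37", "IGKV1-39", "IGKV2-40", "IGKV1-33", "IGKV2-28")
  kvd <- sub("^(IGKV[0-9]+)-", "\\1D-", kv)
  lj <- c("IGLJ2", "IGLJ3-1", "IGLJ3-2", "IGLJ3-3", "IGLJ3-4")
  data.frame(
    member = c(kv, kvd, lj),
    collapsed = c(paste0(kv, "ambi"), paste0(kv, "ambi"),
                  rep("IGLJ2-3ambi", length(lj))),
    stringsAsFactors = FALSE
  )
}

#' Load AIRR rearrangement tables
#'
#' Reads one tab-separated AIRR Rearrangement file per sample. Each file must
#' carry the MiAIRR columns `sequence_id, v_call, j_call, junction_aa,
#' v_identity, j_identity`; rows with missing v_call/j_call/junction_aa or
#' identities outside \[0, 1\] are dropped with a warning that reports the
#' count.
#'
#' @param paths character vector of file paths.
#' @param sample_ids sample identifier per file; defaults to the file base
#'   name without extension.
#' @return data.table of rearrangement records with a `sample_id` column.
#' @export
load_rearrangements <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  stopifnot(length(paths) == length(sample_ids))
  recs <- vector("list", length(paths))
  n_bad <- 0L
  for (i in seq_along(paths)) {
    dt <- data.table::fread(paths[i], sep = "\t", header = TRUE,
                            colClasses = list(character = "junction_aa"),
                            na.strings = c("", "NA"))
    missing_cols <- setdiff(AIRR_REQUIRED, names(dt))
    if (length(missing_cols)) {
      stop("file ", paths[i], " lacks required column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    dt <- dt[, AIRR_REQUIRED, with = FALSE]
    dt[, `:=`(v_identity = as.numeric(v_identity),
              j_identity = as.numeric(j_identity))]
    ok <- !is.na(dt$v_call) & !is.na(dt$j_call) & !is.na(dt$junction_aa) &
      !is.na(dt$v_identity) & !is.na(dt$j_identity) &
      dt$v_identity >= 0 & dt$v_identity <= 1 &
      dt$j_identity >= 0 & dt$j_identity <= 1
    n_bad <- n_bad + sum(!ok)
    dt <- dt[ok]
    if (nrow(dt)) dt[, sample_id := sample_ids[i]]
    recs[[i]] <- dt
  }
  out <- data.table::rbindlist(recs[vapply(recs, nrow, 1L) > 0L])
  if (n_bad > 0L) warning(n_bad, " malformed record(s) skipped")
  if (!nrow(out)) {
    out <- data.table::data.table(
      sequence_id = character(), v_call = character(), j_call = character(),
      junction_aa = character(), v_identity = numeric(),
      j_identity = numeric(), sample_id = character())
  }
  data.table::setcolorder(out, c("sample_id", AIRR_REQUIRED))
  out[]
}

# Strip the allele suffix from a V/J call ("IGKV1-39*01" -> "IGKV1-39").
call_gene <- function(calls) sub("\\*.*$", "", calls)

#' Collapse indistinguishable paralogs to ambi units
#'
#' Rewrites the gene portion of `v_call`/`j_call` according to an ambiguity
#' map, preserving the allele suffix (`IGKV1-39*01` becomes
#' `IGKV1-39ambi*01`). Genes absent from the map pass through unchanged; the
#' operation is idempotent.
#'
#' @param records rearrangement data.table from [load_rearrangements()].
#' @param map data.frame with columns `member`, `collapsed`
#'   (default [default_ambiguity_map()]).
#' @return records with rewritten calls.
#' @export
collapse_ambiguous_genes <- function(records, map = default_ambiguity_map()) {
  records <- data.table::copy(data.table::as.data.table(records))
  rewrite <- function(calls) {
    gene <- call_gene(calls)
    suffix <- substr(calls, nchar(gene) + 1L, nchar(calls))
    idx <- match(gene, map$member)
    hit <- !is.na(idx)
    gene[hit] <- map$collapsed[idx[hit]]
    paste0(gene, suffix)
  }
  records[, `:=`(v_call = rewrite(v_call), j_call = rewrite(j_call))]
  records[]
}

#' Can a proximal/distal paralog pair be told apart in one sample?
#'
#' A pair is disambiguable for a sample when every allele sequence of the
#' proximal gene differs from every allele sequence of the distal gene, i.e.
#' the two diploid allele-sequence sets are disjoint.
#'
#' @param proximal,distal character vectors of allele sequences carried by
#'   the sample for each gene; `NULL` or empty means the gene's alleles are
#'   unknown for this sample.
#' @return `"disambiguable"`, `"ambiguous"`, or `"unknown"` when either set
#'   is missing.
#' @export
assess_paralog_disambiguation <- function(proximal, distal) {
  if (is.null(proximal) || is.null(distal) ||
      length(proximal) == 0L || length(distal) == 0L) {
    return("unknown")
  }
  if (length(intersect(proximal, distal)) > 0L) "ambiguous" else "disambiguable"
}

#' Partition rearrangements by mutation status
#'
#' Unmutated sequences match their assigned germline V and J alleles with
#' 100% identity (`v_identity == 1` and `j_identity == 1`); everything else
#' is mutated (somatic hypermutation in V, J, or both). The partition is
#' exhaustive and disjoint over valid records.
#'
#' @param records rearrangement data.table.
#' @return list with elements `unmutated` and `mutated`.
#' @export
partition_by_mutation <- function(records) {
  records <- data.table::as.data.table(records)
  if (any(records$v_identity < 0 | records$v_identity > 1 |
          records$j_identity < 0 | records$j_identity > 1, na.rm = TRUE)) {
    stop("identity values outside [0, 1]")
  }
  unm <- records$v_identity == 1 & records$j_identity == 1
  list(unmutated = records[unm], mutated = records[!unm])
}

#' Compute a gene usage matrix
#'
#' For each retained sample, usage frequency of a gene is its sequence count
#' divided by the sample's total sequence count in the partition. Samples
#' with fewer than `min_sample_sequences` sequences are dropped; genes are
#' retained only if their count reaches `min_gene_count` in at least one
#' retained sample. Frequencies are relative to the full per-sample partition
#' total and are not renormalized after the gene filter.
#'
#' @param records rearrangement records of one partition (already collapsed).
#' @param partition_label `"unmutated"` or `"mutated"` (stored, not checked
#'   against identities).
#' @param axis count V genes (`"V"`, from `v_call`) or J genes (`"J"`).
#' @param min_gene_count per-gene retention threshold (default 10).
#' @param min_sample_sequences per-sample retention threshold (default 100).
#' @return object of class `usage_matrix`: list with `genes`, `samples`,
#'   `values` (m genes x n samples frequencies), `counts`, `totals`,
#'   `partition`, `axis`.
#' @export
compute_usage_matrix <- function(records, partition_label = "unmutated",
                                 axis = c("V", "J"),
                                 min_gene_count = 10L,
                                 min_sample_sequences = 100L) {
  axis <- match.arg(axis)
  records <- data.table::as.data.table(records)
  gene <- call_gene(if (axis == "V") records$v_call else records$j_call)
  dt <- data.table::data.table(sample_id = records$sample_id, gene = gene)
  totals <- dt[, .N, by = sample_id]
  keep_samples <- totals[N >= min_sample_sequences, sample_id]
  if (!length(keep_samples)) stop("no samples pass the sequence-count filter")
  dt <- dt[sample_id %in% keep_samples]
  counts <- dt[, .N, by = .(gene, sample_id)]
  cnt <- as.matrix(data.table::dcast(counts, gene ~ sample_id,
                                     value.var = "N", fill = 0L),
                   rownames = "gene")
  tot <- setNames(totals$N, totals$sample_id)[colnames(cnt)]
  keep_genes <- apply(cnt, 1L, max) >= min_gene_count
  vals <- sweep(cnt, 2L, tot, "/")
  structure(list(
    genes = rownames(cnt)[keep_genes],
    samples = colnames(cnt),
    values = vals[keep_genes, , drop = FALSE],
    counts = cnt[keep_genes, , drop = FALSE],
    totals = tot,
    all_values = vals,
    partition = partition_label,
    axis = axis
  ), class = "usage_matrix")
}

#' @export
print.usage_matrix <- function(x, ...) {
  cat(sprintf("usage_matrix: %d %s genes x %d samples (%s partition)\n",
              length(x$genes), x$axis, length(x$samples), x$partition))
  invisible(x)
}

#' Sample-level CDR3 physicochemical property means
#'
#' The CDR3 is the junction with its first and last residue trimmed (the
#' conserved flanking cysteine and phenylalanine/tryptophan). Per-sequence
#' properties (see [peptide_properties()]) are averaged per sample, one vote
#' per unique sequence. Sequences whose trimmed CDR3 is empty or carries
#' non-standard residues are excluded from the means; samples with zero
#' eligible sequences get `NA` rows.
#'
#' @param records rearrangement records of one partition.
#' @param partition_label stored partition tag.
#' @param ph pH for the net-charge computation.
#' @return data.frame: one row per sample, columns `sample_id`,
#'   `n_sequences` (eligible count) and the nine property means.
#' @export
compute_cdr3_properties <- function(records, partition_label = "unmutated",
                                    ph = 7.4) {
  records <- data.table::as.data.table(records)
  junction <- records$junction_aa
  cdr3 <- ifelse(nchar(junction) >= 3L,
                 substr(junction, 2L, nchar(junction) - 1L), "")
  props <- peptide_properties(cdr3, ph = ph)
  props$sample_id <- records$sample_id
  eligible <- !is.na(props$gravy)
  pd <- data.table::as.data.table(props[eligible, ])
  prop_cols <- c("length", "gravy", "bulk", "aliphatic", "polarity",
                 "charge", "acidic", "basic", "aromatic")
  means <- pd[, c(list(n_sequences = .N),
                  lapply(.SD, mean)), by = sample_id, .SDcols = prop_cols]
  all_samples <- unique(records$sample_id)
  out <- merge(data.table::data.table(sample_id = all_samples), means,
               by = "sample_id", all.x = TRUE, sort = TRUE)
  out[is.na(n_sequences), n_sequences := 0L]
  attr(out, "partition") <- partition_label
  out[]
}
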