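# Cohort variant genotypes: VCF ingestion, common-variant filtering and
# feature annotation. Internal coordinates are 1-based inclusive; BED input
# is converted at the boundary.

#' Load cohort variants from a multi-sample VCF
#'
#' Parses a VCF v4.2 with GT fields via \pkg{vcfR}. Multiallelic records are
#' split into biallelic records (one per alternate allele; genotypes are
#' recoded against that allele). Dosage is the per-sample count of the
#' alternate allele; phase is retained when GT uses `|`. Records with ALT
#' `<DEL>` (or an `SVTYPE` INFO key) are typed `SV`, everything else `SNV`.
#'
#' @param vcf_path path to an uncompressed or bgzipped VCF.
#' @return object of class `variant_set`: list with `variants` (data.frame
#'   id, pos, type, ref, alt, maf, annotation), `dosage` (variants x samples,
#'   NA for missing genotypes), `hap1`/`hap2` (NA where unphased or missing),
#'   `phased` (logical per variant: all non-missing GTs phased), `samples`.
#' @export
load_variants <- function(vcf_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  rows <- list()
  id_seen <- character(0)
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      id <- fix$ID[i]
      if (is.na(id) || id == ".") id <- paste0(fix$CHROM[i], ":", fix$POS[i])
      if (length(alts) > 1L) id <- paste0(id, "_alt", k)
      if (id %in% id_seen) id <- paste0(id, "_dup")
      id_seen <- c(id_seen, id)
      is_sv <- grepl("^<", alts[k]) ||
        (!is.na(fix$INFO[i]) && grepl("SVTYPE=", fix$INFO[i], fixed = TRUE))
      g <- gt[i, ]
      phased_gt <- grepl("|", g, fixed = TRUE)
      parts <- strsplit(g, "[/|]")
      a1 <- suppressWarnings(as.integer(vapply(parts, function(p)
        if (length(p) >= 1L) p[1] else NA_character_, "")))
      a2 <- suppressWarnings(as.integer(vapply(parts, function(p)
        if (length(p) >= 2L) p[2] else NA_character_, "")))
      # recode against alternate allele k
      d1 <- as.integer(a1 == k)
      d2 <- as.integer(a2 == k)
      rows[[length(rows) + 1L]] <- list(
        id = id, pos = as.integer(fix$POS[i]),
        type = if (is_sv) "SV" else "SNV",
        ref = fix$REF[i], alt = alts[k],
        d1 = d1, d2 = d2, phased = phased_gt)
    }
  }
  nv <- length(rows)
  dosage <- matrix(NA_integer_, nv, length(samples),
                   dimnames = list(vapply(rows, `[[`, "", "id"), samples))
  hap1 <- dosage
  hap2 <- dosage
  phased <- logical(nv)
  for (i in seq_len(nv)) {
    r <- rows[[i]]
    dosage[i, ] <- r$d1 + r$d2
    ok <- !is.na(r$d1) & !is.na(r$d2)
    phased[i] <- all(r$phased[ok]) && any(ok)
    hap1[i, ok & r$phased] <- r$d1[ok & r$phased]
    hap2[i, ok & r$phased] <- r$d2[ok & r$phased]
  }
  vars <- data.frame(
    id = vapply(rows, `[[`, "", "id"),
    pos = vapply(rows, `[[`, 1L, "pos"),
    type = vapply(rows, `[[`, "", "type"),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    stringsAsFactors = FALSE)
  vars$maf <- apply(dosage, 1L, dosage_maf)
  vars$annotation <- "intergenic"
  structure(list(variants = vars, dosage = dosage, hap1 = hap1, hap2 = hap2,
                 phased = phased, samples = samples),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variants (%d SNV, %d SV) x %d samples\n",
              nrow(x$variants), sum(x$variants$type == "SNV"),
              sum(x$variants$type == "SV"), length(x$samples)))
  invisible(x)
}

# minor allele frequency from a dosage vector (NA-tolerant)
dosage_maf <- function(d) {
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}

#' Build a variant_set from a simulated genotype_set
#'
#' Converts simulator output (SNV haplotype matrices plus SV deletion
#' carriers) into the `variant_set` container used by the association and LD
#' machinery, without a VCF round trip.
#'
#' @param geno a `genotype_set` from [simulate_cohort_genotypes()].
#' @return a `variant_set` (SVs coded as alternate-allele dosage of the
#'   deletion).
#' @export
as_variant_set <- function(geno) {
  stopifnot(inherits(geno, "genotype_set"))
  vars <- geno$variants
  dosage <- geno$dosage
  hap1 <- geno$hap1
  hap2 <- geno$hap2
  if (nrow(geno$svs)) {
    sv_vars <- data.frame(id = geno$svs$sv_id, pos = geno$svs$start,
                          type = "SV", ref = "N", alt = "<DEL>",
                          stringsAsFactors = FALSE)
    vars <- rbind(vars[, c("id", "pos", "type", "ref", "alt")], sv_vars)
    dosage <- rbind(dosage, geno$sv_hap1 + geno$sv_hap2)
    hap1 <- rbind(hap1, geno$sv_hap1)
    hap2 <- rbind(hap2, geno$sv_hap2)
  }
  ord <- order(vars$pos)
  vars <- vars[ord, ]
  vars$maf <- apply(dosage[ord, , drop = FALSE], 1L, dosage_maf)
  vars$annotation <- "intergenic"
  structure(list(variants = vars, dosage = dosage[ord, , drop = FALSE],
                 hap1 = hap1[ord, , drop = FALSE],
                 hap2 = hap2[ord, , drop = FALSE],
                 phased = rep(TRUE, nrow(vars)), samples = geno$samples),
            class = "variant_set")
}

#' Filter to common variants
#'
#' Retains variants with minor allele frequency at or above `maf_min`
#' (default 5%), SNVs and SVs alike. All-missing variants are removed with a
#' warning.
#'
#' @param vs a `variant_set`.
#' @param maf_min MAF threshold.
#' @return filtered `variant_set`.
#' @export
filter_common <- function(vs, maf_min = 0.05) {
  stopifnot(inherits(vs, "variant_set"))
  missing_all <- is.na(vs$variants$maf)
  if (any(missing_all)) {
    warning(sum(missing_all), " all-missing variant(s) removed")
  }
  keep <- !missing_all & vs$variants$maf >= maf_min
  subset_variant_set(vs, keep)
}

subset_variant_set <- function(vs, keep) {
  structure(list(variants = vs$variants[keep, , drop = FALSE],
                 dosage = vs$dosage[keep, , drop = FALSE],
                 hap1 = vs$hap1[keep, , drop = FALSE],
                 hap2 = vs$hap2[keep, , drop = FALSE],
                 phased = vs$phased[keep], samples = vs$samples),
            class = "variant_set")
}

#' Read a BED file of feature intervals
#'
#' BED is 0-based half-open; intervals are converted to 1-based inclusive.
#' The name column (4th) carries the feature class.
#'
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `feature`.
#' @export
read_feature_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("feature BED needs a name column")
  data.frame(chrom = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
             feature = bed[[4]], stringsAsFactors = FALSE)
}

# most specific feature wins when intervals of different classes overlap
FEATURE_PRECEDENCE <- c("RSS-heptamer", "RSS-nonamer", "RSS-spacer",
                        "L-Part1", "V-exon", "intron")

#' Annotate variants by containing feature
#'
#' Labels each variant with the feature class of the interval containing its
#' position; positions in no interval are `intergenic`. Where intervals of
#' different classes overlap a position, the most specific class wins
#' (RSS motifs, then leader, exon, intron).
#'
#' @param vs a `variant_set`.
#' @param features data.frame from [read_feature_bed()], or a BED path.
#' @return `variant_set` with the `annotation` column filled in.
#' @export
annotate_variants <- function(vs, features) {
  stopifnot(inherits(vs, "variant_set"))
  if (is.character(features)) features <- read_feature_bed(features)
  ann <- rep("intergenic", nrow(vs$variants))
  pos <- vs$variants$pos
  prec <- c(FEATURE_PRECEDENCE,
            setdiff(unique(features$feature), FEATURE_PRECEDENCE))
  rank <- match(features$feature, prec)
  best <- rep(Inf, length(pos))
  for (i in seq_len(nrow(features))) {
    hit <- pos >= features$start[i] & pos <= features$end[i] &
      rank[i] < best
    ann[hit] <- features$feature[i]
    best[hit] <- rank[i]
  }
  vs$variants$annotation <- ann
  vs
}
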