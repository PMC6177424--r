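## Step 1 of the workflow: catalog SNPs overlapping miRNA seeds, miRNA
## binding sites and length-filtered lincRNA genes.

#' Length-filter lincRNA intervals
#'
#' Keeps a lincRNA interval iff its length (end - start in 0-based half-open
#' coordinates, i.e. `width()` of the internal `GRanges`) is strictly greater
#' than `min_len` and strictly less than `max_len`; boundary lengths are
#' excluded. Non-lincRNA intervals pass through unchanged. Idempotent.
#'
#' @param features feature `GRanges` (see [featureIntervals()]).
#' @param min_len,max_len length bounds in bases (defaults 200 and 100000).
#' @return The filtered feature `GRanges`.
#' @export
filterLincrnas <- function(features, min_len = 200, max_len = 100000) {
  if (min_len >= max_len) stop("min_len must be < max_len")
  cls <- S4Vectors::mcols(features)$feature_class
  len <- GenomicRanges::width(features)
  keep <- cls != "lincrna" | (len > min_len & len < max_len)
  features[keep]
}

#' Map SNPs to feature intervals
#'
#' A SNP at VCF position `pos` occupies the single base `[pos-1, pos)` and
#' maps to every same-chromosome interval containing that base. Overlap is
#' computed with `GenomicRanges::findOverlaps`; feature strand is ignored.
#' The result is independent of input order (sorted by snp then feature id)
#' and per-class match counts are reported via `message()`.
#'
#' @param genotypes a [GenotypeData-class] object (or anything with
#'   [variantInfo()]-compatible row ranges).
#' @param features feature `GRanges`.
#' @return data.table with columns `snp_id`, `feature_id`, `feature_class`,
#'   `target_gene`, `mirna_family`; one row per (SNP, interval) overlap,
#'   unique on (`snp_id`, `feature_id`).
#' @export
mapSnpsToFeatures <- function(genotypes, features) {
  snps <- SummarizedExperiment::rowRanges(genotypes)
  hits <- GenomicRanges::findOverlaps(snps, features, ignore.strand = TRUE)
  mc <- S4Vectors::mcols(features)
  out <- data.table::data.table(
    snp_id = names(snps)[S4Vectors::queryHits(hits)],
    feature_id = mc$feature_id[S4Vectors::subjectHits(hits)],
    feature_class = mc$feature_class[S4Vectors::subjectHits(hits)],
    target_gene = mc$target_gene[S4Vectors::subjectHits(hits)],
    mirna_family = mc$mirna_family[S4Vectors::subjectHits(hits)]
  )
  out <- unique(out, by = c("snp_id", "feature_id"))
  data.table::setorder(out, snp_id, feature_id)
  if (nrow(out)) {
    tab <- table(out$feature_class)
    message("SNP-feature catalog: ",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  out[]
}
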