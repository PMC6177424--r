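## Pairwise linkage disequilibrium from unphased dosages: composite
## (genotypic) R-squared, i.e. the squared Pearson correlation of dosage
## vectors, which agrees with haplotypic r2 under Hardy-Weinberg equilibrium.

#' LD R-squared between two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete samples. Symmetric and
#' invariant under allele flip (`d -> 2 - d`) of either vector. Undefined
#' (`NA`) when fewer than 2 complete pairs remain or either vector is
#' constant.
#'
#' @param dosage_a,dosage_b paired dosage vectors over the same samples.
#' @return list with `r2` and `n_used`.
#' @export
ldR2 <- function(dosage_a, dosage_b) {
  stopifnot(length(dosage_a) == length(dosage_b))
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]
  b <- dosage_b[ok]
  n <- length(a)
  if (n < 2L || stats::var(a) == 0 || stats::var(b) == 0)
    return(list(r2 = NA_real_, n_used = n))
  list(r2 = stats::cor(a, b)^2, n_used = n)
}

#' Enumerate high-LD partners of target SNPs
#'
#' Finds every pair (target, other variant) with `r2 >= threshold`
#' (inclusive), optionally restricted to a basepair window around the target
#' on the same chromosome. Pairs are returned once, in canonical order
#' (`snp_a < snp_b` lexicographically), with no self-pairs; pairs with
#' undefined LD (constant vector) are skipped.
#'
#' @param target_snps character vector of variant ids present in `genotypes`.
#' @param genotypes a [GenotypeData-class] object.
#' @param threshold minimum R-squared (inclusive; default 0.8).
#' @param window optional basepair distance limit (`NULL` = genome-wide).
#' @return data.table with columns `snp_a`, `snp_b`, `r2`, `n_used`.
#' @export
ldPartners <- function(target_snps, genotypes, threshold = 0.8, window = NULL) {
  d <- dosageMatrix(genotypes)
  vi <- variantInfo(genotypes)
  unknown <- setdiff(target_snps, rownames(d))
  if (length(unknown))
    stop("unknown target SNP id(s): ",
         paste(utils::head(unknown), collapse = ", "))
  target_snps <- unique(target_snps)
  empty <- data.table::data.table(snp_a = character(), snp_b = character(),
                                  r2 = numeric(), n_used = integer())
  if (nrow(d) < 2L) return(empty)
  pos <- stats::setNames(vi$pos, vi$id)
  chrom <- stats::setNames(vi$chrom, vi$id)
  res <- list()
  for (tg in target_snps) {
    others <- setdiff(rownames(d), tg)
    if (!is.null(window))
      others <- others[chrom[others] == chrom[tg] &
                         abs(pos[others] - pos[tg]) <= window]
    for (ot in others) {
      ld <- ldR2(d[tg, ], d[ot, ])
      if (!is.na(ld$r2) && ld$r2 >= threshold) {
        pair <- sort(c(tg, ot))
        res[[paste(pair, collapse = "\r")]] <- data.table::data.table(
          snp_a = pair[1], snp_b = pair[2], r2 = ld$r2,
          n_used = as.integer(ld$n_used)
        )
      }
    }
  }
  if (!length(res)) return(empty)
  out <- data.table::rbindlist(res)
  data.table::setorder(out, snp_a, snp_b)
  out[]
}
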