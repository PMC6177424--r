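## Step 3 of the workflow: select eQTL of clinical/pharmacological interest by
## direct rsid match against annotation catalogs, and indirectly through
## high-LD proxy SNPs. Matching is by (lowercased) rsid only; trait/gene
## strings are payload, never join keys.

.emptyHits <- function() {
  data.table::data.table(
    snp_id = character(), gene_id = character(), tissue = character(),
    p_adj = numeric(), source = character(), trait_or_drug = character(),
    ann_gene = character(), mode = character(), proxy_snp = character(),
    r2 = numeric()
  )
}

.normAnn <- function(annotations) {
  ann <- data.table::as.data.table(annotations)
  ann$snp_id <- tolower(ann$snp_id)
  ann
}

#' Direct clinical join
#'
#' One hit per (significant eQTL, annotation row) pair sharing an rsid;
#' duplicates across tissues are preserved as separate hits.
#'
#' @param eqtls data.frame of significant eQTL (columns `snp_id`, `gene_id`,
#'   `tissue`, `p_adj`; pre-filtered to significant).
#' @param annotations annotation table (internal schema, see
#'   [readAnnotations()]).
#' @return data.table of clinical hits with `mode = "direct"` and empty proxy
#'   fields.
#' @export
directJoin <- function(eqtls, annotations) {
  eq <- data.table::as.data.table(eqtls)
  ann <- .normAnn(annotations)
  if (nrow(eq) == 0L || nrow(ann) == 0L) return(.emptyHits())
  eq$snp_id <- tolower(eq$snp_id)
  m <- merge(eq[, c("snp_id", "gene_id", "tissue", "p_adj")],
             ann[, c("snp_id", "source", "trait_or_drug", "gene")],
             by = "snp_id", allow.cartesian = TRUE)
  if (nrow(m) == 0L) return(.emptyHits())
  out <- data.table::data.table(
    snp_id = m$snp_id, gene_id = m$gene_id, tissue = m$tissue,
    p_adj = m$p_adj, source = m$source, trait_or_drug = m$trait_or_drug,
    ann_gene = m$gene, mode = "direct", proxy_snp = NA_character_,
    r2 = NA_real_
  )
  data.table::setorder(out, snp_id, gene_id, trait_or_drug)
  unique(out)
}

#' LD-mediated clinical join
#'
#' A hit is produced whenever a significant eQTL's SNP is in high LD
#' (`r2 >= threshold`) with an annotated SNP other than itself; the annotated
#' partner is recorded as `proxy_snp` with its `r2`. An annotated SNP that is
#' itself the eQTL SNP is reported only by [directJoin()], never as its own
#' proxy.
#'
#' @inheritParams directJoin
#' @param ld_pairs data.table from [ldPartners()] (canonical `snp_a < snp_b`).
#' @param threshold minimum R-squared (inclusive; default 0.8).
#' @return data.table of clinical hits with `mode = "ld"`.
#' @export
ldJoin <- function(eqtls, annotations, ld_pairs, threshold = 0.8) {
  eq <- data.table::as.data.table(eqtls)
  ann <- .normAnn(annotations)
  ld <- data.table::as.data.table(ld_pairs)
  if (nrow(eq) == 0L || nrow(ann) == 0L || nrow(ld) == 0L)
    return(.emptyHits())
  eq$snp_id <- tolower(eq$snp_id)
  ld <- ld[ld$r2 >= threshold, ]
  ## symmetrize: partner table keyed by the eQTL-side SNP
  part <- data.table::rbindlist(list(
    data.table::data.table(snp_id = tolower(ld$snp_a),
                           proxy_snp = tolower(ld$snp_b), r2 = ld$r2),
    data.table::data.table(snp_id = tolower(ld$snp_b),
                           proxy_snp = tolower(ld$snp_a), r2 = ld$r2)
  ))
  m <- merge(eq[, c("snp_id", "gene_id", "tissue", "p_adj")], part,
             by = "snp_id", allow.cartesian = TRUE)
  if (nrow(m) == 0L) return(.emptyHits())
  m <- merge(m, ann[, c("snp_id", "source", "trait_or_drug", "gene")],
             by.x = "proxy_snp", by.y = "snp_id", allow.cartesian = TRUE)
  m <- m[m$proxy_snp != m$snp_id, ]
  if (nrow(m) == 0L) return(.emptyHits())
  out <- data.table::data.table(
    snp_id = m$snp_id, gene_id = m$gene_id, tissue = m$tissue,
    p_adj = m$p_adj, source = m$source, trait_or_drug = m$trait_or_drug,
    ann_gene = m$gene, mode = "ld", proxy_snp = m$proxy_snp, r2 = m$r2
  )
  data.table::setorder(out, snp_id, gene_id, proxy_snp, trait_or_drug)
  unique(out)
}

#' Combined clinical hit set
#'
#' Union of [directJoin()] and [ldJoin()], deduplicated on (eQTL, annotation
#' row, mode).
#'
#' @inheritParams ldJoin
#' @return data.table of clinical hits.
#' @export
clinicalHits <- function(eqtls, annotations, ld_pairs, threshold = 0.8) {
  out <- data.table::rbindlist(list(
    directJoin(eqtls, annotations),
    ldJoin(eqtls, annotations, ld_pairs, threshold)
  ))
  unique(out)
}
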