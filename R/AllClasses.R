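#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData assays
NULL

## Edge relation vocabulary, serialized verbatim in SIF/GraphML exports.
NET_RELATIONS <- c("located_in", "located_in_sig_eQTL", "sig_eQTL",
                   "sig_associated_with", "associated_with", "regulated_by", "LD")

NET_ROLES <- c("snp", "gene", "mirna", "lincrna", "phenotype")

FEATURE_CLASSES <- c("mirna_seed", "mirna_binding_site", "lincrna")

## Endpoint contract per relation: allowed source roles / target roles.
.relationContract <- list(
  located_in          = list(from = "snp", to = c("gene", "mirna", "lincrna")),
  located_in_sig_eQTL = list(from = "snp", to = c("gene", "mirna", "lincrna")),
  sig_eQTL            = list(from = "snp", to = c("gene", "mirna", "lincrna")),
  sig_associated_with = list(from = "snp", to = "phenotype"),
  associated_with     = list(from = c("gene", "lincrna"), to = "phenotype"),
  regulated_by        = list(from = "gene", to = "mirna"),
  LD                  = list(from = "snp", to = "snp")
)

#' GenotypeData: alternative-allele dosages over a cohort
#'
#' Variants x samples matrix of alternative-allele dosages (0, 1, 2 or `NA`
#' for missing), stored as a `RangedSummarizedExperiment` whose row ranges
#' carry the variant coordinates (1-based, width-1) and `ref`/`alt` alleles.
#'
#' @slot .Data inherited `RangedSummarizedExperiment` with a single `"dosage"`
#'   assay.
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    ok <- is.na(d) | d %in% c(0, 1, 2)
    if (!all(ok)) msg <- c(msg, "dosage entries must be 0, 1, 2 or NA")
  }
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "variant ids must be present and unique")
  cn <- colnames(object)
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "sample ids must be present and unique")
  rr <- SummarizedExperiment::rowRanges(object)
  mc <- S4Vectors::mcols(rr)
  if (!all(c("ref", "alt") %in% colnames(mc)))
    msg <- c(msg, "rowRanges must carry 'ref' and 'alt' allele columns")
  else {
    if (any(nchar(mc$ref) != 1L) || any(nchar(mc$alt) != 1L))
      msg <- c(msg, "only single-nucleotide alleles are supported")
    if (any(mc$ref == mc$alt)) msg <- c(msg, "ref and alt alleles must differ")
  }
  if (length(rr) && any(GenomicRanges::start(rr) < 1L))
    msg <- c(msg, "variant positions must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ExpressionData: gene abundance over a cohort
#'
#' Genes x samples matrix of non-negative, RPKM-like abundances, stored as a
#' `SummarizedExperiment` with a single `"abundance"` assay.
#'
#' @export
setClass("ExpressionData", contains = "SummarizedExperiment")

setValidity("ExpressionData", function(object) {
  msg <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  else {
    a <- SummarizedExperiment::assay(object, "abundance")
    if (anyNA(a)) msg <- c(msg, "expression values must not be missing")
    else if (any(a < 0)) msg <- c(msg, "expression values must be non-negative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (length(msg)) msg else TRUE
})

#' AssociationNetwork: typed multi-graph over SNPs, genes, ncRNAs and phenotypes
#'
#' Nodes carry one of the roles `snp`, `gene`, `mirna`, `lincrna`, `phenotype`
#' (roles partition the node set). Edges carry one of the seven labeled
#' relations; each relation constrains the roles of its endpoints, `LD` edges
#' are undirected, stored once with lexicographically sorted endpoints, and
#' self-loops are forbidden.
#'
#' @slot nodes data.frame with columns `id`, `role`.
#' @slot edges data.frame with columns `from`, `to`, `relation`, `directed`.
#' @export
setClass("AssociationNetwork",
  representation(nodes = "data.frame", edges = "data.frame"),
  prototype(
    nodes = data.frame(id = character(), role = character(),
                       stringsAsFactors = FALSE),
    edges = data.frame(from = character(), to = character(),
                       relation = character(), directed = logical(),
                       stringsAsFactors = FALSE)
  )
)

setValidity("AssociationNetwork", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msg <- character()
  if (!all(c("id", "role") %in% colnames(nd)))
    msg <- c(msg, "nodes need columns 'id' and 'role'")
  if (!all(c("from", "to", "relation", "directed") %in% colnames(ed)))
    msg <- c(msg, "edges need columns 'from', 'to', 'relation', 'directed'")
  if (length(msg)) return(msg)
  if (anyDuplicated(nd$id))
    msg <- c(msg, "node roles must partition the node set (duplicate id)")
  if (!all(nd$role %in% NET_ROLES))
    msg <- c(msg, "unknown node role")
  if (!all(ed$relation %in% NET_RELATIONS))
    msg <- c(msg, "unknown edge relation")
  if (any(ed$from == ed$to))
    msg <- c(msg, "self-loops are forbidden")
  role <- stats::setNames(nd$role, nd$id)
  if (!all(ed$from %in% nd$id) || !all(ed$to %in% nd$id))
    msg <- c(msg, "edge references an undeclared node")
  else if (nrow(ed)) {
    for (rel in unique(ed$relation)) {
      ct <- .relationContract[[rel]]
      sel <- ed$relation == rel
      if (!all(role[ed$from[sel]] %in% ct$from) ||
          !all(role[ed$to[sel]] %in% ct$to))
        msg <- c(msg, sprintf("endpoint contract violated for relation '%s'", rel))
    }
    ld <- ed[ed$relation == "LD", , drop = FALSE]
    if (nrow(ld)) {
      if (any(ld$directed)) msg <- c(msg, "LD edges must be undirected")
      if (any(ld$from >= ld$to))
        msg <- c(msg, "LD edges must be stored once in canonical (sorted) order")
      if (anyDuplicated(paste(ld$from, ld$to)))
        msg <- c(msg, "duplicate LD edge")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenotypeData", function(object) {
  d <- SummarizedExperiment::assay(object, "dosage")
  cat(sprintf("GenotypeData: %d variants x %d samples (%.2f%% missing)\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
})

setMethod("show", "ExpressionData", function(object) {
  cat(sprintf("ExpressionData: %d genes x %d samples\n",
              nrow(object), ncol(object)))
})

setMethod("show", "AssociationNetwork", function(object) {
  cat(sprintf("AssociationNetwork: %d nodes, %d edges\n",
              nrow(object@nodes), nrow(object@edges)))
  if (nrow(object@nodes)) {
    tab <- table(object@nodes$role)
    cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (nrow(object@edges)) {
    tab <- table(object@edges$relation)
    cat("  relations:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})
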