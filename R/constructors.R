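#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix, variants x samples, entries 0/1/2 or `NA`;
#'   rownames are variant ids, colnames sample ids.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, one row per row of `dosage` (matched by `id`).
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)))
  variants <- as.data.frame(variants)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% colnames(variants)))
    stop("variants table needs columns: ", paste(need, collapse = ", "))
  if (!setequal(variants$id, rownames(dosage)))
    stop("variant ids do not match dosage rownames")
  variants <- variants[match(rownames(dosage), variants$id), ]
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(variants$chrom),
    ranges = IRanges::IRanges(start = variants$pos, width = 1L),
    ref = as.character(variants$ref), alt = as.character(variants$alt)
  )
  names(rr) <- variants$id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowRanges = rr
  )
  methods::new("GenotypeData", se)
}

#' Construct an ExpressionData object
#'
#' @param abundance numeric matrix, genes x samples, non-negative; rownames
#'   are gene ids, colnames sample ids.
#' @return An [ExpressionData-class] object.
#' @export
ExpressionData <- function(abundance) {
  stopifnot(is.matrix(abundance))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance)
  )
  methods::new("ExpressionData", se)
}

#' Construct an AssociationNetwork
#'
#' @param nodes data.frame with columns `id`, `role`.
#' @param edges data.frame with columns `from`, `to`, `relation`, `directed`.
#' @return An [AssociationNetwork-class] object; the validity method enforces
#'   role disjointness and the per-relation endpoint contracts.
#' @export
AssociationNetwork <- function(nodes = NULL, edges = NULL) {
  proto <- methods::new("AssociationNetwork")
  if (is.null(nodes)) nodes <- proto@nodes
  if (is.null(edges)) edges <- proto@edges
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  methods::new("AssociationNetwork", nodes = nodes, edges = edges)
}

#' @rdname GenotypeData
#' @param x a `GenotypeData` object.
#' @export
dosageMatrix <- function(x) {
  stopifnot(methods::is(x, "GenotypeData"))
  SummarizedExperiment::assay(x, "dosage")
}

#' @rdname GenotypeData
#' @export
variantInfo <- function(x) {
  stopifnot(methods::is(x, "GenotypeData"))
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(
    id = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = S4Vectors::mcols(rr)$ref,
    alt = S4Vectors::mcols(rr)$alt,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @rdname ExpressionData
#' @param x an `ExpressionData` object.
#' @export
exprMatrix <- function(x) {
  stopifnot(methods::is(x, "ExpressionData"))
  SummarizedExperiment::assay(x, "abundance")
}

#' @rdname AssociationNetwork
#' @param x an `AssociationNetwork` object.
#' @export
netNodes <- function(x) {
  stopifnot(methods::is(x, "AssociationNetwork"))
  x@nodes
}

#' @rdname AssociationNetwork
#' @export
netEdges <- function(x) {
  stopifnot(methods::is(x, "AssociationNetwork"))
  x@edges
}

#' Build a validated feature-interval set
#'
#' Feature intervals (miRNA seeds, miRNA-binding sites, lincRNA genes) are
#' represented as a `GRanges` with metadata columns `feature_id`,
#' `feature_class`, `target_gene` and `mirna_family`. Binding sites must carry
#' a target gene and a miRNA family; lincRNA intervals must not carry a target
#' gene.
#'
#' @param chrom,start,end interval coordinates, `start`/`end` 0-based
#'   half-open (BED convention); converted to the 1-based `GRanges`
#'   representation internally, so `width()` equals `end - start`.
#' @param feature_id unique interval identifiers.
#' @param feature_class one of `mirna_seed`, `mirna_binding_site`, `lincrna`.
#' @param strand `+`, `-` or `*`.
#' @param target_gene gene id for binding sites, `NA` otherwise.
#' @param mirna_family miRNA family for seeds/binding sites, `NA` otherwise.
#' @return A `GRanges` of validated feature intervals.
#' @export
featureIntervals <- function(chrom, start, end, feature_id, feature_class,
                             strand = "*", target_gene = NA_character_,
                             mirna_family = NA_character_) {
  n <- length(feature_id)
  target_gene <- rep_len(as.character(target_gene), n)
  mirna_family <- rep_len(as.character(mirna_family), n)
  strand <- rep_len(strand, n)
  strand[strand == "."] <- "*"
  if (any(start >= end)) stop("feature intervals must have start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = strand,
    feature_id = as.character(feature_id),
    feature_class = as.character(feature_class),
    target_gene = target_gene,
    mirna_family = mirna_family
  )
  validateFeatureIntervals(gr)
}

#' @rdname featureIntervals
#' @param gr a `GRanges` with feature metadata columns.
#' @export
validateFeatureIntervals <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  need <- c("feature_id", "feature_class", "target_gene", "mirna_family")
  if (!all(need %in% colnames(mc)))
    stop("feature intervals need metadata columns: ",
         paste(need, collapse = ", "))
  if (!all(mc$feature_class %in% FEATURE_CLASSES))
    stop("unknown feature_class; expected one of ",
         paste(FEATURE_CLASSES, collapse = ", "))
  blank <- function(x) is.na(x) | x == ""
  bs <- mc$feature_class == "mirna_binding_site"
  if (any(bs & (blank(mc$target_gene) | blank(mc$mirna_family))))
    stop("binding-site intervals need non-empty target_gene and mirna_family")
  li <- mc$feature_class == "lincrna"
  if (any(li & !blank(mc$target_gene)))
    stop("lincRNA intervals must have empty target_gene")
  gr
}
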