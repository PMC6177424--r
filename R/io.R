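## Readers/writers for every external format the pipeline touches. VCF is
## parsed with VariantAnnotation and written as a minimal GT-only v4.2 subset;
## tabular formats go through data.table with strict schema validation.
## Coordinates: VCF positions are 1-based; feature TSVs use BED-style 0-based
## half-open starts/ends, converted to GRanges on ingest.

#' @importFrom data.table fread fwrite data.table as.data.table setorder rbindlist setnames :=
NULL

#' Write genotypes as a minimal VCF v4.2
#'
#' GT-only, unphased ("0/1" style, "./." for missing).
#'
#' @param genotypes a [GenotypeData-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVcf <- function(genotypes, path) {
  vi <- variantInfo(genotypes)
  d <- dosageMatrix(genotypes)
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1], nrow = nrow(d))
  gt[is.na(d)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(d)), collapse = "\t")
  )
  body <- paste(vi$chrom, vi$pos, vi$id, vi$ref, vi$alt, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Parses unphased GT fields to alternative-allele dosages; `./.` becomes
#' missing. Multi-allelic or non-SNP records are rejected with a message
#' reporting how many were dropped.
#'
#' @param path a VCF file (v4.2, GT format field).
#' @return A [GenotypeData-class] object.
#' @export
readGenotypesVcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (ncol(vcf) == 0L) stop("VCF contains zero samples")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  nalt <- S4Vectors::elementNROWS(altl)
  alt <- rep(NA_character_, length(rr))
  alt[nalt == 1L] <- as.character(unlist(altl[nalt == 1L]))
  keep <- nalt == 1L & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    alt %in% c("A", "C", "G", "T")
  if (any(!keep))
    message(sum(!keep), " multi-allelic or non-SNP record(s) dropped")
  if (!any(keep)) stop("no biallelic SNP records in VCF")
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  if (is.null(gt)) stop("VCF has no GT genotype field")
  alleles <- gsub("\\|", "/", gt)
  dosage <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
  dosage[alleles == "0/0"] <- 0
  dosage[alleles %in% c("0/1", "1/0")] <- 1
  dosage[alleles == "1/1"] <- 2
  bad <- !(alleles %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(bad))
    stop("unparseable GT value(s): ",
         paste(utils::head(unique(alleles[bad])), collapse = ", "))
  variants <- data.frame(
    id = rownames(gt),
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref = ref[keep], alt = alt[keep], stringsAsFactors = FALSE
  )
  GenotypeData(dosage, variants)
}

.requireCols <- function(dt, cols, what) {
  miss <- setdiff(cols, colnames(dt))
  if (length(miss))
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(miss, collapse = ", ")))
  invisible(dt)
}

#' Read/write the expression matrix TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param path TSV file path.
#' @return [ExpressionData-class] for the reader; `path` invisibly for the
#'   writer.
#' @export
readExpressionTsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  .requireCols(dt, "gene_id", "expression table")
  if (ncol(dt) < 2L) stop("expression table has zero samples")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$gene_id
  if (anyNA(m) || any(m < 0))
    stop("expression values must be non-negative and non-missing")
  ExpressionData(m)
}

#' @rdname readExpressionTsv
#' @param expression an [ExpressionData-class] object.
#' @export
writeExpressionTsv <- function(expression, path) {
  m <- exprMatrix(expression)
  dt <- data.table::data.table(gene_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read/write feature intervals (BED6-derived TSV)
#'
#' Columns: `chrom`, `start`, `end` (0-based half-open), `feature_id`,
#' `score`, `strand`, `feature_class`, `target_gene`, `mirna_family`.
#'
#' @param path TSV file path.
#' @return Validated feature `GRanges` for the reader; `path` invisibly for
#'   the writer.
#' @export
readFeaturesTsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = c("NA", ""))
  .requireCols(dt, c("chrom", "start", "end", "feature_id", "strand",
                     "feature_class", "target_gene", "mirna_family"),
               "feature table")
  if (nrow(dt) == 0L)
    return(featureIntervals(character(), integer(), integer(), character(),
                            character()))
  if (any(dt$start >= dt$end)) stop("feature intervals must have start < end")
  featureIntervals(
    chrom = dt$chrom, start = dt$start, end = dt$end,
    feature_id = dt$feature_id, feature_class = dt$feature_class,
    strand = dt$strand, target_gene = as.character(dt$target_gene),
    mirna_family = as.character(dt$mirna_family)
  )
}

#' @rdname readFeaturesTsv
#' @param features a feature `GRanges` (see [featureIntervals()]).
#' @export
writeFeaturesTsv <- function(features, path) {
  mc <- S4Vectors::mcols(features)
  st <- as.character(GenomicRanges::strand(features))
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(features)),
    start = GenomicRanges::start(features) - 1L,
    end = GenomicRanges::end(features),
    feature_id = mc$feature_id,
    score = 0L,
    strand = ifelse(st == "*", ".", st),
    feature_class = mc$feature_class,
    target_gene = mc$target_gene,
    mirna_family = mc$mirna_family
  )
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read/write precomputed tissue-eQTL tables
#'
#' Columns: `snp_id`, `gene_id`, `tissue`, `slope`, `p`. Unknown extra
#' columns are preserved.
#'
#' @param path TSV file path.
#' @return data.table for the reader; `path` invisibly for the writer.
#' @export
readPrecomputedEqtl <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  .requireCols(dt, c("snp_id", "gene_id", "tissue", "slope", "p"),
               "precomputed eQTL table")
  if (nrow(dt)) {
    if (any(is.na(dt$tissue) | dt$tissue == ""))
      stop("precomputed eQTL table: tissue must be non-empty")
    if (any(dt$p < 0 | dt$p > 1))
      stop("precomputed eQTL table: p must be in [0, 1]")
  }
  dt[]
}

#' @rdname readPrecomputedEqtl
#' @param eqtl a data.frame with the precomputed-eQTL schema.
#' @export
writePrecomputedEqtlTsv <- function(eqtl, path) {
  data.table::fwrite(data.table::as.data.table(eqtl), path, sep = "\t")
  invisible(path)
}

#' Read/write clinical annotation catalogs
#'
#' Two layouts are supported: `gwas` (columns `snp_id`, `trait`,
#' `mapped_gene`, `pubmed_id`) and `pharmgkb` (columns `snp_id`, `gene`,
#' `drug`, `phenotype_category`). Both are normalized to the internal schema
#' `snp_id`, `source`, `trait_or_drug`, `gene`; extra columns are preserved.
#'
#' @param path TSV file path.
#' @param layout `"gwas"` or `"pharmgkb"`.
#' @return data.table in the internal annotation schema for the reader;
#'   `path` invisibly for the writer.
#' @export
readAnnotations <- function(path, layout = c("gwas", "pharmgkb")) {
  layout <- match.arg(layout)
  dt <- data.table::fread(path, sep = "\t", na.strings = c("NA", ""))
  if (layout == "gwas") {
    .requireCols(dt, c("snp_id", "trait", "mapped_gene"), "gwas annotations")
    out <- data.table::data.table(
      snp_id = tolower(dt$snp_id), source = "gwas",
      trait_or_drug = dt$trait, gene = as.character(dt$mapped_gene)
    )
  } else {
    .requireCols(dt, c("snp_id", "gene", "drug"), "pharmgkb annotations")
    out <- data.table::data.table(
      snp_id = tolower(dt$snp_id), source = "pharmgkb",
      trait_or_drug = dt$drug, gene = as.character(dt$gene)
    )
  }
  if (nrow(out) && any(is.na(out$snp_id) | out$snp_id == ""))
    stop("annotation table: snp_id must be non-empty")
  out[]
}

#' @rdname readAnnotations
#' @param annotations data.frame in the internal annotation schema
#'   (`snp_id`, `source`, `trait_or_drug`, `gene`); only rows matching
#'   `layout` are written.
#' @export
writeAnnotationsTsv <- function(annotations, path, layout = c("gwas", "pharmgkb")) {
  layout <- match.arg(layout)
  ann <- data.table::as.data.table(annotations)
  ann <- ann[ann$source == layout, ]
  if (layout == "gwas") {
    out <- data.table::data.table(
      snp_id = ann$snp_id, trait = ann$trait_or_drug,
      mapped_gene = ann$gene,
      pubmed_id = sprintf("PMID%07d", seq_len(nrow(ann)))
    )
  } else {
    out <- data.table::data.table(
      snp_id = ann$snp_id, gene = ann$gene, drug = ann$trait_or_drug,
      phenotype_category = "efficacy"
    )
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read both annotation layouts into one table
#'
#' @param gwas_path,pharmgkb_path file paths; either may be `NULL`.
#' @return data.table in the internal annotation schema.
#' @export
readAllAnnotations <- function(gwas_path = NULL, pharmgkb_path = NULL) {
  parts <- list()
  if (!is.null(gwas_path)) parts$gwas <- readAnnotations(gwas_path, "gwas")
  if (!is.null(pharmgkb_path))
    parts$pharmgkb <- readAnnotations(pharmgkb_path, "pharmgkb")
  if (!length(parts))
    return(data.table::data.table(snp_id = character(), source = character(),
                                  trait_or_drug = character(),
                                  gene = character()))
  data.table::rbindlist(parts, use.names = TRUE)[]
}

#' Export an association network
#'
#' SIF: one line per edge, `source<TAB>relation<TAB>target`; undirected LD
#' edges are emitted once with lexicographically sorted endpoints. GraphML:
#' node `role` and edge `relation`/`edge_directed` as attributes (readable by
#' Cytoscape and [readNetworkGraphml()]).
#'
#' @param net an [AssociationNetwork-class] object.
#' @param path output path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  ed <- netEdges(net)
  if (format == "sif") {
    lines <- if (nrow(ed))
      paste(ed$from, ed$relation, ed$to, sep = "\t") else character()
    writeLines(lines, path)
  } else {
    g <- asIgraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import a GraphML association network
#'
#' @param path a GraphML file written by [writeNetwork()].
#' @return An [AssociationNetwork-class] object.
#' @export
readNetworkGraphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name, role = igraph::V(g)$role,
                      stringsAsFactors = FALSE)
  if (igraph::ecount(g)) {
    el <- igraph::as_edgelist(g)
    edges <- data.frame(from = el[, 1], to = el[, 2],
                        relation = igraph::E(g)$relation,
                        directed = as.logical(igraph::E(g)$edge_directed),
                        stringsAsFactors = FALSE)
    ## restore canonical order for undirected LD edges
    ld <- edges$relation == "LD" & edges$from > edges$to
    tmp <- edges$from[ld]
    edges$from[ld] <- edges$to[ld]
    edges$to[ld] <- tmp
  } else {
    edges <- NULL
  }
  AssociationNetwork(nodes, edges)
}
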