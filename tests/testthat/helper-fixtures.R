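# Shared fixtures and independent oracles, all built in code.

# Quadratic all-pairs SNP-in-interval oracle (same chrom, pos-1 in [start,end)
# with BED coordinates, i.e. 1-based pos in [start+1, end]).
bruteForceOverlap <- function(variants, features) {
  mc <- S4Vectors::mcols(features)
  fchrom <- as.character(GenomicRanges::seqnames(features))
  fstart <- GenomicRanges::start(features) # 1-based inclusive
  fend <- GenomicRanges::end(features)
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    for (j in seq_along(features)) {
      if (variants$chrom[i] == fchrom[j] &&
          variants$pos[i] >= fstart[j] && variants$pos[i] <= fend[j]) {
        rows[[length(rows) + 1L]] <- data.frame(
          snp_id = variants$id[i], feature_id = mc$feature_id[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(snp_id = character(), feature_id = character()))
  out <- unique(do.call(rbind, rows))
  out[order(out$snp_id, out$feature_id), , drop = FALSE]
}

# Literal step-up definition of Benjamini-Hochberg: sort ascending,
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, mapped back.
stepUpBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Depth-first-search connected-components oracle on an undirected edge list.
dfsComponents <- function(node_ids, from, to) {
  adj <- stats::setNames(vector("list", length(node_ids)), node_ids)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj[[to[k]]] <- c(adj[[to[k]]], from[k])
  }
  comp <- stats::setNames(rep(NA_integer_, length(node_ids)), node_ids)
  cid <- 0L
  for (v in node_ids) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      stack <- c(stack, setdiff(adj[[u]], names(comp)[!is.na(comp)]))
    }
  }
  comp
}

# Toy inputs shaped like the miRNA association-network model: SNP s in the
# binding site of miRNA m within gene g, significant eQTL s->g, trait t on s
# (direct). Optionally an LD partner p with its own trait.
toyMirnaInputs <- function(with_ld_partner = FALSE) {
  hits <- data.frame(
    snp_id = "rs1", gene_id = "geneA", tissue = "", p_adj = 1e-6,
    source = "gwas", trait_or_drug = "traitX", ann_gene = NA_character_,
    mode = "direct", proxy_snp = NA_character_, r2 = NA_real_,
    stringsAsFactors = FALSE)
  catalog <- data.frame(
    snp_id = "rs1", feature_id = "site1", feature_class = "mirna_binding_site",
    target_gene = "geneA", mirna_family = "miR-1", stringsAsFactors = FALSE)
  eqtls <- data.frame(snp_id = "rs1", gene_id = "geneA", tissue = "",
                      p_adj = 1e-6, significant = TRUE,
                      stringsAsFactors = FALSE)
  annotations <- data.frame(snp_id = "rs1", source = "gwas",
                            trait_or_drug = "traitX", gene = NA_character_,
                            stringsAsFactors = FALSE)
  ld <- data.frame(snp_a = character(), snp_b = character(), r2 = numeric(),
                   n_used = integer(), stringsAsFactors = FALSE)
  if (with_ld_partner) {
    hits <- rbind(hits, data.frame(
      snp_id = "rs1", gene_id = "geneA", tissue = "", p_adj = 1e-6,
      source = "gwas", trait_or_drug = "traitY", ann_gene = NA_character_,
      mode = "ld", proxy_snp = "rs2", r2 = 0.9, stringsAsFactors = FALSE))
    annotations <- rbind(annotations, data.frame(
      snp_id = "rs2", source = "gwas", trait_or_drug = "traitY",
      gene = NA_character_, stringsAsFactors = FALSE))
    ld <- data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.9, n_used = 100L,
                     stringsAsFactors = FALSE)
  }
  list(hits = hits, catalog = catalog, eqtls = eqtls,
       annotations = annotations, ld = ld)
}

# Star network: one hub SNP with k eQTL-linked genes.
starNetwork <- function(k) {
  nodes <- data.frame(
    id = c("rs_hub", paste0("gene", seq_len(k))),
    role = c("snp", rep("gene", k)), stringsAsFactors = FALSE)
  edges <- data.frame(
    from = "rs_hub", to = paste0("gene", seq_len(k)), relation = "sig_eQTL",
    directed = TRUE, stringsAsFactors = FALSE)
  AssociationNetwork(nodes, edges)
}

# Path network: gene1 <- snp -> gene2 via two eQTL edges.
pathNetwork <- function() {
  nodes <- data.frame(id = c("rs_mid", "gene1", "gene2"),
                      role = c("snp", "gene", "gene"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = "rs_mid", to = c("gene1", "gene2"),
                      relation = "sig_eQTL", directed = TRUE,
                      stringsAsFactors = FALSE)
  AssociationNetwork(nodes, edges)
}

# Demo cohort used by the end-to-end tests.
demoConfig <- function(seed = 11L, n_haplotypes_per_block = 4L,
                       annotation_hit_rate = 1) {
  cohortConfig(
    n_samples = 200L, n_variants = 300L, n_genes = 50L,
    planted_effects = data.frame(variant = c(5L, 65L, 125L, 185L, 245L),
                                 gene = c(1L, 11L, 21L, 31L, 41L),
                                 beta = 0.8),
    noise_sd = 1, missing_rate = 0.02, feature_density = 0.5,
    annotation_hit_rate = annotation_hit_rate,
    n_haplotypes_per_block = n_haplotypes_per_block, seed = seed)
}
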