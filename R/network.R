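## Typed multi-graph association networks over SNP, gene, miRNA/lincRNA and
## phenotype nodes, their connected-component decomposition, and the iterative
## eQTL-knockout perturbation scan.

.addNode <- function(reg, id, role) {
  cur <- reg$roles[[id]]
  if (is.null(cur)) reg$roles[[id]] <- role
  else if (cur != role)
    stop(sprintf("node '%s' assigned conflicting roles '%s' and '%s'",
                 id, cur, role))
  invisible(NULL)
}

.buildNetwork <- function(hits, catalog, eqtls, annotations, ld_pairs,
                          model, ld_threshold = 0.8) {
  hits <- data.table::as.data.table(hits)
  catalog <- data.table::as.data.table(catalog)
  eqtls <- data.table::as.data.table(eqtls)
  annotations <- data.table::as.data.table(annotations)
  ld <- data.table::as.data.table(ld_pairs)
  if (nrow(hits) == 0L) return(AssociationNetwork())
  hits$snp_id <- tolower(hits$snp_id)
  catalog$snp_id <- tolower(catalog$snp_id)
  eqtls$snp_id <- tolower(eqtls$snp_id)
  annotations$snp_id <- tolower(annotations$snp_id)
  if (nrow(ld)) {
    ld$snp_a <- tolower(ld$snp_a)
    ld$snp_b <- tolower(ld$snp_b)
    ld <- ld[ld$r2 >= ld_threshold, ]
  }
  sigPairs <- if (nrow(eqtls) && "significant" %in% colnames(eqtls))
    paste(eqtls$snp_id[eqtls$significant], eqtls$gene_id[eqtls$significant])
  else character()
  ncClass <- if (model == "mirna") "mirna_binding_site" else "lincrna"
  cat_nc <- catalog[catalog$feature_class == ncClass, ]

  reg <- new.env()
  reg$roles <- list()
  edges <- list()
  addEdge <- function(from, to, relation, directed = TRUE) {
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, to = to, relation = relation, directed = directed,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    .addNode(reg, h$snp_id, "snp")
    .addNode(reg, h$gene_id, "gene")
    .addNode(reg, h$trait_or_drug, "phenotype")
    ## the hit's eQTL edge
    if (model == "mirna" &&
        nrow(cat_nc[cat_nc$snp_id == h$snp_id &
                    cat_nc$target_gene == h$gene_id, ]))
      addEdge(h$snp_id, h$gene_id, "located_in_sig_eQTL")
    else
      addEdge(h$snp_id, h$gene_id, "sig_eQTL")
    ## the annotation edge: on the SNP itself (direct) or on its LD proxy
    if (identical(h$mode, "direct")) {
      addEdge(h$snp_id, h$trait_or_drug, "sig_associated_with")
    } else {
      proxy <- tolower(h$proxy_snp)
      .addNode(reg, proxy, "snp")
      pair <- sort(c(h$snp_id, proxy))
      addEdge(pair[1], pair[2], "LD", directed = FALSE)
      addEdge(proxy, h$trait_or_drug, "sig_associated_with")
    }
  }
  snpNodes <- names(reg$roles)[unlist(reg$roles) == "snp"]
  geneNodes <- names(reg$roles)[unlist(reg$roles) == "gene"]

  ## catalog-driven edges for every SNP node (eQTL SNPs and proxies alike)
  cat_here <- cat_nc[cat_nc$snp_id %in% snpNodes, ]
  for (i in seq_len(nrow(cat_here))) {
    r <- cat_here[i, ]
    if (model == "mirna") {
      if (!r$target_gene %in% geneNodes) next
      ## gene regulated by the miRNA predicted to bind this site
      .addNode(reg, r$mirna_family, "mirna")
      addEdge(r$target_gene, r$mirna_family, "regulated_by")
      ## SNP located in the gene; folded into located_in_sig_eQTL when the
      ## pair is a significant eQTL (emitted above)
      if (!paste(r$snp_id, r$target_gene) %in% sigPairs)
        addEdge(r$snp_id, r$target_gene, "located_in")
    } else {
      .addNode(reg, r$feature_id, "lincrna")
      addEdge(r$snp_id, r$feature_id, "located_in")
    }
  }

  ## gene-phenotype associations reported by the catalogs
  if (nrow(annotations)) {
    blank <- is.na(annotations$gene) | annotations$gene == ""
    ga <- unique(annotations[!blank, c("gene", "trait_or_drug")])
    ga <- ga[ga$gene %in% geneNodes, ]
    for (i in seq_len(nrow(ga))) {
      .addNode(reg, ga$trait_or_drug[i], "phenotype")
      addEdge(ga$gene[i], ga$trait_or_drug[i], "associated_with")
    }
  }

  ## all high-LD edges among SNP nodes
  if (nrow(ld)) {
    both <- ld[ld$snp_a %in% snpNodes & ld$snp_b %in% snpNodes, ]
    for (i in seq_len(nrow(both)))
      addEdge(both$snp_a[i], both$snp_b[i], "LD", directed = FALSE)
  }

  nodes <- data.frame(id = names(reg$roles),
                      role = unlist(reg$roles, use.names = FALSE),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), ]
  ed <- unique(do.call(rbind, edges))
  ed <- ed[order(ed$relation, ed$from, ed$to), ]
  AssociationNetwork(nodes, ed)
}

#' Build the miRNA association network
#'
#' Multi-graph over SNP, gene, miRNA and phenotype nodes: a clinical hit's
#' eQTL edge is `located_in_sig_eQTL` when its SNP lies in a binding site of
#' the gene (else `sig_eQTL`); `located_in` links SNPs to host genes of
#' non-significant pairs; `sig_associated_with` links the annotated SNP (the
#' eQTL SNP for direct hits, the LD proxy for indirect hits) to its
#' phenotype; `associated_with` links catalog-reported genes to phenotypes;
#' `regulated_by` links a host gene to the miRNA predicted to bind it; `LD`
#' links SNP pairs at the R-squared threshold.
#'
#' @param hits clinical hits (see [clinicalHits()]).
#' @param catalog SNP-feature catalog (see [mapSnpsToFeatures()]).
#' @param eqtls eQTL table with a `significant` column.
#' @param annotations annotation table (internal schema).
#' @param ld_pairs data.table from [ldPartners()].
#' @param ld_threshold minimum R-squared for LD edges (inclusive).
#' @return An [AssociationNetwork-class] object.
#' @export
buildMirnaNetwork <- function(hits, catalog, eqtls, annotations, ld_pairs,
                              ld_threshold = 0.8) {
  .buildNetwork(hits, catalog, eqtls, annotations, ld_pairs,
                model = "mirna", ld_threshold = ld_threshold)
}

#' Build the lincRNA association network
#'
#' As [buildMirnaNetwork()] but over SNP, gene, lincRNA and phenotype nodes:
#' `located_in` links a SNP to the lincRNA containing it, `sig_eQTL` links the
#' SNP to the gene whose expression it associates with. Because lincRNAs have
#' no predicted gene targets, no lincRNA-gene edge is ever emitted.
#'
#' @inheritParams buildMirnaNetwork
#' @return An [AssociationNetwork-class] object.
#' @export
buildLincrnaNetwork <- function(hits, catalog, eqtls, annotations, ld_pairs,
                                ld_threshold = 0.8) {
  .buildNetwork(hits, catalog, eqtls, annotations, ld_pairs,
                model = "lincrna", ld_threshold = ld_threshold)
}

#' Convert an association network to igraph
#'
#' Directed igraph with node attribute `role` and edge attributes `relation`
#' and `edge_directed` (FALSE for LD edges, which are stored once).
#'
#' @param net an [AssociationNetwork-class] object.
#' @return An `igraph` object.
#' @export
asIgraph <- function(net) {
  nd <- netNodes(net)
  ed <- netEdges(net)
  igraph::graph_from_data_frame(
    d = data.frame(from = ed$from, to = ed$to, relation = ed$relation,
                   edge_directed = ed$directed, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nd$id, role = nd$role,
                          stringsAsFactors = FALSE)
  )
}

#' Connected components (sub-networks) of an association network
#'
#' Components of the underlying undirected simple graph (edge direction and
#' multi-edge duplication ignored for connectivity); multi-edges still count
#' in each component's `n_edges`. Components are numbered by size descending,
#' ties broken by smallest node id.
#'
#' @param net an [AssociationNetwork-class] object.
#' @return list with `summary` (data.table: `component`, `n_nodes`,
#'   `n_edges`) and `membership` (named integer vector over node ids).
#' @export
networkComponents <- function(net) {
  nd <- netNodes(net)
  ed <- netEdges(net)
  if (nrow(nd) == 0L)
    return(list(summary = data.table::data.table(component = integer(),
                                                 n_nodes = integer(),
                                                 n_edges = integer()),
                membership = stats::setNames(integer(), character())))
  g <- asIgraph(net)
  cmp <- igraph::components(g, mode = "weak")
  memb <- cmp$membership
  ## renumber: size descending, ties by smallest node id
  minId <- vapply(seq_len(cmp$no),
                  function(k) min(names(memb)[memb == k]), character(1))
  ord <- order(-cmp$csize, minId)
  newId <- integer(cmp$no)
  newId[ord] <- seq_len(cmp$no)
  memb <- stats::setNames(newId[memb], names(memb))
  nEdges <- integer(cmp$no)
  if (nrow(ed)) {
    ec <- memb[ed$from]
    tab <- table(ec)
    nEdges[as.integer(names(tab))] <- as.integer(tab)
  }
  summary <- data.table::data.table(
    component = seq_len(cmp$no),
    n_nodes = as.integer(table(factor(memb, levels = seq_len(cmp$no)))),
    n_edges = nEdges
  )
  list(summary = summary, membership = memb)
}

#' Iterative eQTL-knockout perturbation scan
#'
#' For each distinct eQTL pair (edges with relation `sig_eQTL` or
#' `located_in_sig_eQTL`), removes it from a fresh copy of the network and
#' recounts connected components. `mode = "nodes"` (default) removes both the
#' SNP and the gene node with all incident edges; `mode = "edge"` removes only
#' that pair's eQTL edges. Nodes isolated by a knockout are retained and
#' counted as size-1 components. The report is sorted by `components_after`
#' descending.
#'
#' @param net an [AssociationNetwork-class] object.
#' @param mode `"nodes"` or `"edge"`.
#' @return data.table with columns `snp_id`, `gene_id`, `mode`,
#'   `components_before`, `components_after`.
#' @export
knockoutScan <- function(net, mode = c("nodes", "edge")) {
  mode <- match.arg(mode)
  nd <- netNodes(net)
  ed <- netEdges(net)
  eqRel <- c("sig_eQTL", "located_in_sig_eQTL")
  eq <- unique(ed[ed$relation %in% eqRel, c("from", "to")])
  empty <- data.table::data.table(
    snp_id = character(), gene_id = character(), mode = character(),
    components_before = integer(), components_after = integer())
  if (nrow(eq) == 0L) {
    warning("network contains no eQTL edges")
    return(empty)
  }
  before <- nrow(networkComponents(net)$summary)
  res <- vector("list", nrow(eq))
  for (i in seq_len(nrow(eq))) {
    snp <- eq$from[i]
    gene <- eq$to[i]
    if (mode == "nodes") {
      keepN <- !(nd$id %in% c(snp, gene))
      nd2 <- nd[keepN, , drop = FALSE]
      ed2 <- ed[!(ed$from %in% c(snp, gene) | ed$to %in% c(snp, gene)), ,
                drop = FALSE]
    } else {
      nd2 <- nd
      ed2 <- ed[!(ed$from == snp & ed$to == gene & ed$relation %in% eqRel), ,
                drop = FALSE]
    }
    after <- nrow(networkComponents(AssociationNetwork(nd2, ed2))$summary)
    res[[i]] <- data.table::data.table(
      snp_id = snp, gene_id = gene, mode = mode,
      components_before = before, components_after = after)
  }
  out <- data.table::rbindlist(res)
  data.table::setorder(out, -components_after, snp_id, gene_id)
  out[]
}

#' Per-component summary with node-role counts
#'
#' @param net an [AssociationNetwork-class] object.
#' @return data.table: one row per component with `n_nodes`, `n_edges` and a
#'   count column per node role.
#' @export
componentSummary <- function(net) {
  cmp <- networkComponents(net)
  nd <- netNodes(net)
  out <- cmp$summary
  for (role in NET_ROLES) {
    cnt <- integer(nrow(out))
    ids <- nd$id[nd$role == role]
    if (length(ids)) {
      tab <- table(cmp$membership[ids])
      cnt[as.integer(names(tab))] <- as.integer(tab)
    }
    out[[paste0("n_", role)]] <- cnt
  }
  out[]
}
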