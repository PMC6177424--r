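test_that("the validity method enforces the typed-graph contracts", {
  expect_equal(nrow(netNodes(AssociationNetwork())), 0)
  nodes <- data.frame(id = c("rs1", "geneA", "t"),
                      role = c("snp", "gene", "phenotype"))
  ok <- AssociationNetwork(nodes, data.frame(
    from = "rs1", to = "geneA", relation = "sig_eQTL", directed = TRUE))
  expect_s4_class(ok, "AssociationNetwork")
  # undeclared node
  expect_error(AssociationNetwork(nodes, data.frame(
    from = "rs9", to = "geneA", relation = "sig_eQTL", directed = TRUE)),
    "undeclared")
  # endpoint contract: gene -> phenotype may not use sig_associated_with
  expect_error(AssociationNetwork(nodes, data.frame(
    from = "geneA", to = "t", relation = "sig_associated_with",
    directed = TRUE)), "endpoint contract")
  # self loops forbidden
  expect_error(AssociationNetwork(nodes, data.frame(
    from = "rs1", to = "rs1", relation = "LD", directed = FALSE)),
    "self-loops")
  # LD edges canonical and undirected
  two <- data.frame(id = c("rs1", "rs2"), role = "snp")
  expect_error(AssociationNetwork(two, data.frame(
    from = "rs2", to = "rs1", relation = "LD", directed = FALSE)),
    "canonical")
  expect_error(AssociationNetwork(two, data.frame(
    from = "rs1", to = "rs2", relation = "LD", directed = TRUE)),
    "undirected")
  # duplicate node id (role partition)
  expect_error(AssociationNetwork(
    data.frame(id = c("x", "x"), role = c("snp", "gene")),
    NULL), "duplicate")
})

test_that("the miRNA network toy fixture matches the hand enumeration", {
  toy <- toyMirnaInputs()
  net <- buildMirnaNetwork(toy$hits, toy$catalog, toy$eqtls, toy$annotations,
                           toy$ld)
  nd <- netNodes(net)
  expect_setequal(paste(nd$id, nd$role),
                  c("rs1 snp", "geneA gene", "miR-1 mirna",
                    "traitX phenotype"))
  ed <- netEdges(net)
  expect_setequal(
    paste(ed$from, ed$relation, ed$to),
    c("rs1 located_in_sig_eQTL geneA", "geneA regulated_by miR-1",
      "rs1 sig_associated_with traitX"))

  # adding one LD partner with its own trait: exactly one LD edge and one
  # extra sig_associated_with edge appear
  toy2 <- toyMirnaInputs(with_ld_partner = TRUE)
  net2 <- buildMirnaNetwork(toy2$hits, toy2$catalog, toy2$eqtls,
                            toy2$annotations, toy2$ld)
  ed2 <- netEdges(net2)
  new <- setdiff(paste(ed2$from, ed2$relation, ed2$to),
                 paste(ed$from, ed$relation, ed$to))
  expect_setequal(new, c("rs1 LD rs2", "rs2 sig_associated_with traitY"))
  expect_equal(netNodes(net2)$role[netNodes(net2)$id == "rs2"], "snp")
})

test_that("the lincRNA network never links a lincRNA to a gene", {
  hits <- data.frame(snp_id = "rs1", gene_id = "geneB", tissue = "thyroid",
                     p_adj = 1e-5, source = "gwas", trait_or_drug = "traitZ",
                     ann_gene = "geneB", mode = "direct",
                     proxy_snp = NA_character_, r2 = NA_real_)
  catalog <- data.frame(snp_id = "rs1", feature_id = "linc1",
                        feature_class = "lincrna",
                        target_gene = NA_character_,
                        mirna_family = NA_character_)
  eqtls <- data.frame(snp_id = "rs1", gene_id = "geneB", tissue = "thyroid",
                      p_adj = 1e-5, significant = TRUE)
  ann <- data.frame(snp_id = "rs1", source = "gwas", trait_or_drug = "traitZ",
                    gene = "geneB")
  net <- buildLincrnaNetwork(hits, catalog, eqtls, ann,
                             data.frame(snp_a = character(),
                                        snp_b = character(), r2 = numeric()))
  ed <- netEdges(net)
  expect_setequal(
    paste(ed$from, ed$relation, ed$to),
    c("rs1 located_in linc1", "rs1 sig_eQTL geneB",
      "rs1 sig_associated_with traitZ", "geneB associated_with traitZ"))
  role <- stats::setNames(netNodes(net)$role, netNodes(net)$id)
  # no lincRNA-gene edge in either direction
  expect_false(any(role[ed$from] == "lincrna" & role[ed$to] == "gene"))
  expect_false(any(role[ed$from] == "gene" & role[ed$to] == "lincrna"))
  # empty inputs give an empty network
  expect_equal(nrow(netNodes(buildLincrnaNetwork(
    hits[0, ], catalog, eqtls, ann, NULL))), 0)
})

test_that("components match a DFS oracle and ignore direction/multiplicity", {
  # two disjoint edges -> 2 components; singleton -> its own component
  nodes <- data.frame(id = c("rs1", "geneA", "rs2", "geneB", "t"),
                      role = c("snp", "gene", "snp", "gene", "phenotype"))
  edges <- data.frame(from = c("rs1", "rs2"), to = c("geneA", "geneB"),
                      relation = "sig_eQTL", directed = TRUE)
  cmp <- networkComponents(AssociationNetwork(nodes, edges))
  expect_equal(nrow(cmp$summary), 3)
  expect_equal(cmp$summary$n_nodes, c(2L, 2L, 1L))
  # multi-edges count in n_edges but not connectivity
  edges2 <- rbind(edges, data.frame(from = "rs1", to = "geneA",
                                    relation = "located_in", directed = TRUE))
  cmp2 <- networkComponents(AssociationNetwork(nodes, edges2))
  expect_equal(nrow(cmp2$summary), 3)
  expect_equal(sum(cmp2$summary$n_edges), 3)

  # random networks vs the DFS oracle
  set.seed(77)
  for (rep in 1:5) {
    n <- 100
    ids <- sprintf("rs%03d", 1:n)
    nd <- data.frame(id = ids, role = "snp")
    pairs <- t(combn(ids, 2))
    take <- sample(nrow(pairs), 60)
    ed <- data.frame(from = pmin(pairs[take, 1], pairs[take, 2]),
                     to = pmax(pairs[take, 1], pairs[take, 2]),
                     relation = "LD", directed = FALSE)
    ed <- unique(ed)
    net <- AssociationNetwork(nd, ed)
    memb <- networkComponents(net)$membership
    oracle <- dfsComponents(ids, ed$from, ed$to)
    # same partition (compare via co-membership of a sample of pairs)
    idx <- sample(nrow(pairs), 500)
    same_got <- memb[pairs[idx, 1]] == memb[pairs[idx, 2]]
    same_want <- oracle[pairs[idx, 1]] == oracle[pairs[idx, 2]]
    expect_equal(unname(same_got), unname(same_want))
  }
})

test_that("GraphML round-trip preserves the component partition", {
  toy <- toyMirnaInputs(with_ld_partner = TRUE)
  net <- buildMirnaNetwork(toy$hits, toy$catalog, toy$eqtls, toy$annotations,
                           toy$ld)
  f <- withr::local_tempfile(fileext = ".graphml")
  writeNetwork(net, f, "graphml")
  net2 <- readNetworkGraphml(f)
  m1 <- networkComponents(net)$membership
  m2 <- networkComponents(net2)$membership
  expect_setequal(names(m1), names(m2))
  expect_equal(m2[names(m1)], m1)
})

test_that("knockout semantics: path fixture", {
  net <- pathNetwork()
  # mode=nodes: removing (rs_mid, gene1) leaves only gene2
  ko_n <- knockoutScan(net, mode = "nodes")
  expect_equal(nrow(ko_n), 2)
  expect_true(all(ko_n$components_before == 1))
  expect_true(all(ko_n$components_after == 1))
  # mode=edge: removing one eQTL edge splits off one node
  ko_e <- knockoutScan(net, mode = "edge")
  expect_true(all(ko_e$components_after == 2))
  expect_true(all(ko_e$components_after - ko_e$components_before %in% c(0, 1)))
})

test_that("knockout semantics: star fixture, identical impact per hub eQTL", {
  for (k in c(3, 5)) {
    net <- starNetwork(k)
    ko <- knockoutScan(net, mode = "nodes")
    expect_equal(nrow(ko), k)
    expect_true(all(ko$components_before == 1))
    # removing the hub SNP and one gene strands the k-1 other genes
    expect_true(all(ko$components_after == k - 1))
    expect_equal(length(unique(ko$components_after)), 1)
  }
  # report is sorted by impact
  net <- starNetwork(4)
  extra <- AssociationNetwork(
    rbind(netNodes(net), data.frame(id = c("rs_b", "geneX"),
                                    role = c("snp", "gene"))),
    rbind(netEdges(net), data.frame(from = "rs_b", to = "geneX",
                                    relation = "sig_eQTL", directed = TRUE)))
  ko <- knockoutScan(extra, mode = "nodes")
  expect_true(all(diff(ko$components_after) <= 0))
  # no eQTL edges -> empty report with warning
  ld_only <- AssociationNetwork(
    data.frame(id = c("rs1", "rs2"), role = "snp"),
    data.frame(from = "rs1", to = "rs2", relation = "LD", directed = FALSE))
  expect_warning(out <- knockoutScan(ld_only), "no eQTL")
  expect_equal(nrow(out), 0)
})

test_that("endpoint contracts hold on every synthetic construction", {
  cfg <- demoConfig(seed = 41)
  res <- suppressMessages(suppressWarnings(
    runPipeline(runConfig(outdir = withr::local_tempdir(), cohort = cfg,
                          seed = 41))))
  for (net in list(res$mirna_net, res$lincrna_net)) {
    expect_s4_class(net, "AssociationNetwork") # validity ran on construction
    ed <- netEdges(net)
    role <- stats::setNames(netNodes(net)$role, netNodes(net)$id)
    expect_true(all(role[ed$from[ed$relation == "sig_associated_with"]] ==
                      "snp"))
    expect_true(all(role[ed$to[ed$relation == "sig_associated_with"]] ==
                      "phenotype"))
    ld <- ed[ed$relation == "LD", ]
    expect_true(all(ld$from < ld$to))
  }
})
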