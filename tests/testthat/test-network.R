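test_that("empty sponge output gives an empty network", {
  empty <- spongeTest(
    data.frame(id_a = character(), id_b = character(),
               pair_type = character(), method = character(),
               coefficient = numeric(), n_samples = integer(),
               common_mirnas = character(), stringsAsFactors = FALSE),
    data.frame(id_a = character(), id_b = character(),
               pair_type = character(), method = character(),
               coefficient = numeric(), n_samples = integer(),
               stringsAsFactors = FALSE),
    universeSize = 10)
  net <- buildNetwork(data.frame(), empty)
  expect_equal(nrow(networkNodes(net)), 0L)
  expect_equal(nrow(networkEdges(net)), 0L)
  s <- networkSummary(net)
  expect_equal(s$n_circRNA + s$n_miRNA + s$n_mRNA + s$n_circ_mrna, 0L)
})

test_that("a single triad yields 3 nodes and 3 edges", {
  retained <- data.frame(
    id_a = c("mir1", "mir1"), id_b = c("circ1", "gene1"),
    pair_type = c("mirna_circ", "mirna_mrna"),
    method = "spearman", coefficient = c(-0.9, -0.8), n_samples = 6L,
    stringsAsFactors = FALSE)
  sponge <- data.frame(circ_id = "circ1", mrna_id = "gene1",
                       k = 1L, K = 1L, n = 1L, N = 40L, pvalue = 0.025,
                       pcc = 0.95, shared_mirnas = "mir1",
                       stringsAsFactors = FALSE)
  net <- buildNetwork(retained, sponge, tissue = "hypothalamus")
  expect_equal(nrow(networkNodes(net)), 3L)
  expect_equal(nrow(networkEdges(net)), 3L)
  s <- networkSummary(net)
  expect_equal(c(s$n_circRNA, s$n_miRNA, s$n_mRNA), c(1L, 1L, 1L))
  expect_equal(s$n_circ_mrna, 1L)
  # negative-edge coefficients are carried over from the retained pairs
  ed <- networkEdges(net)
  expect_equal(ed$coefficient[ed$edge_type == "circ_mirna"], -0.9)
  expect_equal(ed$coefficient[ed$edge_type == "mirna_mrna"], -0.8)
})

test_that("nodes are exactly the union of edge endpoints, sorted", {
  net <- toyNetwork()
  nd <- networkNodes(net); ed <- networkEdges(net)
  expect_setequal(nd$id, unique(c(ed$from, ed$to)))
  expect_identical(nd$id, nd$id[order(nd$type, nd$id)])
  expect_identical(order(ed$edge_type, ed$from, ed$to), seq_len(nrow(ed)))
})

test_that("tripartite typing is enforced by the class validity", {
  net <- toyNetwork()
  bad <- networkEdges(net)
  bad$edge_type[bad$edge_type == "circ_mrna"][1] <- "circ_mirna"
  expect_error(new("CeRNANetwork", nodes = networkNodes(net), edges = bad,
                   tissue = "toy"), "tripartite")
  dangling <- networkEdges(net)
  dangling$from[1] <- "ghost"
  expect_error(new("CeRNANetwork", nodes = networkNodes(net),
                   edges = dangling, tissue = "toy"), "dangling")
})

test_that("a network missing a sponge edge's witnesses cannot be built", {
  retained <- data.frame(
    id_a = "mir1", id_b = "circ1", pair_type = "mirna_circ",
    method = "spearman", coefficient = -0.9, n_samples = 6L,
    stringsAsFactors = FALSE)  # no mirna_mrna edge for gene1
  sponge <- data.frame(circ_id = "circ1", mrna_id = "gene1",
                       k = 1L, K = 1L, n = 1L, N = 40L, pvalue = 0.025,
                       pcc = 0.95, shared_mirnas = "mir1",
                       stringsAsFactors = FALSE)
  expect_error(buildNetwork(retained, sponge), "assembly error")
})

test_that("subnetwork extraction reproduces anchor wiring", {
  net <- toyNetwork()
  sub <- extractSubnetwork(net, "gene1")
  expect_setequal(networkNodes(sub)$id, c("circ1", "mir1", "gene1"))
  expect_equal(nrow(networkEdges(sub)), 3L)
  expect_warning(empty <- extractSubnetwork(net, "nope"), "not in network")
  expect_equal(nrow(networkNodes(empty)), 0L)
})

test_that("anchor reports count regulating circRNAs and miRNAs", {
  # one mRNA regulated by 3 circRNAs through 2 miRNAs, by construction
  retained <- data.frame(
    id_a = c("mirA", "mirA", "mirB", "mirA", "mirB"),
    id_b = c("c1", "c2", "c3", "g1", "g1"),
    pair_type = c("mirna_circ", "mirna_circ", "mirna_circ",
                  "mirna_mrna", "mirna_mrna"),
    method = "spearman", coefficient = -0.9, n_samples = 6L,
    stringsAsFactors = FALSE)
  sponge <- data.frame(circ_id = c("c1", "c2", "c3"), mrna_id = "g1",
                       k = 1L, K = 1L, n = 2L, N = 40L, pvalue = 0.01,
                       pcc = 0.95,
                       shared_mirnas = c("mirA", "mirA", "mirB"),
                       stringsAsFactors = FALSE)
  net <- buildNetwork(retained, sponge)
  rep <- anchorReport(net, "g1")
  expect_equal(rep$n_circRNA, 3L)
  expect_equal(rep$n_miRNA, 2L)
  expect_equal(rep$n_circ_mrna_pairs, 3L)
})

test_that("the audit passes clean networks and flags tampering", {
  net <- toyNetwork()
  expect_equal(as.integer(auditNetwork(net)), 0L)
  tampered <- net
  tampered@edges$coefficient[tampered@edges$edge_type == "circ_mrna"] <- 0.5
  v <- auditNetwork(tampered)
  expect_gt(v, 0)
  expect_match(attr(v, "details")[1], "PCC")
})

test_that("recovery metrics score planted triads correctly", {
  net <- toyNetwork()
  truthHit <- new("GroundTruth",
    plantedDE = data.frame(class = c("circRNA", "mRNA", "circRNA", "mRNA"),
                           feature_id = c("circ1", "gene1", "circ2", "gene2"),
                           direction = "up", stringsAsFactors = FALSE),
    plantedTriads = data.frame(circ_id = c("circ1", "circ2"),
                               mirna_id = c("mir1", "mir2"),
                               mrna_id = c("gene1", "gene2"),
                               stringsAsFactors = FALSE),
    plantedInteractions = data.frame(
      mirna_id = c("mir1", "mir1", "mir2", "mir2"),
      target_id = c("circ1", "gene1", "circ2", "gene2"),
      target_type = c("circRNA", "mRNA", "circRNA", "mRNA"),
      stringsAsFactors = FALSE))
  m <- recoveryMetrics(net, truthHit)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)

  emptyNet <- buildNetwork(data.frame(),
                           data.frame(circ_id = character(),
                                      mrna_id = character(), k = integer(),
                                      K = integer(), n = integer(),
                                      N = integer(), pvalue = numeric(),
                                      pcc = numeric(),
                                      shared_mirnas = character(),
                                      stringsAsFactors = FALSE))
  m0 <- recoveryMetrics(emptyNet, truthHit)
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 1)  # no false positives by convention
})

test_that("igraph conversion and GraphML serialization round-trip", {
  net <- toyNetwork()
  g <- networkIgraph(net)
  expect_equal(igraph::vcount(g), nrow(networkNodes(net)))
  expect_equal(igraph::ecount(g), nrow(networkEdges(net)))
  path <- tempfile(fileext = ".graphml")
  writeGraphML(net, path)
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_setequal(igraph::V(g2)$type, networkNodes(net)$type)
})
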