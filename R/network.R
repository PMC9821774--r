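.emptyNodes <- function() data.frame(id = character(), type = character(),
                                     direction = character(),
                                     stringsAsFactors = FALSE)
.emptyEdges <- function() data.frame(from = character(), to = character(),
                                     edge_type = character(),
                                     coefficient = numeric(),
                                     pvalue = numeric(),
                                     shared_mirnas = character(),
                                     stringsAsFactors = FALSE)

.sortNetwork <- function(nodes, edges) {
  if (nrow(nodes)) nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  if (nrow(edges))
    edges <- edges[order(edges$edge_type, edges$from, edges$to), ,
                   drop = FALSE]
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Assemble the tripartite ceRNA network
#'
#' The network contains every retained circRNA-mRNA sponge edge together
#' with its witnesses: for each shared miRNA of a sponge edge, the negative
#' circRNA-miRNA and miRNA-mRNA edges (with their Spearman coefficients)
#' that support it. Nodes are exactly the features incident to at least one
#' retained edge; node and edge ordering is deterministic (nodes by type
#' then ID, edges by type then endpoints).
#'
#' @param retainedPairs retained negative pairs from
#'   [filterMirnaTargetPairs()].
#' @param spongeEdges retained sponge edges from [spongeTest()].
#' @param tissue tissue label.
#' @param deTables optional named list of DE tables used to annotate node
#'   DE directions.
#' @return a [CeRNANetwork-class].
#' @export
buildNetwork <- function(retainedPairs, spongeEdges, tissue = "",
                         deTables = NULL) {
  edges <- .emptyEdges()
  if (nrow(spongeEdges)) {
    corOf <- setNames(retainedPairs$coefficient,
                      paste(retainedPairs$id_a, retainedPairs$id_b,
                            retainedPairs$pair_type, sep = "\r"))
    lst <- vector("list", nrow(spongeEdges))
    for (i in seq_len(nrow(spongeEdges))) {
      ci <- spongeEdges$circ_id[i]; mi <- spongeEdges$mrna_id[i]
      shared <- strsplit(spongeEdges$shared_mirnas[i], ";", fixed = TRUE)[[1]]
      shared <- shared[nzchar(shared)]
      sup <- lapply(shared, function(m) {
        kc <- paste(m, ci, "mirna_circ", sep = "\r")
        km <- paste(m, mi, "mirna_mrna", sep = "\r")
        if (!kc %in% names(corOf) || !km %in% names(corOf))
          stop("assembly error: sponge edge ", ci, "-", mi,
               " lacks retained negative pairs for miRNA ", m)
        rbind(
          data.frame(from = ci, to = m, edge_type = "circ_mirna",
                     coefficient = corOf[[kc]], pvalue = NA_real_,
                     shared_mirnas = "", stringsAsFactors = FALSE),
          data.frame(from = m, to = mi, edge_type = "mirna_mrna",
                     coefficient = corOf[[km]], pvalue = NA_real_,
                     shared_mirnas = "", stringsAsFactors = FALSE))
      })
      lst[[i]] <- rbind(
        data.frame(from = ci, to = mi, edge_type = "circ_mrna",
                   coefficient = spongeEdges$pcc[i],
                   pvalue = spongeEdges$pvalue[i],
                   shared_mirnas = spongeEdges$shared_mirnas[i],
                   stringsAsFactors = FALSE),
        do.call(rbind, sup))
    }
    edges <- do.call(rbind, lst)
    edges <- edges[!duplicated(paste(edges$from, edges$to,
                                     edges$edge_type)), , drop = FALSE]
  }
  nodes <- .emptyNodes()
  if (nrow(edges)) {
    typeOfEndpoint <- rbind(
      data.frame(id = edges$from,
                 type = vapply(edges$edge_type, function(e)
                   .edgeEndpointTypes[[e]][1], character(1)),
                 stringsAsFactors = FALSE),
      data.frame(id = edges$to,
                 type = vapply(edges$edge_type, function(e)
                   .edgeEndpointTypes[[e]][2], character(1)),
                 stringsAsFactors = FALSE))
    nodes <- unique(typeOfEndpoint)
    nodes$direction <- NA_character_
    if (!is.null(deTables)) {
      for (cl in intersect(names(deTables), VALID_RNA_CLASSES)) {
        de <- deTables[[cl]]
        idx <- nodes$type == cl
        nodes$direction[idx] <-
          de$direction[match(nodes$id[idx], de$feature_id)]
      }
    }
  }
  s <- .sortNetwork(nodes, edges)
  new("CeRNANetwork", nodes = s$nodes, edges = s$edges,
      tissue = as.character(tissue))
}

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "CeRNANetwork", function(x) x@nodes)

#' @rdname networkNodes
#' @export
setMethod("networkEdges", "CeRNANetwork", function(x) x@edges)

setMethod("show", "CeRNANetwork", function(object) {
  s <- networkSummary(object)
  cat("CeRNANetwork", if (nzchar(object@tissue))
    paste0("[", object@tissue, "]") else "", "\n")
  cat("  nodes:", s$n_circRNA, "circRNA,", s$n_miRNA, "miRNA,",
      s$n_mRNA, "mRNA\n")
  cat("  edges:", s$n_circ_mirna, "circ-miRNA,", s$n_mirna_mrna,
      "miRNA-mRNA,", s$n_circ_mrna, "circRNA-mRNA pairs\n")
})

#' @rdname networkSummary
#' @export
setMethod("networkSummary", "CeRNANetwork", function(x) {
  nd <- x@nodes; ed <- x@edges
  deg <- table(factor(c(ed$from, ed$to), levels = nd$id))
  degByType <- lapply(setNames(VALID_RNA_CLASSES, VALID_RNA_CLASSES),
                      function(cl) as.integer(deg[nd$id[nd$type == cl]]))
  list(
    tissue = x@tissue,
    n_circRNA = sum(nd$type == "circRNA"),
    n_miRNA = sum(nd$type == "miRNA"),
    n_mRNA = sum(nd$type == "mRNA"),
    n_circ_mirna = sum(ed$edge_type == "circ_mirna"),
    n_mirna_mrna = sum(ed$edge_type == "mirna_mrna"),
    n_circ_mrna = sum(ed$edge_type == "circ_mrna"),
    degree = degByType)
})

#' Extract an anchor-centred subnetwork
#'
#' Returns the induced subgraph containing the anchors, all their
#' neighbours, and every edge among that node set — the reporting style
#' used for single-gene ceRNA subnetworks (e.g. all circRNAs and miRNAs
#' regulating one mRNA). Use [anchorReport()] for per-anchor regulator
#' counts. Missing anchors yield an empty network with a warning.
#'
#' @param network a [CeRNANetwork-class].
#' @param anchors node IDs to centre on.
#' @return a [CeRNANetwork-class].
#' @export
extractSubnetwork <- function(network, anchors) {
  present <- anchors[anchors %in% network@nodes$id]
  if (!length(present)) {
    if (length(anchors)) warning("anchor(s) not in network: ",
                                 paste(anchors, collapse = ", "))
    return(new("CeRNANetwork", nodes = .emptyNodes(), edges = .emptyEdges(),
               tissue = network@tissue))
  }
  ed <- network@edges
  touch <- ed$from %in% present | ed$to %in% present
  keepNodes <- union(present, unique(c(ed$from[touch], ed$to[touch])))
  keepEdges <- ed[ed$from %in% keepNodes & ed$to %in% keepNodes, ,
                  drop = FALSE]
  keep <- network@nodes[network@nodes$id %in% keepNodes, , drop = FALSE]
  s <- .sortNetwork(keep, keepEdges)
  new("CeRNANetwork", nodes = s$nodes, edges = s$edges,
      tissue = network@tissue)
}

#' Per-anchor regulator counts
#'
#' For each anchor, counts the distinct circRNAs and miRNAs connected to it
#' and the circRNA-mRNA pairs it participates in.
#'
#' @param network a [CeRNANetwork-class].
#' @param anchors node IDs.
#' @return data.frame with columns `anchor`, `n_circRNA`, `n_miRNA`,
#'   `n_circ_mrna_pairs`.
#' @export
anchorReport <- function(network, anchors) {
  typeOf <- setNames(network@nodes$type, network@nodes$id)
  ed <- network@edges
  do.call(rbind, lapply(anchors, function(a) {
    touch <- ed$from == a | ed$to == a
    nb <- setdiff(unique(c(ed$from[touch], ed$to[touch])), a)
    data.frame(anchor = a,
               n_circRNA = sum(typeOf[nb] == "circRNA"),
               n_miRNA = sum(typeOf[nb] == "miRNA"),
               n_circ_mrna_pairs = sum(touch & ed$edge_type == "circ_mrna"),
               stringsAsFactors = FALSE)
  }))
}

#' Audit a network's structural constraints
#'
#' Re-validates every emitted edge against the construction rules:
#' tripartite typing (no same-class edges), every circRNA-mRNA edge has
#' Pearson coefficient strictly above `pccThreshold`, sponge p-value
#' strictly below `alpha`, and at least one shared miRNA present in the
#' network together with both of its supporting negative edges.
#'
#' @param network a [CeRNANetwork-class].
#' @param pccThreshold,alpha the thresholds the network was built with.
#' @return number of violations (0 for a clean network); the violation
#'   messages are attached as attribute `"details"`.
#' @export
auditNetwork <- function(network, pccThreshold = 0.9, alpha = 0.05) {
  bad <- character()
  v <- validObject(network, test = TRUE)  # tripartiteness + danglers
  if (!isTRUE(v)) bad <- c(bad, v)
  ed <- network@edges
  key <- paste(ed$from, ed$to, ed$edge_type)
  cm <- ed[ed$edge_type == "circ_mrna", , drop = FALSE]
  for (i in seq_len(nrow(cm))) {
    lbl <- paste0(cm$from[i], "-", cm$to[i])
    if (!(cm$coefficient[i] > pccThreshold))
      bad <- c(bad, paste0(lbl, ": PCC not > ", pccThreshold))
    if (!(cm$pvalue[i] < alpha))
      bad <- c(bad, paste0(lbl, ": sponge p not < ", alpha))
    shared <- strsplit(cm$shared_mirnas[i], ";", fixed = TRUE)[[1]]
    shared <- shared[nzchar(shared)]
    ok <- vapply(shared, function(m)
      paste(cm$from[i], m, "circ_mirna") %in% key &&
        paste(m, cm$to[i], "mirna_mrna") %in% key, logical(1))
    if (!length(ok) || !any(ok))
      bad <- c(bad, paste0(lbl, ": no shared-miRNA witness with both",
                           " negative edges"))
  }
  n <- length(bad)
  attr(n, "details") <- bad
  n
}

#' Triad-recovery metrics against ground truth
#'
#' A planted triad counts as recovered iff the network contains its
#' circRNA-mRNA edge and both of its negative miRNA edges. Emitted triads
#' are all (circRNA, miRNA, mRNA) triples wired that way in the network.
#' Precision is the planted fraction of emitted triads (1 by convention
#' when nothing is emitted: no false positives), recall the recovered
#' fraction of planted triads.
#'
#' @param network a [CeRNANetwork-class].
#' @param truth a [GroundTruth-class].
#' @return list with `precision`, `recall`, `f1`, `n_planted`, `n_emitted`,
#'   `n_recovered`.
#' @export
recoveryMetrics <- function(network, truth) {
  ed <- network@edges
  key <- paste(ed$from, ed$to, ed$edge_type)
  cm <- ed[ed$edge_type == "circ_mrna", , drop = FALSE]
  emitted <- character()
  for (i in seq_len(nrow(cm))) {
    shared <- strsplit(cm$shared_mirnas[i], ";", fixed = TRUE)[[1]]
    shared <- shared[nzchar(shared)]
    wit <- shared[vapply(shared, function(m)
      paste(cm$from[i], m, "circ_mirna") %in% key &&
        paste(m, cm$to[i], "mirna_mrna") %in% key, logical(1))]
    emitted <- c(emitted, paste(cm$from[i], wit, cm$to[i], sep = "\r"))
  }
  planted <- with(truth@plantedTriads,
                  paste(circ_id, mirna_id, mrna_id, sep = "\r"))
  nRec <- sum(planted %in% emitted)
  precision <- if (length(emitted)) mean(emitted %in% planted) else 1
  recall <- if (length(planted)) nRec / length(planted) else 1
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_planted = length(planted), n_emitted = length(emitted),
       n_recovered = nRec)
}

#' Convert to igraph / write GraphML
#'
#' @param network a [CeRNANetwork-class].
#' @return `networkIgraph()`: an [igraph::igraph] object with node `type`
#'   and `direction` and edge `edge_type`, `coefficient`, `pvalue`
#'   attributes.
#' @export
networkIgraph <- function(network) {
  ed <- network@edges
  ed$shared_mirnas[is.na(ed$shared_mirnas)] <- ""
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = network@nodes)
}

#' @rdname networkIgraph
#' @param path output path for GraphML.
#' @export
writeGraphML <- function(network, path) {
  g <- networkIgraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write network tables
#'
#' Flat edge-list TSV (`source`, `target`, `edge_type`, `coefficient`,
#' `pvalue`, `shared_mirnas`) and node-attribute TSV (`id`, `type`,
#' `direction`).
#'
#' @param network a [CeRNANetwork-class].
#' @param edgePath,nodePath output paths.
#' @return invisibly, the edge path.
#' @export
writeNetworkTSV <- function(network, edgePath, nodePath) {
  ed <- network@edges
  names(ed)[names(ed) == "from"] <- "source"
  names(ed)[names(ed) == "to"] <- "target"
  utils::write.table(ed, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network@nodes, nodePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edgePath)
}
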