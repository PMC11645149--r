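# Seed-expanded PPI network with borrowed/intrinsic layer projection and a
# hypergeometric test of inter-layer connectivity.

#' Upper-tail hypergeometric overlap probability
#'
#' `P(X >= overlap_k)` where `X` is the overlap of a random draw of
#' `draw_n` elements from a universe of `universe_n` containing
#' `success_k` marked elements. Shared core of the network connectivity
#' test and over-representation analysis.
#'
#' @param overlap_k Observed overlap.
#' @param success_k Number of marked elements in the universe.
#' @param draw_n Size of the draw.
#' @param universe_n Universe size.
#' @return Upper-tail probability in `(0, 1]`.
#' @export
hypergeom_upper <- function(overlap_k, success_k, draw_n, universe_n) {
  .assert(universe_n >= 1, "universe must be non-empty")
  .assert(success_k <= universe_n && draw_n <= universe_n,
          "layer larger than universe")
  .assert(overlap_k <= min(success_k, draw_n),
          "overlap exceeds a layer size")
  stats::phyper(overlap_k - 1, success_k, universe_n - success_k, draw_n,
                lower.tail = FALSE)
}

.new_mlnet <- function(graph) {
  structure(list(graph = graph, layer_report = list()),
            class = "MultilayerNetwork")
}

#' Build a seed-expanded interaction network
#'
#' Retains edges at or above `min_confidence`, then grows the node set from
#' the seeds by `hops` rounds of neighbor expansion (default one hop: seeds
#' plus first neighbors). The edge set is every qualifying edge among
#' retained nodes. Seeds absent from the edge table are kept as isolated,
#' flagged nodes.
#'
#' @param seeds A [gene_set] (or character vector) of seed symbols.
#' @param edges An [edge_table].
#' @param min_confidence Minimum edge confidence (default 0.4, the usual
#'   "medium confidence" STRING convention).
#' @param hops Number of expansion rounds (>= 0).
#' @return An object of class `MultilayerNetwork` wrapping an undirected
#'   igraph graph with vertex attributes `layer` (initially `"connector"`)
#'   and `is_seed`.
#' @export
build_seed_network <- function(seeds, edges, min_confidence = 0.4, hops = 1L) {
  seeds <- .as_genes(seeds)
  .assert(length(seeds) > 0L, "seed set is empty")
  .assert(hops >= 0L, "hops must be >= 0")
  keep <- edges[edges$confidence >= min_confidence, , drop = FALSE]
  g_full <- igraph::graph_from_data_frame(
    keep[, c("a", "b")], directed = FALSE,
    vertices = sort(unique(c(keep$a, keep$b, seeds))))
  igraph::E(g_full)$confidence <- keep$confidence
  nodes <- intersect(seeds, igraph::V(g_full)$name)
  frontier <- nodes
  for (h in seq_len(hops)) {
    if (length(frontier) == 0L) break
    idx <- unique(unlist(igraph::adjacent_vertices(g_full, frontier)))
    nb <- igraph::V(g_full)$name[idx]
    frontier <- setdiff(nb, nodes)
    nodes <- union(nodes, frontier)
  }
  g <- igraph::induced_subgraph(g_full, nodes)
  igraph::V(g)$is_seed <- igraph::V(g)$name %in% seeds
  igraph::V(g)$layer <- "connector"
  .new_mlnet(g)
}

#' Build a network over an entire edge table, without seed expansion
#'
#' Convenience wrapper used when the analysis universe is the whole
#' interactome (e.g. when testing inter-layer connectivity against a
#' degree-matched control) rather than a seed neighborhood.
#'
#' @param edges An [edge_table].
#' @param min_confidence Minimum retained edge confidence.
#' @return A `MultilayerNetwork` over every node of the table.
#' @export
network_from_edges <- function(edges, min_confidence = 0) {
  .assert(nrow(edges) > 0L, "edge table is empty")
  build_seed_network(unique(c(edges$a, edges$b)), edges,
                     min_confidence = min_confidence, hops = 0L)
}

#' Nodes of a MultilayerNetwork
#' @param net A `MultilayerNetwork`.
#' @return Data frame with columns `node`, `layer`, `is_seed`, sorted by
#'   node.
#' @export
network_nodes <- function(net) {
  g <- net$graph
  df <- data.frame(node = igraph::V(g)$name, layer = igraph::V(g)$layer,
                   is_seed = igraph::V(g)$is_seed, stringsAsFactors = FALSE)
  df <- df[order(df$node), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Edges of a MultilayerNetwork
#' @param net A `MultilayerNetwork`.
#' @return An [edge_table].
#' @export
network_edges <- function(net) {
  g <- net$graph
  if (igraph::ecount(g) == 0L)
    return(edge_table(character(), character(), numeric()))
  el <- igraph::as_edgelist(g)
  edge_table(el[, 1L], el[, 2L], igraph::E(g)$confidence)
}

#' @export
print.MultilayerNetwork <- function(x, ...) {
  g <- x$graph
  tags <- table(factor(igraph::V(g)$layer,
                       levels = c("borrowed", "intrinsic", "both", "connector")))
  cat(sprintf("MultilayerNetwork: %d nodes, %d edges (%d seeds)\n",
              igraph::vcount(g), igraph::ecount(g),
              sum(igraph::V(g)$is_seed)))
  cat(sprintf("layers: borrowed %d, intrinsic %d, both %d, connector %d\n",
              tags[["borrowed"]], tags[["intrinsic"]], tags[["both"]],
              tags[["connector"]]))
  invisible(x)
}

#' Project a gene set onto the network as a layer
#'
#' Tags network nodes belonging to `gene_set` with `layer_name`; nodes
#' already carrying the other layer become `"both"`. The induced-subgraph
#' node and edge counts of the tagged set are recorded in
#' `net$layer_report[[layer_name]]`.
#'
#' @param net A `MultilayerNetwork`.
#' @param gene_set [gene_set] or character vector to project.
#' @param layer_name `"borrowed"` or `"intrinsic"`.
#' @return The updated `MultilayerNetwork`.
#' @export
project_layer <- function(net, gene_set, layer_name) {
  .assert(layer_name %in% c("borrowed", "intrinsic"),
          "layer_name must be 'borrowed' or 'intrinsic'")
  g <- net$graph
  genes <- .as_genes(gene_set)
  hit <- igraph::V(g)$name %in% genes
  cur <- igraph::V(g)$layer
  other <- setdiff(c("borrowed", "intrinsic"), layer_name)
  newtag <- ifelse(hit & cur %in% c(other, "both"), "both",
                   ifelse(hit, layer_name, cur))
  igraph::V(g)$layer <- newtag
  sub <- igraph::induced_subgraph(g, which(hit))
  net$graph <- g
  net$layer_report[[layer_name]] <- list(n_nodes = igraph::vcount(sub),
                                         n_edges = igraph::ecount(sub))
  net
}

# Closed neighborhood of a layer: tagged members plus their direct
# interactors ("nodes/proteins interacting within the layer").
.layer_neighborhood <- function(net, layer_name) {
  g <- net$graph
  members <- which(igraph::V(g)$layer %in% c(layer_name, "both"))
  if (length(members) == 0L) return(character())
  idx <- unique(unlist(igraph::adjacent_vertices(g, members)))
  union(igraph::V(g)$name[members], igraph::V(g)$name[idx])
}

#' Hypergeometric test of connectivity between the two projected layers
#'
#' For each layer, takes the closed neighborhood of its tagged nodes
#' (members plus direct interactors), then asks whether the two
#' neighborhoods overlap more than expected if one were drawn at random
#' from the network's node universe: upper-tail hypergeometric
#' `P(X >= overlap)` with the full node set as universe.
#'
#' @param net A `MultilayerNetwork` with both layers projected.
#' @return An object of class `LayerOverlapTest`: list with `universe_n`,
#'   `layer1_k` (borrowed neighborhood), `layer2_n` (intrinsic
#'   neighborhood), `overlap_k`, `p_value`, `tail`.
#' @export
layer_connectivity_test <- function(net) {
  .assert(all(c("borrowed", "intrinsic") %in% names(net$layer_report)),
          "project both layers before testing connectivity")
  n1 <- .layer_neighborhood(net, "borrowed")
  n2 <- .layer_neighborhood(net, "intrinsic")
  N <- igraph::vcount(net$graph)
  k <- length(intersect(n1, n2))
  structure(list(universe_n = N, layer1_k = length(n1),
                 layer2_n = length(n2), overlap_k = k,
                 p_value = hypergeom_upper(k, length(n1), length(n2), N),
                 tail = "upper"),
            class = "LayerOverlapTest")
}

#' @export
print.LayerOverlapTest <- function(x, ...) {
  cat(sprintf(paste0("Layer overlap: %d of universe %d ",
                     "(layers %d / %d), upper-tail hypergeometric p = %.3g\n"),
              x$overlap_k, x$universe_n, x$layer1_k, x$layer2_n, x$p_value))
  invisible(x)
}

#' Export a network as node/edge TSVs plus a summary JSON
#' @param net A `MultilayerNetwork`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
export_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- network_nodes(net)
  edges <- network_edges(net)
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(a = edges$a, b = edges$b, confidence = edges$confidence),
    file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  tags <- table(factor(nodes$layer,
                       levels = c("borrowed", "intrinsic", "both", "connector")))
  summary <- list(n_nodes = nrow(nodes), n_edges = nrow(edges),
                  n_seeds = sum(nodes$is_seed),
                  layer_counts = as.list(stats::setNames(as.integer(tags),
                                                         names(tags))))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Re-import a network written by [export_network]
#' @param dir Directory containing `nodes.tsv` and `edges.tsv`.
#' @return A `MultilayerNetwork`.
#' @export
read_network <- function(dir) {
  nodes <- .read_delim(file.path(dir, "nodes.tsv"))
  edges <- .read_delim(file.path(dir, "edges.tsv"))
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b"), drop = FALSE], directed = FALSE,
    vertices = nodes[, "node", drop = FALSE])
  igraph::E(g)$confidence <- as.numeric(edges$confidence)
  igraph::V(g)$layer <- nodes$layer[match(igraph::V(g)$name, nodes$node)]
  igraph::V(g)$is_seed <- nodes$is_seed[match(igraph::V(g)$name, nodes$node)]
  net <- .new_mlnet(g)
  for (layer in c("borrowed", "intrinsic")) {
    hit <- which(igraph::V(g)$layer %in% c(layer, "both"))
    if (length(hit) > 0L) {
      sub <- igraph::induced_subgraph(g, hit)
      net$layer_report[[layer]] <- list(n_nodes = igraph::vcount(sub),
                                        n_edges = igraph::ecount(sub))
    }
  }
  net
}
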