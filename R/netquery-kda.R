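# Anchor-to-gene-set shortest-path subnetwork extraction, k-layer downstream
# neighborhoods, layer-wise enrichment validation against perturbation
# signatures, and key-driver analysis.

#' Shortest-path subnetwork from an anchor to a target gene set
#'
#' For every target reachable from the anchor along directed edges, all tied
#' shortest directed paths are computed; the subnetwork is the union of their
#' nodes and edges. Unreachable targets are reported separately.
#'
#' @param network directed network (edge data.frame or `consensus_network`).
#' @param anchor anchor gene (must be a network node).
#' @param targets target gene set; targets absent from the network are
#'   reported as unreachable.
#' @return object of class `anchor_subnetwork`: list with `nodes`
#'   (data.frame node, role in anchor/target/intermediate), `edges` (parent,
#'   child), `unreachable` (character) and `anchor`.
#' @export
shortest_path_subnetwork <- function(network, anchor, targets) {
  edges <- as_edge_df(network)
  nodes <- network_nodes(network)
  if (!anchor %in% nodes)
    stop(sprintf("anchor '%s' not in network", anchor), call. = FALSE)
  targets <- setdiff(unique(targets), anchor)
  ig <- edges_to_igraph(edges, nodes)
  present <- intersect(targets, nodes)
  d <- igraph::distances(ig, v = anchor, to = present, mode = "out")
  reached <- present[is.finite(d[1, ])]
  unreachable <- c(setdiff(targets, nodes), setdiff(present, reached))
  sub_nodes <- character(0)
  sub_edges <- edges[0, c("parent", "child"), drop = FALSE]
  for (tg in reached) {
    paths <- igraph::all_shortest_paths(ig, from = anchor, to = tg,
                                        mode = "out")$vpaths
    for (pth in paths) {
      nm <- names(pth)
      sub_nodes <- union(sub_nodes, nm)
      if (length(nm) > 1L)
        sub_edges <- rbind(sub_edges,
                           data.frame(parent = nm[-length(nm)], child = nm[-1],
                                      stringsAsFactors = FALSE))
    }
  }
  sub_edges <- unique(sub_edges)
  sub_edges <- sub_edges[order(sub_edges$parent, sub_edges$child), ,
                         drop = FALSE]
  rownames(sub_edges) <- NULL
  role <- ifelse(sub_nodes == anchor, "anchor",
                 ifelse(sub_nodes %in% reached, "target", "intermediate"))
  node_df <- data.frame(node = sub_nodes, role = role,
                        stringsAsFactors = FALSE)
  node_df <- node_df[order(node_df$node), , drop = FALSE]
  rownames(node_df) <- NULL
  structure(list(nodes = node_df, edges = sub_edges,
                 unreachable = sort(unreachable), anchor = anchor),
            class = "anchor_subnetwork")
}

#' @export
print.anchor_subnetwork <- function(x, ...) {
  cat(sprintf("anchor_subnetwork from %s: %d nodes (%d targets reached, %d intermediates), %d edges; %d target(s) unreachable\n",
              x$anchor, nrow(x$nodes), sum(x$nodes$role == "target"),
              sum(x$nodes$role == "intermediate"), nrow(x$edges),
              length(x$unreachable)))
  invisible(x)
}

#' k-layer downstream neighborhood of a node
#'
#' All nodes at directed distance 1..k from `node` (the node itself is
#' excluded).
#'
#' @param network directed network (edge data.frame or `consensus_network`).
#' @param node source gene.
#' @param k maximum layer depth (>= 1).
#' @return character vector of gene ids (sorted).
#' @export
downstream_neighborhood <- function(network, node, k) {
  k <- assert_count(k, "k", min = 1L)
  nodes <- network_nodes(network)
  if (!node %in% nodes)
    stop(sprintf("node '%s' not in network", node), call. = FALSE)
  ig <- edges_to_igraph(as_edge_df(network), nodes)
  d <- igraph::distances(ig, v = node, mode = "out")[1, ]
  sort(names(d)[is.finite(d) & d >= 1 & d <= k])
}

#' Layer-wise enrichment of downstream neighborhoods for a signature
#'
#' For each layer depth k = 1..k_max, tests the k-layer downstream
#' neighborhood of `node` for over-representation of `signature` by a
#' one-sided Fisher exact test within `universe`. Layers with an empty
#' neighborhood are recorded as non-informative (NA statistics).
#'
#' @param network directed network.
#' @param node source gene (typically the anchor).
#' @param signature gene set to test (subset of `universe`).
#' @param k_max deepest layer tested.
#' @param universe background gene set (defaults to the network's nodes).
#' @return data.frame with one row per layer (layer, neighborhood_size,
#'   overlap, p, fold_enrichment).
#' @export
layer_enrichment_profile <- function(network, node, signature, k_max = 6,
                                     universe = NULL) {
  k_max <- assert_count(k_max, "k_max")
  universe <- unique(universe %||% network_nodes(network))
  signature <- intersect(unique(signature), universe)
  if (!length(signature)) stop("signature empty within universe", call. = FALSE)
  rows <- lapply(seq_len(k_max), function(k) {
    nb <- downstream_neighborhood(network, node, k)
    nb <- intersect(nb, universe)
    if (!length(nb))
      return(data.frame(layer = k, neighborhood_size = 0L, overlap = 0L,
                        p = NA_real_, fold_enrichment = NA_real_))
    fe <- fisher_enrichment(nb, signature, universe)
    data.frame(layer = k, neighborhood_size = length(nb),
               overlap = fe$overlap, p = fe$p,
               fold_enrichment = fe$fold_enrichment)
  })
  do.call(rbind, rows)
}

#' Key-driver analysis of a directed network
#'
#' For every node with a non-empty h-layer downstream neighborhood, tests the
#' neighborhood for over-representation of `target_set` (one-sided Fisher
#' exact test, universe = network nodes), BH-adjusts across tested nodes,
#' and calls drivers at `fdr < fdr_cutoff`. Nodes are ranked by p, then by
#' neighborhood size (descending), then by name.
#'
#' @param network directed network.
#' @param target_set gene set whose regulators are sought; must intersect
#'   the network's nodes.
#' @param h neighborhood depth (default 6).
#' @param fdr_cutoff driver call threshold on the BH-adjusted p (default
#'   0.05).
#' @return data.frame (node, layer, neighborhood_size, overlap, p, fdr,
#'   is_driver), ranked; leaf nodes (empty neighborhoods) are excluded.
#' @export
key_driver_analysis <- function(network, target_set, h = 6,
                                fdr_cutoff = 0.05) {
  h <- assert_count(h, "h")
  nodes <- network_nodes(network)
  if (!length(nodes)) stop("empty network", call. = FALSE)
  target_set <- intersect(unique(target_set), nodes)
  if (!length(target_set))
    stop("`target_set` does not intersect the network", call. = FALSE)
  ig <- edges_to_igraph(as_edge_df(network), nodes)
  dmat <- igraph::distances(ig, mode = "out")
  rows <- lapply(nodes, function(v) {
    d <- dmat[v, ]
    nb <- names(d)[is.finite(d) & d >= 1 & d <= h]
    if (!length(nb)) return(NULL)
    fe <- fisher_enrichment(nb, target_set, nodes)
    data.frame(node = v, layer = h, neighborhood_size = length(nb),
               overlap = fe$overlap, p = fe$p,
               fold_enrichment = fe$fold_enrichment,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no node has a non-empty neighborhood", call. = FALSE)
  out$fdr <- p.adjust(out$p, "BH")
  out$is_driver <- out$fdr < fdr_cutoff
  out <- out[order(out$p, -out$neighborhood_size, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}
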