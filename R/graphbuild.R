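# Analysis-subgraph construction: shortest-path extraction from source
# pathways to observed genes, and degree-one compaction of unobserved
# nodes with sign-preserving rewiring.

#' Extract the shortest-path subgraph from sources to targets
#'
#' For every target reachable from a source, keeps the union of *all*
#' tied shortest directed paths (unweighted edge count) from each source.
#' Edge signs are preserved; when parallel opposite-sign edges connect two
#' consecutive path nodes, both are kept. Targets unreachable from every
#' source are dropped and reported.
#'
#' @param graph A `signed_graph`.
#' @param sources Nonempty character vector of source node ids (e.g. the
#'   receptors of the queried pathways).
#' @param targets Character vector of target node ids (e.g. the variant
#'   genes).
#' @return A `signed_graph` restricted to the kept nodes/edges, with
#'   attribute `"dropped_targets"` listing unreachable targets. Inputs are
#'   the retained declared inputs plus any node left without predecessors.
#' @export
extract_subgraph <- function(graph, sources, targets) {
  stopifnot(inherits(graph, "signed_graph"))
  sources <- unique(as.character(sources))
  targets <- unique(as.character(targets))
  if (length(sources) == 0L) stop("at least one source node is required")
  if (!all(sources %in% graph$nodes)) stop("unknown source node(s)")
  if (!all(targets %in% graph$nodes)) stop("unknown target node(s)")
  ig <- as_igraph(graph)
  keep_nodes <- character(0)
  keep_pairs <- character(0)
  reached <- character(0)
  for (s in sources) {
    d <- igraph::distances(ig, v = s, to = targets, mode = "out")
    ok <- targets[is.finite(d[1, ])]
    reached <- union(reached, ok)
    if (length(ok) == 0L) next
    paths <- igraph::all_shortest_paths(ig, from = s, to = ok,
                                        mode = "out")$vpaths
    for (p in paths) {
      nm <- names(p)
      keep_nodes <- c(keep_nodes, nm)
      if (length(nm) > 1L) {
        keep_pairs <- c(keep_pairs,
                        paste(nm[-length(nm)], nm[-1L], sep = "\r"))
      }
    }
  }
  keep_nodes <- unique(keep_nodes)
  keep_pairs <- unique(keep_pairs)
  es <- graph$edges
  keep_edge <- paste(es$source, es$target, sep = "\r") %in% keep_pairs
  sub_edges <- es[keep_edge, , drop = FALSE]
  dropped <- setdiff(targets, reached)
  sub <- signed_graph(
    data.frame(source = sub_edges$source, sign = as_sign_chr(sub_edges$sign),
               target = sub_edges$target, stringsAsFactors = FALSE),
    nodes = keep_nodes,
    roles = graph$roles[keep_nodes],
    inputs = union(intersect(graph$inputs, keep_nodes),
                   setdiff(keep_nodes, unique(sub_edges$target))))
  attr(sub, "dropped_targets") <- dropped
  sub
}

#' Compact a graph by removing unobserved degree-one nodes
#'
#' Iteratively deletes every node that is not observed (and not a declared
#' input) and has exactly one predecessor or exactly one successor, rewiring
#' each (predecessor, successor) pair into a direct edge whose sign is the
#' product of the two traversed signs. Removals that would create a
#' self-loop are skipped. The sweep visits nodes in sorted id order and
#' repeats to a fixpoint, so the result is deterministic. This compaction
#' preserves the coloring model on the retained nodes.
#'
#' @param graph A `signed_graph`.
#' @param observed Character vector of protected (observed) nodes; defaults
#'   to the graph's gene nodes.
#' @return The compacted `signed_graph` (same inputs, roles restricted).
#' @examples
#' g <- signed_graph(data.frame(source = c("A", "X"), sign = c("+", "-"),
#'                              target = c("X", "G")),
#'                   roles = c(G = "gene"))
#' compact_graph(g)$edges # single edge A -> G with sign -1
#' @export
compact_graph <- function(graph, observed = observable_genes(graph)) {
  stopifnot(inherits(graph, "signed_graph"))
  if (!all(observed %in% graph$nodes)) stop("observed nodes must be in the graph")
  nodes <- graph$nodes
  es <- graph$edges
  protected <- union(observed, graph$inputs)
  repeat {
    changed <- FALSE
    for (v in sort(setdiff(nodes, protected))) {
      in_idx <- which(es$target == v)
      out_idx <- which(es$source == v)
      if (length(in_idx) != 1L && length(out_idx) != 1L) next
      preds <- es$source[in_idx]
      succs <- es$target[out_idx]
      if (v %in% c(preds, succs)) next            # self-loop on v
      if (length(intersect(preds, succs))) next   # removal would create one
      new_edges <- NULL
      if (length(in_idx) && length(out_idx)) {
        grid <- expand.grid(i = in_idx, o = out_idx)
        new_edges <- data.frame(
          source = es$source[grid$i],
          target = es$target[grid$o],
          sign = es$sign[grid$i] * es$sign[grid$o],
          stringsAsFactors = FALSE)
      }
      es <- es[-c(in_idx, out_idx), , drop = FALSE]
      if (!is.null(new_edges)) es <- rbind(es, new_edges)
      es <- es[!duplicated(paste(es$source, es$target, es$sign)), ,
               drop = FALSE]
      nodes <- setdiff(nodes, v)
      changed <- TRUE
    }
    if (!changed) break
  }
  signed_graph(
    data.frame(source = es$source, sign = as_sign_chr(es$sign),
               target = es$target, stringsAsFactors = FALSE),
    nodes = nodes,
    roles = graph$roles[nodes],
    inputs = intersect(graph$inputs, nodes))
}

#' Count observed genes downstream of a node
#'
#' Connectivity annotation for ranked nodes: how many observed genes are
#' reachable by directed paths from the node, reported against the total
#' number of observed genes (e.g. "8/529").
#'
#' @param graph A `signed_graph`.
#' @param node A node id.
#' @param observed Character vector of observed gene ids; defaults to the
#'   graph's gene nodes.
#' @return Named integer vector `c(downstream =, total_observed =)`.
#' @export
count_connected_genes <- function(graph, node,
                                  observed = observable_genes(graph)) {
  stopifnot(inherits(graph, "signed_graph"))
  if (!node %in% graph$nodes) stop("unknown node: ", node)
  ig <- as_igraph(graph)
  reach <- names(igraph::subcomponent(ig, node, mode = "out"))
  down <- length(intersect(setdiff(reach, node), observed))
  c(downstream = down, total_observed = length(observed))
}
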