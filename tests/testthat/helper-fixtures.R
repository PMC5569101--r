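# Small graphs used across tests.

# A -(+)-> B, A -(-)-> C; A is the only input.
fork_graph <- function() {
  signed_graph(data.frame(source = "A", sign = c("+", "-"),
                          target = c("B", "C")),
               roles = c(B = "gene", C = "gene"))
}

# A -(+)-> B -(+)-> C chain.
chain_graph <- function(signs = c("+", "+"), roles = NULL) {
  signed_graph(data.frame(source = c("A", "B"), sign = signs,
                          target = c("B", "C")),
               roles = roles)
}

# Star: one input `hub` activating m observed leaves.
star_graph <- function(m = 6) {
  leaves <- sprintf("g%d", seq_len(m))
  signed_graph(data.frame(source = "hub", sign = "+", target = leaves),
               roles = stats::setNames(rep("gene", m), leaves))
}

# Random signed graph + roles for property tests; guarantees >= 1 gene.
random_graph <- function(n_nodes, p_edge = 0.3, p_inh = 0.4,
                         p_gene = 0.5, seed = 1) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n_nodes))
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  ed <- pairs[runif(nrow(pairs)) < p_edge, , drop = FALSE]
  ed$sign <- ifelse(runif(nrow(ed)) < p_inh, "-", "+")
  genes <- ids[runif(n_nodes) < p_gene]
  if (length(genes) == 0L) genes <- ids[1]
  signed_graph(ed[, c("source", "sign", "target")], nodes = ids,
               roles = stats::setNames(rep("gene", length(genes)), genes))
}

# A random partial labeling over the graph's genes (possibly inconsistent).
random_labeling <- function(graph, p_obs = 0.8, seed = 1) {
  set.seed(seed)
  genes <- observable_genes(graph)
  obs <- genes[runif(length(genes)) < p_obs]
  labeling(stats::setNames(sample(c("+", "-", "0"), length(obs),
                                  replace = TRUE), obs))
}
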