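# Signed directed influence graphs and partial sign labelings.

#' Construct a signed influence graph
#'
#' A directed graph whose edges carry activation (`"+"`) or inhibition
#' (`"-"`) signs, whose nodes carry a role (`"gene"` for observable
#' transcripts, `"species"` for unobserved proteins, complexes or events),
#' and which declares a set of *input* nodes exempt from the consistency
#' rules. Parallel edges between the same pair of nodes are allowed when
#' their signs differ (a regulator documented to both activate and inhibit);
#' duplicated edges with identical sign are rejected.
#'
#' @param edges A data.frame with columns `source`, `sign`, `target`
#'   (column order free); `sign` in `{"+", "-"}`.
#' @param nodes Optional character vector of node ids; defaults to the edge
#'   endpoints. Extra isolated nodes may be declared here.
#' @param roles Optional named character vector mapping node ids to
#'   `"gene"` or `"species"`; unnamed nodes default to `"species"`.
#' @param inputs Optional character vector of input node ids. Defaults to
#'   the nodes with no predecessor.
#' @return An object of class `signed_graph` with components `nodes`,
#'   `roles`, `edges` (data.frame `source`, `target`, `sign` with integer
#'   signs 1/-1) and `inputs`.
#' @examples
#' g <- signed_graph(data.frame(source = "A", sign = c("+", "-"),
#'                              target = c("B", "C")))
#' g$inputs # "A"
#' @export
signed_graph <- function(edges, nodes = NULL, roles = NULL, inputs = NULL) {
  if (is.null(edges)) edges <- data.frame(source = character(0),
                                          sign = character(0),
                                          target = character(0))
  stopifnot(is.data.frame(edges),
            all(c("source", "sign", "target") %in% names(edges)))
  src <- as.character(edges$source)
  tgt <- as.character(edges$target)
  sgn <- as_sign_int(edges$sign)
  if (any(sgn == 0L)) stop("edge signs must be '+' or '-'")
  all_nodes <- unique(c(as.character(nodes), src, tgt))
  if (length(all_nodes) == 0L) stop("graph must have at least one node")
  if (anyDuplicated(paste(src, tgt, sgn))) {
    stop("duplicate edges with identical (source, target, sign)")
  }
  role <- stats::setNames(rep("species", length(all_nodes)), all_nodes)
  if (!is.null(roles)) {
    roles <- unlist(roles)
    if (is.null(names(roles)) || !all(names(roles) %in% all_nodes)) {
      stop("roles must be a named vector over declared nodes")
    }
    if (!all(roles %in% c("gene", "species"))) {
      stop("roles must be 'gene' or 'species'")
    }
    role[names(roles)] <- roles
  }
  if (is.null(inputs)) {
    inputs <- setdiff(all_nodes, unique(tgt))
  } else {
    inputs <- as.character(inputs)
    if (!all(inputs %in% all_nodes)) stop("inputs must be declared nodes")
  }
  structure(list(nodes = all_nodes,
                 roles = role,
                 edges = data.frame(source = src, target = tgt, sign = sgn,
                                    stringsAsFactors = FALSE),
                 inputs = inputs),
            class = "signed_graph")
}

#' @export
print.signed_graph <- function(x, ...) {
  cat(sprintf("signed_graph: %d nodes (%d genes), %d edges, %d inputs\n",
              length(x$nodes), sum(x$roles == "gene"),
              nrow(x$edges), length(x$inputs)))
  invisible(x)
}

#' Observable gene nodes of a graph
#'
#' @param graph A `signed_graph`.
#' @return Character vector of node ids with role `"gene"`.
#' @export
observable_genes <- function(graph) {
  stopifnot(inherits(graph, "signed_graph"))
  names(graph$roles)[graph$roles == "gene"]
}

# igraph view of the topology; edge attribute `sign` carries 1/-1.
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("source", "target", "sign")],
    directed = TRUE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE))
}

#' Construct a partial sign labeling for one profile
#'
#' @param signs Named vector of signs (`"+"`, `"-"`, `"0"`), names are node
#'   ids observed in this profile.
#' @param profile_id Identifier of the profile the observations belong to.
#' @return An object of class `labeling` with components `profile_id` and
#'   `signs` (named integer vector, 1/-1/0).
#' @export
labeling <- function(signs, profile_id = "profile") {
  si <- as_sign_int(signs)
  if (length(si) && (is.null(names(si)) || any(!nzchar(names(si))))) {
    stop("all observed signs must be named by node id")
  }
  if (anyDuplicated(names(si))) stop("duplicated node ids in labeling")
  structure(list(profile_id = as.character(profile_id), signs = si),
            class = "labeling")
}

#' @export
print.labeling <- function(x, ...) {
  cat(sprintf("labeling '%s': %d observed nodes (+:%d -:%d 0:%d)\n",
              x$profile_id, length(x$signs), sum(x$signs == 1L),
              sum(x$signs == -1L), sum(x$signs == 0L)))
  invisible(x)
}

#' Restrict a labeling to a set of nodes
#'
#' Used to align observation files with the node namespace of a graph
#' before solving (expression matrices usually contain genes absent from
#' the regulatory graph).
#'
#' @param beta A `labeling`.
#' @param nodes Character vector of node ids to keep.
#' @return The restricted `labeling`.
#' @export
restrict_labeling <- function(beta, nodes) {
  stopifnot(inherits(beta, "labeling"))
  labeling(beta$signs[names(beta$signs) %in% nodes], beta$profile_id)
}

check_labeling_nodes <- function(graph, beta) {
  missing <- setdiff(names(beta$signs), graph$nodes)
  if (length(missing)) {
    stop("labeled node(s) not in graph: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a signed graph from TSV files
#'
#' The edge file is a tab-separated table with header columns
#' `source`, `sign`, `target` (sign in `{"+", "-"}`). The optional role file
#' has columns `node`, `role` (role in `{"gene", "species"}`); the optional
#' input file lists one node id per line.
#'
#' @param edge_file Path to the edge TSV.
#' @param role_file Optional path to the node-role TSV.
#' @param input_file Optional path to the inputs list.
#' @return A `signed_graph`.
#' @export
read_signed_graph <- function(edge_file, role_file = NULL, input_file = NULL) {
  ed <- utils::read.delim(edge_file, colClasses = "character")
  roles <- NULL
  if (!is.null(role_file)) {
    rd <- utils::read.delim(role_file, colClasses = "character")
    stopifnot(all(c("node", "role") %in% names(rd)))
    roles <- stats::setNames(rd$role, rd$node)
  }
  inputs <- if (!is.null(input_file)) readLines(input_file) else NULL
  inputs <- inputs[nzchar(inputs)]
  if (length(inputs) == 0L) inputs <- NULL
  signed_graph(ed, nodes = names(roles), roles = roles, inputs = inputs)
}

#' Write a signed graph to TSV files
#'
#' @param graph A `signed_graph`.
#' @param edge_file Path for the edge TSV.
#' @param role_file Optional path for the node-role TSV.
#' @param input_file Optional path for the inputs list.
#' @return Invisibly, `graph`.
#' @export
write_signed_graph <- function(graph, edge_file, role_file = NULL,
                               input_file = NULL) {
  stopifnot(inherits(graph, "signed_graph"))
  ed <- data.frame(source = graph$edges$source,
                   sign = as_sign_chr(graph$edges$sign),
                   target = graph$edges$target)
  utils::write.table(ed, edge_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(role_file)) {
    utils::write.table(data.frame(node = graph$nodes,
                                  role = unname(graph$roles[graph$nodes])),
                       role_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(input_file)) writeLines(graph$inputs, input_file)
  invisible(graph)
}

#' Read per-profile observations from a TSV file
#'
#' Expects header columns `node`, `sign` with sign in `{"+", "-", "0"}`.
#'
#' @param file Path to the observation TSV.
#' @param profile_id Profile identifier; defaults to the file base name.
#' @return A `labeling`.
#' @export
read_observations <- function(file,
                              profile_id = sub("\\.[^.]*$", "", basename(file))) {
  d <- utils::read.delim(file, colClasses = "character")
  stopifnot(all(c("node", "sign") %in% names(d)))
  labeling(stats::setNames(d$sign, d$node), profile_id)
}

#' Write a labeling to an observation TSV file
#'
#' @param beta A `labeling`.
#' @param file Output path.
#' @return Invisibly, `beta`.
#' @export
write_observations <- function(beta, file) {
  stopifnot(inherits(beta, "labeling"))
  utils::write.table(data.frame(node = names(beta$signs),
                                sign = as_sign_chr(beta$signs)),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(beta)
}
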