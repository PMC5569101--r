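# Sign-consistency reasoning core: local consistency rules, exact
# enumeration of colorings, MCOS and SCENFIT repairs, sign projection.
#
# A coloring assigns every node a sign in {+, -, 0}. Local rules:
#   R1  input nodes are consistent unconditionally;
#   R2  a non-input variant node needs at least one predecessor whose
#       transmitted influence equals its sign;
#   R3  a non-input invariant node needs either all predecessor influences
#       invariant, or two predecessors with opposite variant influences.
#
# The engine materialises the candidate coloring space (3^k for k free
# nodes, bounded) as an integer matrix and evaluates the rules vectorised
# per node over all candidates. The set of rule-violating nodes of each
# candidate directly yields the MCOS repairs: exempting exactly those nodes
# makes the candidate consistent, and every cardinality-minimal correction
# set is the violation set of some candidate.

default_bound <- function() getOption("signcon.brute_force_bound", 12L)

# Enumerate all colorings with `fixed` (named int vector) clamped.
# Returns list(mu = integer matrix nodes x candidates, viol = logical matrix).
coloring_space <- function(graph, fixed = integer(0), bound = default_bound()) {
  nodes <- graph$nodes
  fixed <- as_sign_int(fixed)
  if (length(fixed)) check_labeling_nodes(graph, list(signs = fixed))
  free <- setdiff(nodes, names(fixed))
  k <- length(free)
  if (k > bound) {
    stop(sprintf(paste0("exhaustive enumeration refused: %d free nodes ",
                        "exceed the bound of %d (raise `bound` or reduce ",
                        "the problem)"), k, bound))
  }
  n_cand <- 3L^k
  mu <- matrix(0L, nrow = length(nodes), ncol = n_cand,
               dimnames = list(nodes, NULL))
  if (length(fixed)) mu[names(fixed), ] <- fixed
  if (k > 0L) {
    idx <- 0:(n_cand - 1L)
    for (j in seq_len(k)) {
      mu[free[j], ] <- .sign_int[(idx %/% 3L^(j - 1L)) %% 3L + 1L]
    }
  }
  list(mu = mu, viol = violation_matrix(graph, mu))
}

# Logical matrix nodes x candidates: TRUE where a node violates its local
# rule in that candidate coloring. Input nodes never violate.
violation_matrix <- function(graph, mu) {
  n_cand <- ncol(mu)
  nodes <- graph$nodes
  viol <- matrix(FALSE, nrow = length(nodes), ncol = n_cand,
                 dimnames = list(nodes, NULL))
  row_of <- stats::setNames(seq_along(nodes), nodes)
  es <- graph$edges
  tgt_rows <- split(seq_len(nrow(es)), es$target)
  for (n in setdiff(nodes, graph$inputs)) {
    v <- mu[row_of[[n]], ]
    rows <- tgt_rows[[n]]
    if (is.null(rows)) {            # no predecessors: only 0 is explained
      viol[row_of[[n]], ] <- v != 0L
      next
    }
    has_p <- rep(FALSE, n_cand)
    has_m <- rep(FALSE, n_cand)
    all_z <- rep(TRUE, n_cand)
    for (i in rows) {
      inf <- es$sign[i] * mu[row_of[[es$source[i]]], ]
      has_p <- has_p | inf == 1L
      has_m <- has_m | inf == -1L
      all_z <- all_z & inf == 0L
    }
    ok <- (v == 1L & has_p) |
          (v == -1L & has_m) |
          (v == 0L & (all_z | (has_p & has_m)))
    viol[row_of[[n]], ] <- !ok
  }
  viol
}

#' Check a total coloring for sign consistency
#'
#' A coloring is consistent when every non-input node's sign is explained
#' by its direct predecessors: a variant node needs at least one activator
#' of the same sign or inhibitor of the opposite sign; an invariant node
#' needs either only invariant influences or two opposite variant
#' influences. Declared input nodes are consistent unconditionally.
#'
#' @param graph A `signed_graph`.
#' @param mu Named vector assigning a sign (`"+"`, `"-"`, `"0"`) to every
#'   graph node.
#' @return `TRUE` or `FALSE`.
#' @export
is_consistent_coloring <- function(graph, mu) {
  stopifnot(inherits(graph, "signed_graph"))
  mi <- as_sign_int(mu)
  if (!setequal(names(mi), graph$nodes) || length(mi) != length(graph$nodes)) {
    stop("mu must assign exactly one sign to every graph node")
  }
  m <- matrix(mi[graph$nodes], ncol = 1, dimnames = list(graph$nodes, NULL))
  !any(violation_matrix(graph, m))
}

#' Enumerate all consistent colorings extending a labeling
#'
#' Exhaustively enumerates the `3^k` colorings over the `k` unobserved
#' nodes and keeps those satisfying the consistency rules.
#'
#' @param graph A `signed_graph`.
#' @param beta A `labeling` (possibly empty).
#' @param bound Maximum number of free nodes accepted (default 12, option
#'   `signcon.brute_force_bound`); beyond it the call is refused.
#' @return A character matrix, rows = nodes, one column per consistent
#'   coloring (possibly zero columns).
#' @export
enumerate_colorings <- function(graph, beta = labeling(character(0)),
                                bound = default_bound()) {
  stopifnot(inherits(graph, "signed_graph"), inherits(beta, "labeling"))
  check_labeling_nodes(graph, beta)
  sp <- coloring_space(graph, beta$signs, bound)
  keep <- colSums(sp$viol) == 0L
  mu <- sp$mu[, keep, drop = FALSE]
  matrix(as_sign_chr(mu), nrow = nrow(mu), dimnames = list(rownames(mu), NULL))
}

#' Projection class of a set of signs
#'
#' Maps the nonempty subsets of `{+, -, 0}` to the seven projection
#' classes: the strong classes `"+"`, `"-"`, `"0"` (one sign across all
#' consistent colorings), the weak classes `"Not+"` (`{-,0}`), `"Not-"`
#' (`{+,0}`), `"change"` (`{+,-}`), and `"?"` (all three signs).
#'
#' @param signs Vector of signs (duplicates allowed).
#' @return The class label, a character scalar.
#' @export
projection_class <- function(signs) {
  si <- unique(as_sign_int(signs))
  if (length(si) == 0L) stop("projection of an empty sign set is undefined")
  key <- paste0(as.integer(1L %in% si), as.integer(-1L %in% si),
                as.integer(0L %in% si))
  switch(key,
         "100" = "+", "010" = "-", "001" = "0",
         "011" = "Not+", "101" = "Not-", "110" = "change",
         "111" = "?")
}

#' Project node signs across a set of colorings
#'
#' Summarises, for each node, the set of signs it takes across all supplied
#' consistent colorings as one of the seven projection classes.
#'
#' @param colorings A character matrix as returned by
#'   [enumerate_colorings()] (rows = nodes, columns = colorings), or a list
#'   of named sign vectors.
#' @param nodes Nodes to project; defaults to all.
#' @return Named character vector of projection class labels.
#' @export
project_signs <- function(colorings, nodes = NULL) {
  if (is.list(colorings) && !is.matrix(colorings)) {
    if (length(colorings) == 0L) stop("projection over zero colorings is undefined")
    nms <- names(colorings[[1L]])
    colorings <- vapply(colorings, function(m) as_sign_chr(m[nms]),
                        character(length(nms)))
    if (is.null(dim(colorings))) colorings <- matrix(colorings, nrow = length(nms))
    rownames(colorings) <- nms
  }
  if (ncol(colorings) == 0L) stop("projection over zero colorings is undefined")
  if (is.null(nodes)) nodes <- rownames(colorings)
  out <- vapply(nodes, function(n) projection_class(colorings[n, ]),
                character(1))
  stats::setNames(out, nodes)
}

switch_cost_matrix <- function(old, new_mat) {
  # old: scalar int sign; new_mat: integer vector of signs. Costs per the
  # repair model: variant flip 2, variant<->invariant 1, identical 0.
  cost <- integer(length(new_mat))
  diff <- new_mat != old
  inv <- (old == 0L) | (new_mat == 0L)
  cost[diff & inv] <- 1L
  cost[diff & !inv] <- 2L
  cost
}

#' Restore consistency by minimal repairs (MCOS or SCENFIT)
#'
#' Confronts a partial labeling with the graph and, when no consistent
#' coloring extends it, computes *all* minimal repairs:
#'
#' * **MCOS** corrects the graph: the minimal-cardinality sets of non-input
#'   nodes granted an artificial influence (exempting them from the
#'   consistency rules, equivalent to adding an edge from a fresh
#'   unconstrained input). The score is the number of exempted nodes.
#' * **SCENFIT** corrects the data: the minimal-cost sets of sign switches
#'   on observed nodes, a variant-to-opposite-variant switch costing 2 and
#'   a variant/invariant switch costing 1. The score is the total cost.
#'
#' In both modes the consistent colorings under all minimal repairs are
#' pooled (their union defines the sign projections); a consistent input
#' returns score 0 with the unrepaired colorings.
#'
#' @param graph A `signed_graph`.
#' @param beta A `labeling` of observed nodes.
#' @param mode `"mcos"` or `"scenfit"`.
#' @param interventions Optional named sign vector of clamped nodes
#'   (perturbations): they are fixed in every coloring and, under SCENFIT,
#'   never switchable and never charged.
#' @param bound Free-node bound for the exhaustive engine (see
#'   [enumerate_colorings()]). Under SCENFIT every non-clamped node is
#'   free, because observed nodes may switch.
#' @return An object of class `repair_result`: list with `mode`, `score`
#'   (0 when already consistent; `Inf` if interventions are infeasible),
#'   `repairs` (list of repair sets: character vectors of exempted nodes
#'   for MCOS, data.frames `node`/`from`/`to` for SCENFIT), `colorings`
#'   (character matrix of pooled consistent colorings) and `projections`
#'   (named vector of projection classes).
#' @examples
#' g <- signed_graph(data.frame(source = "A", sign = c("+", "-"),
#'                              target = c("B", "C")))
#' r <- solve_consistency(g, labeling(c(B = "+", C = "+")), "mcos")
#' r$score          # 1
#' r$projections["A"] # "change"
#' @export
solve_consistency <- function(graph, beta = labeling(character(0)),
                              mode = c("mcos", "scenfit"),
                              interventions = NULL,
                              bound = default_bound()) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "signed_graph"), inherits(beta, "labeling"))
  check_labeling_nodes(graph, beta)
  iv <- if (is.null(interventions)) integer(0) else as_sign_int(interventions)
  if (length(iv)) {
    check_labeling_nodes(graph, list(signs = iv))
    clash <- intersect(names(iv), names(beta$signs))
    if (length(clash)) {
      stop("intervention on already-observed node(s): ",
           paste(clash, collapse = ", "))
    }
  }

  if (mode == "mcos") {
    fixed <- c(beta$signs, iv)
    sp <- coloring_space(graph, fixed, bound)
    nv <- colSums(sp$viol)
    score <- min(nv)
    sel <- which(nv == score)
    repairs <- unique(lapply(sel, function(j) {
      sort(rownames(sp$viol)[sp$viol[, j]])
    }))
    mu <- sp$mu[, sel, drop = FALSE]
  } else {
    sp <- coloring_space(graph, iv, bound)
    cons <- colSums(sp$viol) == 0L
    if (!any(cons)) {
      return(structure(list(mode = mode, score = Inf, repairs = list(),
                            colorings = matrix(character(0),
                                               nrow = length(graph$nodes),
                                               dimnames = list(graph$nodes, NULL)),
                            projections = NULL),
                       class = "repair_result"))
    }
    cost <- rep(0L, ncol(sp$mu))
    for (n in names(beta$signs)) {
      cost <- cost + switch_cost_matrix(beta$signs[[n]], sp$mu[n, ])
    }
    score <- min(cost[cons])
    sel <- which(cons & cost == score)
    repairs <- unique(lapply(sel, function(j) {
      ch <- names(beta$signs)[sp$mu[names(beta$signs), j] != beta$signs]
      ch <- sort(ch)
      data.frame(node = ch,
                 from = unname(as_sign_chr(beta$signs[ch])),
                 to = unname(as_sign_chr(sp$mu[ch, j])),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
    mu <- sp$mu[, sel, drop = FALSE]
  }
  colorings <- matrix(as_sign_chr(mu), nrow = nrow(mu),
                      dimnames = list(rownames(mu), NULL))
  structure(list(mode = mode,
                 score = if (is.infinite(score)) Inf else as.integer(score),
                 repairs = repairs,
                 colorings = colorings,
                 projections = project_signs(colorings)),
            class = "repair_result")
}

#' @export
print.repair_result <- function(x, ...) {
  cat(sprintf("repair_result (%s): score %s, %d minimal repair set(s), %d coloring(s)\n",
              toupper(x$mode), format(x$score), length(x$repairs),
              ncol(x$colorings)))
  invisible(x)
}

#' Write the result of a consistency solve to disk
#'
#' Emits a JSON summary (`score`, number of repair sets, repairs,
#' projections) and a tab-separated projection table.
#'
#' @param result A `repair_result`.
#' @param json_file,tsv_file Output paths (either may be `NULL` to skip).
#' @return Invisibly, `result`.
#' @export
write_repair_result <- function(result, json_file = NULL, tsv_file = NULL) {
  stopifnot(inherits(result, "repair_result"))
  if (!is.null(json_file)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite is required to write the JSON summary")
    }
    repairs <- lapply(result$repairs, function(r) {
      if (is.data.frame(r)) r else as.list(r)
    })
    jsonlite::write_json(list(mode = result$mode, score = result$score,
                              n_repair_sets = length(result$repairs),
                              repairs = repairs,
                              projections = as.list(result$projections)),
                         json_file, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_file)) {
    utils::write.table(data.frame(node = names(result$projections),
                                  class = unname(result$projections)),
                       tsv_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(result)
}
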