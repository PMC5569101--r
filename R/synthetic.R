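# Synthetic study generator: random signed graphs, planted-consistent
# labelings, controlled corruptions with known repair cost, and two-class
# expression matrices with a reference baseline, planted shifts and
# Gaussian noise. Every generator is deterministic under its seed.

#' Specification of a synthetic study
#'
#' Defaults describe a desk-scale two-class study: a sparse signed graph
#' of 10 nodes, half of them observable genes, an imbalanced design with
#' more case (`MC`) than reference (`NPC`) profiles, expression shifts of
#' 0.5 log2 units on 3 variant genes over a Normal(7, 1) baseline with
#' noise sd 0.1 — magnitudes typical of normalised microarray data and
#' compatible with the reference thresholds (k1, k2) = (0.03, 0.2).
#'
#' @param n_nodes Number of graph nodes.
#' @param edge_density Probability of each ordered node pair carrying an
#'   edge.
#' @param p_inhibition Probability that an edge is an inhibition.
#' @param p_observed Fraction of nodes flagged as observable genes.
#' @param n_profiles_per_class Named integer vector, profiles per class;
#'   names are the class labels and the second is the reference class.
#' @param n_variant_genes Number of genes shifted in the case class.
#' @param shift Absolute expression shift of variant genes (log2 units).
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @param seed Integer seed.
#' @param dag If `TRUE`, only generate acyclic graphs.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 10, edge_density = 0.15,
                           p_inhibition = 0.3, p_observed = 0.5,
                           n_profiles_per_class = c(MC = 6, NPC = 3),
                           n_variant_genes = 3, shift = 0.5,
                           noise_sd = 0.1, seed = 1, dag = FALSE) {
  stopifnot(n_nodes >= 1,
            edge_density >= 0, edge_density <= 1,
            p_inhibition >= 0, p_inhibition <= 1,
            p_observed >= 0, p_observed <= 1,
            length(n_profiles_per_class) == 2,
            !is.null(names(n_profiles_per_class)),
            all(n_profiles_per_class >= 1),
            n_variant_genes >= 0, shift >= 0, noise_sd >= 0)
  structure(list(n_nodes = as.integer(n_nodes),
                 edge_density = edge_density,
                 p_inhibition = p_inhibition,
                 p_observed = p_observed,
                 n_profiles_per_class = n_profiles_per_class,
                 n_variant_genes = as.integer(n_variant_genes),
                 shift = shift, noise_sd = noise_sd,
                 seed = as.integer(seed), dag = isTRUE(dag)),
            class = "synthetic_spec")
}

#' Generate a random signed influence graph
#'
#' Directed edges are drawn independently per ordered node pair with
#' probability `edge_density` (restricted to a random topological order in
#' DAG mode) and signed `-` with probability `p_inhibition`. Sink-side
#' nodes (lowest out-degree) are flagged as observable genes; inputs
#' default to the nodes without predecessors.
#'
#' @param spec A `synthetic_spec`.
#' @return A `signed_graph`.
#' @export
generate_graph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(source = ids, target = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  if (spec$dag) {
    ord <- stats::setNames(sample.int(n), ids)
    pairs <- pairs[ord[pairs$source] < ord[pairs$target], , drop = FALSE]
  }
  keep <- stats::runif(nrow(pairs)) < spec$edge_density
  ed <- pairs[keep, , drop = FALSE]
  if (nrow(ed) == 0L && n > 1L) {
    warning("edge density produced a graph with no edges")
  }
  ed$sign <- ifelse(stats::runif(nrow(ed)) < spec$p_inhibition, "-", "+")
  out_deg <- table(factor(ed$source, levels = ids))
  n_genes <- max(1L, round(spec$p_observed * n))
  genes <- ids[order(out_deg, sample.int(n))][seq_len(n_genes)]
  signed_graph(ed[, c("source", "sign", "target")], nodes = ids,
               roles = stats::setNames(rep("gene", n_genes), genes))
}

# Feasible signs for one node given its predecessors' integer signs and
# the incoming edge signs (both may be empty).
feasible_signs <- function(edge_signs, pred_signs) {
  inf <- edge_signs * pred_signs
  out <- integer(0)
  if (any(inf == 1L)) out <- c(out, 1L)
  if (any(inf == -1L)) out <- c(out, -1L)
  if (all(inf == 0L) || (any(inf == 1L) && any(inf == -1L))) out <- c(out, 0L)
  out
}

#' Plant a consistent coloring and its observable labeling
#'
#' Assigns uniform random signs to the input nodes, then colors the
#' remaining nodes along the condensation (strongly connected components
#' in topological order): acyclic nodes pick a random sign satisfying the
#' consistency rules given their predecessors; cyclic components are
#' colored by bounded exhaustive search over joint assignments (component
#' size capped at 8). The returned labeling restricts the coloring to the
#' observable gene nodes.
#'
#' @param graph A `signed_graph`.
#' @param seed Integer seed.
#' @param profile_id Profile id given to the labeling.
#' @return List with `coloring` (named sign vector over all nodes) and
#'   `labeling` (a `labeling` over the gene nodes).
#' @export
plant_consistent_labeling <- function(graph, seed = 1,
                                      profile_id = "planted") {
  stopifnot(inherits(graph, "signed_graph"))
  set.seed(seed)
  ig <- as_igraph(graph)
  comp <- igraph::components(ig, mode = "strong")
  memb <- comp$membership
  cond <- igraph::contract(ig, memb)
  cond <- igraph::simplify(cond)
  ord <- as.integer(igraph::topo_sort(cond, mode = "out"))
  es <- graph$edges
  mu <- stats::setNames(rep(NA_integer_, length(graph$nodes)), graph$nodes)
  for (cid in ord) {
    members <- names(memb)[memb == cid]
    internal <- es$source %in% members & es$target %in% members
    if (length(members) == 1L && !any(internal)) {
      v <- members
      if (v %in% graph$inputs) {
        mu[v] <- sample(.sign_int, 1L)
      } else {
        rows <- which(es$target == v)
        fs <- feasible_signs(es$sign[rows], mu[es$source[rows]])
        mu[v] <- fs[sample.int(length(fs), 1L)]
      }
    } else {
      if (length(members) > 8L) {
        stop("cyclic component of size ", length(members),
             " exceeds the planting bound of 8; regenerate the graph")
      }
      found <- FALSE
      n_cand <- 3L^length(members)
      for (code in sample.int(n_cand) - 1L) {
        cand <- .sign_int[(code %/% 3L^(seq_along(members) - 1L)) %% 3L + 1L]
        names(cand) <- members
        trial <- mu
        trial[members] <- cand
        ok <- TRUE
        for (v in members) {
          if (v %in% graph$inputs) next
          rows <- which(es$target == v)
          if (!trial[v] %in% feasible_signs(es$sign[rows],
                                            trial[es$source[rows]])) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          mu[members] <- cand
          found <- TRUE
          break
        }
      }
      if (!found) {
        stop("no consistent assignment found for a cyclic component; ",
             "regenerate the graph")
      }
    }
  }
  genes <- observable_genes(graph)
  list(coloring = as_sign_chr(mu),
       labeling = labeling(mu[genes], profile_id))
}

#' Corrupt a labeling with switches of known repair cost
#'
#' Flips `k` observed variant signs to their opposite (`"flip_variant"`,
#' cost 2 each under SCENFIT) or sets them invariant (`"to_invariant"`,
#' cost 1 each), recording the ground-truth switches.
#'
#' @param beta A `labeling`.
#' @param k Number of corrupted nodes; must not exceed the number of
#'   observed variant nodes.
#' @param mode `"flip_variant"` or `"to_invariant"`.
#' @param seed Integer seed.
#' @return List with `labeling` (corrupted) and `switches` (data.frame
#'   `node`, `from`, `to`).
#' @export
corrupt_labeling <- function(beta, k, mode = c("flip_variant", "to_invariant"),
                             seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(beta, "labeling"), k >= 0)
  set.seed(seed)
  eligible <- names(beta$signs)[beta$signs != 0L]
  if (k > length(eligible)) {
    stop("k exceeds the number of observed variant nodes (", length(eligible), ")")
  }
  picked <- if (k > 0) sample(eligible, k) else character(0)
  new_signs <- beta$signs
  to <- if (mode == "flip_variant") -beta$signs[picked] else
    stats::setNames(rep(0L, k), picked)
  new_signs[picked] <- to
  list(labeling = labeling(new_signs, beta$profile_id),
       switches = data.frame(node = picked,
                             from = unname(as_sign_chr(beta$signs[picked])),
                             to = unname(as_sign_chr(to)),
                             row.names = NULL, stringsAsFactors = FALSE))
}

#' Generate a two-class expression matrix with planted shifts
#'
#' Gene baselines are drawn once from Normal(7, 1) log2 units. Profiles of
#' the reference class fluctuate around the baseline with `noise_sd`;
#' profiles of the case class additionally shift `n_variant_genes`
#' randomly chosen genes by `+shift` or `-shift` (the planted sign map is
#' returned as ground truth, `"0"` for unshifted genes).
#'
#' @param graph A `signed_graph`; expression is generated for its gene
#'   nodes.
#' @param spec A `synthetic_spec`.
#' @return List with `expr` (an `expression_set`) and `truth` (named sign
#'   vector over genes describing the planted case-class shifts).
#' @export
generate_expression <- function(graph, spec) {
  stopifnot(inherits(graph, "signed_graph"), inherits(spec, "synthetic_spec"))
  genes <- observable_genes(graph)
  if (spec$n_variant_genes > length(genes)) {
    stop("n_variant_genes exceeds the number of gene nodes (",
         length(genes), ")")
  }
  set.seed(spec$seed + 1L)
  n_per <- spec$n_profiles_per_class
  case_class <- names(n_per)[1L]
  ref_class <- names(n_per)[2L]
  profs <- c(sprintf("%s_%02d", case_class, seq_len(n_per[[1L]])),
             sprintf("%s_%02d", ref_class, seq_len(n_per[[2L]])))
  classes <- stats::setNames(rep(names(n_per), n_per), profs)
  baseline <- stats::setNames(stats::rnorm(length(genes), 7, 1), genes)
  variant <- sample(genes, spec$n_variant_genes)
  truth <- stats::setNames(rep("0", length(genes)), genes)
  truth[variant] <- sample(c("+", "-"), spec$n_variant_genes, replace = TRUE)
  vals <- matrix(stats::rnorm(length(genes) * length(profs), 0, spec$noise_sd),
                 nrow = length(genes),
                 dimnames = list(genes, profs)) + baseline
  shift_vec <- ifelse(truth == "+", spec$shift,
                      ifelse(truth == "-", -spec$shift, 0))
  vals[, classes == case_class] <- vals[, classes == case_class] + shift_vec
  list(expr = expression_set(vals, classes), truth = truth)
}
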