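# In-silico single-node perturbations: SCENFIT score of an augmented
# labeling, nearest-rank top-quantile thresholds, and the Top Perturbation
# Score aggregated per profile class.

#' SCENFIT score of a single-node perturbation
#'
#' Adds an observation fixing `node` to `sign` on top of the profile's
#' labeling and returns the minimal SCENFIT repair cost. The added
#' observation is the intervention: it is clamped, never switchable and
#' never charged.
#'
#' @param graph A `signed_graph`.
#' @param beta The profile's `labeling`; `node` must be unobserved in it.
#' @param node The perturbed node id.
#' @param sign `"+"` (activation) or `"-"` (inhibition).
#' @param bound Free-node bound passed to the solver.
#' @return The SCENFIT score (nonnegative integer; `Inf` when the clamped
#'   sign admits no consistent coloring at all).
#' @export
perturb_and_score <- function(graph, beta, node, sign,
                              bound = default_bound()) {
  stopifnot(inherits(graph, "signed_graph"), inherits(beta, "labeling"))
  if (node %in% names(beta$signs)) {
    stop("node is already observed in the labeling: ", node)
  }
  if (!as_sign_chr(sign) %in% c("+", "-")) {
    stop("perturbations fix a variant sign, '+' or '-'")
  }
  solve_consistency(graph, beta, mode = "scenfit",
                    interventions = stats::setNames(sign, node),
                    bound = bound)$score
}

#' Nearest-rank top-quantile threshold
#'
#' The score separating the top `q` fraction of a score list: with K
#' scores sorted in decreasing order, the threshold is the
#' `ceiling(q * K)`-th largest value. Scores tied with the threshold all
#' count as top-ranked (`score >= threshold`).
#'
#' @param scores Nonempty numeric vector.
#' @param q Upper-quantile fraction in (0, 1].
#' @return The threshold value.
#' @examples
#' top_threshold(1:10, 0.1) # 10
#' @export
top_threshold <- function(scores, q = 0.10) {
  if (length(scores) == 0L) stop("scores must be nonempty")
  stopifnot(q > 0, q <= 1)
  m <- ceiling(q * length(scores))
  sort(scores, decreasing = TRUE)[m]
}

# SCENFIT scores of clamping each candidate to `sign` on one profile,
# sharing a single enumeration of the graph's consistent colorings.
scenfit_scores_batch <- function(graph, beta, candidates, sign,
                                 bound = default_bound()) {
  sp <- coloring_space(graph, integer(0), bound)
  cons <- colSums(sp$viol) == 0L
  cost <- rep(0L, ncol(sp$mu))
  for (n in names(beta$signs)) {
    cost <- cost + switch_cost_matrix(beta$signs[[n]], sp$mu[n, ])
  }
  si <- as_sign_int(sign)
  vapply(candidates, function(k) {
    sel <- cons & sp$mu[k, ] == si
    if (!any(sel)) Inf else min(cost[sel])
  }, numeric(1))
}

#' Top perturbation scores across profiles and classes
#'
#' For every profile and variant sign, computes the SCENFIT score of
#' clamping each candidate node to that sign, derives the profile's
#' nearest-rank top-`q` threshold over those scores, and flags the
#' candidates reaching it. The Top Perturbation Score of an assignment
#' `(node, sign)` in a class is the fraction of the class's profiles in
#' which the assignment is flagged; a one-sided Fisher test compares the
#' flag counts between the two classes.
#'
#' @param graph A `signed_graph`.
#' @param labelings Named list of per-profile `labeling`s.
#' @param classes Named character vector mapping profiles to classes.
#' @param candidates Candidate nodes; default: nodes observed in no
#'   profile. Each candidate must be unobserved in every profile.
#' @param q Top fraction (default 0.10).
#' @param class_a,class_b Classes compared by the Fisher test (flag count
#'   greater in `class_a`).
#' @param bound Free-node bound for the solver.
#' @return List with `scores` (long data.frame `node`, `sign`, `profile`,
#'   `sf`, `f`) and `table` (per (node, sign): `tps_<class_b>`,
#'   `tps_<class_a>`, `p`), the table sorted by ascending p.
#' @export
top_perturbation_scores <- function(graph, labelings, classes,
                                    candidates = NULL, q = 0.10,
                                    class_a = "MC", class_b = "NPC",
                                    bound = default_bound()) {
  stopifnot(inherits(graph, "signed_graph"), length(labelings) >= 1)
  profs <- names(labelings)
  missing_cls <- setdiff(profs, names(classes))
  if (length(missing_cls)) {
    stop("class map missing profile(s): ", paste(missing_cls, collapse = ", "))
  }
  observed_any <- unique(unlist(lapply(labelings, function(b) names(b$signs))))
  if (is.null(candidates)) candidates <- sort(setdiff(graph$nodes, observed_any))
  candidates <- as.character(candidates)
  if (length(candidates) == 0L) stop("no candidate nodes to perturb")
  for (j in profs) {
    bad <- intersect(candidates, names(labelings[[j]]$signs))
    if (length(bad)) {
      stop("candidate(s) observed in profile ", j, ": ",
           paste(bad, collapse = ", "))
    }
  }
  cls <- stats::setNames(as.character(classes[profs]), profs)
  if (!any(cls == class_a) || !any(cls == class_b)) {
    stop("both classes must be nonempty")
  }
  long <- list()
  for (j in profs) {
    for (sign in c("+", "-")) {
      sf <- scenfit_scores_batch(graph, labelings[[j]], candidates, sign,
                                 bound)
      thr <- if (any(is.finite(sf))) top_threshold(sf[is.finite(sf)], q) else Inf
      long[[length(long) + 1L]] <-
        data.frame(node = candidates, sign = sign, profile = j,
                   sf = unname(sf), f = unname(sf >= thr),
                   stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, long)
  tab <- list()
  n_a <- sum(cls == class_a); n_b <- sum(cls == class_b)
  for (sign in c("+", "-")) {
    for (node in candidates) {
      sel <- long$node == node & long$sign == sign
      f <- stats::setNames(long$f[sel], long$profile[sel])
      a_with <- sum(f[names(cls)[cls == class_a]])
      b_with <- sum(f[names(cls)[cls == class_b]])
      p <- stats::fisher.test(
        matrix(c(a_with, n_a - a_with, b_with, n_b - b_with),
               nrow = 2, byrow = TRUE),
        alternative = "greater")$p.value
      tab[[length(tab) + 1L]] <-
        data.frame(node = node, sign = sign,
                   tps_b = b_with / n_b, tps_a = a_with / n_a, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, tab)
  names(tab)[names(tab) == "tps_b"] <- paste0("tps_", class_b)
  names(tab)[names(tab) == "tps_a"] <- paste0("tps_", class_a)
  tab <- tab[order(tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  list(scores = long, table = tab)
}
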