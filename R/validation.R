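# Prediction validation: holdout precision of strong sign projections,
# randomized-data baselines, and the uniform-random precision comparator.

#' Holdout precision of sign predictions
#'
#' Hides a random fraction of the observed nodes, restores consistency
#' from the remainder (MCOS repairs) and scores each hidden node whose
#' projection is a *strong* class (`"+"`, `"-"`, `"0"`): the prediction is
#' correct when the strong class equals the hidden sign. Weak and `"?"`
#' projections are excluded from the denominator in the default strict
#' mode; the lenient mode credits any projection whose sign set contains
#' the hidden sign and keeps weak classes in the denominator.
#'
#' @param graph A `signed_graph`.
#' @param beta A nonempty `labeling`.
#' @param frac Fraction of observed nodes to hide, in (0, 1).
#' @param seed Optional integer seed for the random split.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @param bound Free-node bound passed to the solver.
#' @return List with `precision` (percent, `NA` when no hidden node is
#'   scored), `n_scored` and `n_hidden`.
#' @export
holdout_precision <- function(graph, beta, frac = 0.5, seed = NULL,
                              mode = c("strict", "lenient"),
                              bound = default_bound()) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "signed_graph"), inherits(beta, "labeling"),
            frac > 0, frac < 1, length(beta$signs) > 0)
  check_labeling_nodes(graph, beta)
  if (!is.null(seed)) set.seed(seed)
  obs <- names(beta$signs)
  n_hide <- max(1L, round(frac * length(obs)))
  if (n_hide >= length(obs)) n_hide <- length(obs) - 1L
  hidden <- sample(obs, n_hide)
  kept <- labeling(beta$signs[setdiff(obs, hidden)], beta$profile_id)
  res <- solve_consistency(graph, kept, mode = "mcos", bound = bound)
  proj <- res$projections[hidden]
  truth <- as_sign_chr(beta$signs[hidden])
  if (mode == "strict") {
    scored <- proj %in% c("+", "-", "0")
    correct <- scored & proj == truth
  } else {
    sets <- list("+" = "+", "-" = "-", "0" = "0",
                 "Not+" = c("-", "0"), "Not-" = c("+", "0"),
                 "change" = c("+", "-"), "?" = c("+", "-", "0"))
    scored <- rep(TRUE, length(proj))
    correct <- mapply(function(cl, s) s %in% sets[[cl]], proj, truth)
  }
  n_scored <- sum(scored)
  list(precision = if (n_scored == 0L) NA_real_ else
         100 * sum(correct) / n_scored,
       n_scored = n_scored,
       n_hidden = length(hidden))
}

#' Holdout precision under randomized observations
#'
#' Baseline distribution obtained by permuting the observed signs
#' uniformly across the observed nodes before each holdout repetition.
#'
#' @inheritParams holdout_precision
#' @param reps Number of repetitions.
#' @param seed Integer seed.
#' @return Numeric vector of per-repetition precisions (percent; may
#'   contain `NA` when a repetition scores no node).
#' @export
randomized_baseline <- function(graph, beta, frac = 0.5, reps = 100,
                                seed = 1, mode = c("strict", "lenient"),
                                bound = default_bound()) {
  mode <- match.arg(mode)
  stopifnot(reps >= 1)
  set.seed(seed)
  vapply(seq_len(reps), function(r) {
    perm <- labeling(stats::setNames(sample(beta$signs), names(beta$signs)),
                     beta$profile_id)
    holdout_precision(graph, perm, frac = frac, seed = NULL, mode = mode,
                      bound = bound)$precision
  }, numeric(1))
}

#' Precision of a uniformly random sign predictor
#'
#' Simulates independent uniform truth/prediction pairs over a two-sign
#' (`+`, `-`) or three-sign (`+`, `-`, `0`) alphabet and reports the match
#' percentage — the comparator for discretization-model precision (about
#' 50% for two signs, about 33% for three).
#'
#' @param n_signs 2 or 3.
#' @param n Number of simulated pairs.
#' @param seed Integer seed.
#' @return Match percentage in \[0, 100\].
#' @export
random_sign_precision <- function(n_signs, n, seed = 1) {
  if (!n_signs %in% c(2L, 3L)) stop("n_signs must be 2 or 3")
  stopifnot(n >= 1)
  set.seed(seed)
  truth <- sample.int(n_signs, n, replace = TRUE)
  pred <- sample.int(n_signs, n, replace = TRUE)
  100 * mean(truth == pred)
}

#' Compare two precision distributions
#'
#' Two-tailed Welch t-test between two vectors of per-repetition
#' precisions (e.g. observed vs randomized baselines).
#'
#' @param x,y Numeric vectors of precisions; `NA`s are dropped.
#' @return The `htest` object from [stats::t.test()].
#' @export
compare_precisions <- function(x, y) {
  stats::t.test(x[!is.na(x)], y[!is.na(y)], alternative = "two.sided")
}
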