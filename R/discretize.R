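# Three-sign discretization of expression matrices: per-profile
# differential values against the reference-class mean, two-threshold
# sign calls, the pooled sign-proportion filter, and holdout-based
# threshold selection.

#' Bundle an expression matrix with its profile classes
#'
#' @param values Numeric matrix of log2-normalised expression, rows = genes,
#'   columns = profiles (both dimnames required).
#' @param classes Named character vector mapping every profile (column) to
#'   its class, e.g. `"MC"` or `"NPC"`.
#' @return An object of class `expression_set` (list with `values`,
#'   `classes`).
#' @export
expression_set <- function(values, classes) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  classes <- stats::setNames(as.character(classes), names(classes))
  if (is.null(names(classes))) stop("classes must be named by profile id")
  if (!setequal(names(classes), colnames(values))) {
    stop("classes must cover exactly the profiles (columns) of the matrix")
  }
  structure(list(values = values, classes = classes[colnames(values)]),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d profiles (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(table(x$classes)),
                            table(x$classes)), collapse = ", ")))
  invisible(x)
}

#' Differential expression against the reference-class mean
#'
#' For every gene, subtracts the mean expression over the reference-class
#' profiles from each profile's value, yielding the per-profile
#' differential used for discretization. Reference-class profiles are
#' profiles too and receive differential values like any other column.
#'
#' @param expr An `expression_set`.
#' @param ref_class Reference class label (default `"NPC"`).
#' @return An `expression_set` of differential values (log2
#'   fold-differences), same axes and classes.
#' @export
differential_matrix <- function(expr, ref_class = "NPC") {
  stopifnot(inherits(expr, "expression_set"))
  ref <- expr$classes == ref_class
  if (!any(ref)) stop("no profile of reference class '", ref_class, "'")
  ref_mean <- rowMeans(expr$values[, ref, drop = FALSE])
  expression_set(expr$values - ref_mean, expr$classes)
}

#' Discretize one profile's differential values into signs
#'
#' A gene is over-expressed (`"+"`) when its differential exceeds `k2`,
#' under-expressed (`"-"`) below `-k2`, and invariant (`"0"`) strictly
#' inside `(-k1, k1)`. Values falling in the gaps `[k1, k2]` and
#' `[-k2, -k1]` are assigned no sign: the gene is simply unobserved in the
#' resulting labeling.
#'
#' @param diff An `expression_set` of differential values (see
#'   [differential_matrix()]).
#' @param profile A profile (column) id.
#' @param k1 Invariant half-band width (nonnegative).
#' @param k2 Variant cutoff, `k2 >= k1`.
#' @return A `labeling` for that profile.
#' @export
discretize_profile <- function(diff, profile, k1 = 0.03, k2 = 0.2) {
  stopifnot(inherits(diff, "expression_set"),
            k1 >= 0, k2 >= k1,
            profile %in% colnames(diff$values))
  p <- diff$values[, profile]
  sign_chr <- ifelse(p > k2, "+",
              ifelse(p < -k2, "-",
              ifelse(abs(p) < k1, "0", NA_character_)))
  keep <- !is.na(sign_chr)
  labeling(stats::setNames(sign_chr[keep], rownames(diff$values)[keep]),
           profile_id = profile)
}

#' Discretize every profile of a differential matrix
#'
#' @inheritParams discretize_profile
#' @return Named list of `labeling`s, one per profile.
#' @export
discretize_profiles <- function(diff, k1 = 0.03, k2 = 0.2) {
  profs <- colnames(diff$values)
  stats::setNames(lapply(profs, discretize_profile, diff = diff,
                         k1 = k1, k2 = k2), profs)
}

#' Pooled sign-proportion filter for a threshold combination
#'
#' Threshold combinations whose pooled proportion of variant (`+`/`-`)
#' calls among all calls (variant and invariant) exceeds `max_prop` are
#' discarded.
#'
#' @param labelings Nonempty list of `labeling`s.
#' @param max_prop Maximum tolerated variant proportion (default 0.5;
#'   the comparison is strict, exactly 50% is kept).
#' @return `TRUE` to keep the combination, `FALSE` to discard it.
#' @export
sign_proportion_filter <- function(labelings, max_prop = 0.5) {
  if (length(labelings) == 0L) stop("labelings must be nonempty")
  signs <- unlist(lapply(labelings, function(b) b$signs), use.names = FALSE)
  if (length(signs) == 0L) return(TRUE)
  mean(signs != 0L) <= max_prop
}

#' Grid search of discretization thresholds by holdout precision
#'
#' For every `(k1, k2)` pair in the grid, discretizes all profiles,
#' applies the pooled sign-proportion filter and, for surviving pairs,
#' estimates prediction precision by repeated holdout: each repetition
#' picks one profile at random, hides `holdout_frac` of its observed
#' genes, restores consistency (MCOS) from the rest and scores the strong
#' predictions against the hidden signs (see [holdout_precision()]).
#'
#' @param expr An `expression_set` of raw expression values.
#' @param graph A `signed_graph` whose gene nodes match (a subset of) the
#'   matrix rows.
#' @param grid Data.frame with columns `k1`, `k2` (pairs with `k1 > k2`
#'   are dropped); defaults to [default_threshold_grid()].
#' @param reps Repetitions per surviving pair.
#' @param holdout_frac Fraction of observed genes hidden per repetition.
#' @param seed Integer seed making the search reproducible.
#' @param ref_class Reference class for [differential_matrix()].
#' @param bound Free-node bound passed to the solver.
#' @return Data.frame `k1`, `k2`, `kept`, `mean_precision`, `ci95`
#'   (half-width of the normal-approximation 95% interval), sorted by
#'   decreasing mean precision with discarded pairs last. A warning is
#'   issued when every pair is discarded.
#' @export
threshold_search <- function(expr, graph, grid = default_threshold_grid(),
                             reps = 20, holdout_frac = 0.5, seed = 1,
                             ref_class = "NPC", bound = default_bound()) {
  stopifnot(inherits(expr, "expression_set"), inherits(graph, "signed_graph"),
            nrow(grid) >= 1, reps >= 1,
            holdout_frac > 0, holdout_frac < 1)
  genes <- intersect(observable_genes(graph), rownames(expr$values))
  if (length(genes) == 0L) stop("graph has no observable gene present in the matrix")
  grid <- grid[grid$k1 <= grid$k2, , drop = FALSE]
  diff <- differential_matrix(expr, ref_class)
  set.seed(seed)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    k1 <- grid$k1[i]; k2 <- grid$k2[i]
    labs <- lapply(discretize_profiles(diff, k1, k2),
                   restrict_labeling, nodes = genes)
    labs <- labs[vapply(labs, function(b) length(b$signs) > 0L, logical(1))]
    if (length(labs) == 0L || !sign_proportion_filter(labs)) {
      return(data.frame(k1 = k1, k2 = k2, kept = FALSE,
                        mean_precision = NA_real_, ci95 = NA_real_))
    }
    prec <- vapply(seq_len(reps), function(r) {
      b <- labs[[sample.int(length(labs), 1L)]]
      holdout_precision(graph, b, frac = holdout_frac,
                        seed = sample.int(.Machine$integer.max, 1L),
                        bound = bound)$precision
    }, numeric(1))
    prec <- prec[!is.na(prec)]
    if (length(prec) == 0L) {
      return(data.frame(k1 = k1, k2 = k2, kept = TRUE,
                        mean_precision = NA_real_, ci95 = NA_real_))
    }
    data.frame(k1 = k1, k2 = k2, kept = TRUE,
               mean_precision = mean(prec),
               ci95 = 1.96 * stats::sd(prec) / sqrt(length(prec)))
  })
  out <- do.call(rbind, res)
  if (!any(out$kept)) {
    warning("every threshold combination was discarded by the sign-proportion filter")
  }
  out[order(!out$kept, -ifelse(is.na(out$mean_precision), -Inf,
                               out$mean_precision)), , drop = FALSE]
}

#' Default threshold grid
#'
#' `k1` in 0.01..0.10 by 0.01 crossed with `k2` in 0.1..1.5 by 0.1,
#' pruned to `k1 <= k2`; includes the reference pair (0.03, 0.2).
#'
#' @return Data.frame with columns `k1`, `k2`.
#' @export
default_threshold_grid <- function() {
  g <- expand.grid(k1 = seq(0.01, 0.10, by = 0.01),
                   k2 = seq(0.1, 1.5, by = 0.1))
  g[g$k1 <= g$k2, , drop = FALSE]
}
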