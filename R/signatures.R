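# Class signatures from sign projections: the boolean prediction matrix
# over (node, variant sign, profile), per-class frequency scores, and
# Fisher ranking of class-specific assignments.

#' Build the boolean prediction matrix from per-profile projections
#'
#' Decomposes each profile's sign projections into boolean values
#' `M[node, sign, profile] = 1` when the sign belongs to the node's
#' projected sign set. Only nodes never observed in any profile's labeling
#' are indexed (projections of observed nodes restate the data), and only
#' the variant signs `+` and `-` are kept. Projections are expected to
#' come from MCOS-repaired solves.
#'
#' @param projections Named list, profile id to named character vector of
#'   projection classes (as in `solve_consistency(...)$projections`).
#' @param labelings Named list of the `labeling`s the projections were
#'   computed from (used to exclude observed nodes).
#' @param classes Named character vector mapping every profile to its
#'   class (e.g. `"MC"`/`"NPC"`).
#' @return An object of class `prediction_matrix`: list with logical
#'   matrices `plus` and `minus` (rows = nodes, columns = profiles) and
#'   `classes`.
#' @export
build_prediction_matrix <- function(projections, labelings, classes) {
  stopifnot(is.list(projections), length(projections) >= 1)
  profs <- names(projections)
  missing_cls <- setdiff(profs, names(classes))
  if (length(missing_cls)) {
    stop("class map missing profile(s): ", paste(missing_cls, collapse = ", "))
  }
  observed_any <- unique(unlist(lapply(labelings, function(b) names(b$signs))))
  nodes <- sort(setdiff(unique(unlist(lapply(projections, names))),
                        observed_any))
  sets <- list("+" = "+", "-" = "-", "0" = "0",
               "Not+" = c("-", "0"), "Not-" = c("+", "0"),
               "change" = c("+", "-"), "?" = c("+", "-", "0"))
  member <- function(sign) {
    vapply(profs, function(j) {
      pr <- projections[[j]][nodes]
      vapply(pr, function(cl) !is.na(cl) && sign %in% sets[[cl]], logical(1))
    }, logical(length(nodes)))
  }
  plus <- matrix(member("+"), nrow = length(nodes),
                 dimnames = list(nodes, profs))
  minus <- matrix(member("-"), nrow = length(nodes),
                  dimnames = list(nodes, profs))
  structure(list(plus = plus, minus = minus,
                 classes = stats::setNames(as.character(classes[profs]), profs)),
            class = "prediction_matrix")
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat(sprintf("prediction_matrix: %d nodes x 2 signs x %d profiles (%s)\n",
              nrow(x$plus), ncol(x$plus),
              paste(sprintf("%s:%d", names(table(x$classes)),
                            table(x$classes)), collapse = ", ")))
  invisible(x)
}

sign_slot <- function(M, sign) {
  switch(as_sign_chr(sign), "+" = M$plus, "-" = M$minus,
         stop("frequency scores are defined for variant signs only"))
}

#' Frequency score of a (node, sign) assignment in one class
#'
#' The fraction of profiles of the class in which the node is predicted
#' with the given variant sign.
#'
#' @param M A `prediction_matrix`.
#' @param node A node id indexed in `M`.
#' @param sign `"+"` or `"-"`.
#' @param cls A class label present in `M$classes`.
#' @return A value in \[0, 1\].
#' @export
frequency_score <- function(M, node, sign, cls) {
  stopifnot(inherits(M, "prediction_matrix"))
  slot <- sign_slot(M, sign)
  if (!node %in% rownames(slot)) stop("node not indexed: ", node)
  sel <- M$classes == cls
  if (!any(sel)) stop("empty class: ", cls)
  mean(slot[node, sel])
}

#' Rank (node, sign) assignments specific to one class
#'
#' Keeps assignments whose frequency score is higher in `class_a` than in
#' `class_b` and ranks them by a one-sided Fisher exact test on the 2x2
#' table of with/without counts per class. Raw p-values are reported; a
#' Benjamini-Hochberg column is added for convenience.
#'
#' @param M A `prediction_matrix`.
#' @param class_a,class_b The compared classes (default `"MC"` vs
#'   `"NPC"`; the direction filter keeps `FS_a > FS_b`).
#' @param alternative Sidedness of the Fisher test (default
#'   `"greater"` in `class_a`).
#' @param graph Optional `signed_graph` for a connectivity annotation
#'   (`downstream/total` observed genes, see [count_connected_genes()]).
#' @return Data.frame `node`, `sign`, `fs_b` (named `fs_<class_b>`),
#'   `fs_a`, `p`, `p_bh` (and `connectivity`), sorted by ascending p.
#' @export
rank_assignments <- function(M, class_a = "MC", class_b = "NPC",
                             alternative = "greater", graph = NULL) {
  stopifnot(inherits(M, "prediction_matrix"))
  sel_a <- M$classes == class_a
  sel_b <- M$classes == class_b
  if (!any(sel_a) || !any(sel_b)) stop("both classes must be nonempty")
  rows <- list()
  for (sign in c("+", "-")) {
    slot <- sign_slot(M, sign)
    for (node in rownames(slot)) {
      a_with <- sum(slot[node, sel_a]); a_n <- sum(sel_a)
      b_with <- sum(slot[node, sel_b]); b_n <- sum(sel_b)
      if (a_with / a_n <= b_with / b_n) next
      p <- stats::fisher.test(
        matrix(c(a_with, a_n - a_with, b_with, b_n - b_with),
               nrow = 2, byrow = TRUE),
        alternative = alternative)$p.value
      rows[[length(rows) + 1L]] <-
        data.frame(node = node, sign = sign,
                   fs_b = b_with / b_n, fs_a = a_with / a_n, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(node = character(0), sign = character(0),
                      fs_b = numeric(0), fs_a = numeric(0),
                      p = numeric(0), p_bh = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    out$p_bh <- stats::p.adjust(out$p, method = "BH")
    out <- out[order(out$p), , drop = FALSE]
    rownames(out) <- NULL
  }
  names(out)[names(out) == "fs_b"] <- paste0("fs_", class_b)
  names(out)[names(out) == "fs_a"] <- paste0("fs_", class_a)
  if (!is.null(graph) && nrow(out)) {
    out$connectivity <- vapply(out$node, function(n) {
      cc <- count_connected_genes(graph, n)
      sprintf("%d/%d", cc[["downstream"]], cc[["total_observed"]])
    }, character(1))
  }
  out
}

#' Export a prediction matrix as TSV
#'
#' Long layout: one row per (node, sign) with a 0/1 column per profile,
#' preceded by a class header row, so external learners can consume the
#' matrix directly.
#'
#' @param M A `prediction_matrix`.
#' @param file Output path.
#' @return Invisibly, `M`.
#' @export
write_prediction_matrix <- function(M, file) {
  stopifnot(inherits(M, "prediction_matrix"))
  profs <- colnames(M$plus)
  body <- rbind(
    data.frame(node = rownames(M$plus), sign = "+",
               M$plus * 1L, check.names = FALSE),
    data.frame(node = rownames(M$minus), sign = "-",
               M$minus * 1L, check.names = FALSE))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(c("class", "", unname(M$classes[profs])), collapse = "\t"),
             con)
  utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(M)
}
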