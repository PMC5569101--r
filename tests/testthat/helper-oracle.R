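# Independent brute-force oracle for the consistency model. Deliberately
# written as plain loops over explicit sign characters, sharing no code
# with the package engine, so the two can check each other.

oracle_signs <- c("+", "-", "0")

oracle_influence <- function(edge_sign, src_sign) {
  if (src_sign == "0") return("0")
  if (edge_sign == "+") return(src_sign)
  if (src_sign == "+") "-" else "+"
}

oracle_edge_chr <- function(graph) {
  data.frame(source = graph$edges$source,
             target = graph$edges$target,
             sign = ifelse(graph$edges$sign == 1L, "+", "-"),
             stringsAsFactors = FALSE)
}

oracle_node_ok <- function(graph, mu, n, exempt = character(0)) {
  if (n %in% graph$inputs || n %in% exempt) return(TRUE)
  es <- oracle_edge_chr(graph)
  infl <- character(0)
  for (i in seq_len(nrow(es))) {
    if (es$target[i] == n) {
      infl <- c(infl, oracle_influence(es$sign[i], mu[[es$source[i]]]))
    }
  }
  v <- mu[[n]]
  if (v == "+" || v == "-") return(v %in% infl)
  length(infl) == 0 || all(infl == "0") || ("+" %in% infl && "-" %in% infl)
}

oracle_consistent <- function(graph, mu, exempt = character(0)) {
  for (n in graph$nodes) {
    if (!oracle_node_ok(graph, mu, n, exempt)) return(FALSE)
  }
  TRUE
}

# All total colorings over `nodes` extending the fixed named vector.
oracle_all_colorings <- function(nodes, fixed = character(0)) {
  free <- setdiff(nodes, names(fixed))
  if (length(free) == 0L) {
    return(list(fixed[nodes]))
  }
  grid <- do.call(expand.grid,
                  c(rep(list(oracle_signs), length(free)),
                    list(stringsAsFactors = FALSE)))
  lapply(seq_len(nrow(grid)), function(i) {
    mu <- c(fixed, stats::setNames(as.character(grid[i, ]), free))
    mu[nodes]
  })
}

oracle_enumerate <- function(graph, beta_chr = character(0)) {
  Filter(function(mu) oracle_consistent(graph, mu),
         oracle_all_colorings(graph$nodes, beta_chr))
}

oracle_class <- function(signs) {
  s <- unique(signs)
  has_p <- "+" %in% s; has_m <- "-" %in% s; has_z <- "0" %in% s
  if (has_p && has_m && has_z) return("?")
  if (has_p && has_m) return("change")
  if (has_p && has_z) return("Not-")
  if (has_m && has_z) return("Not+")
  if (has_p) return("+")
  if (has_m) return("-")
  "0"
}

oracle_project <- function(colorings) {
  nodes <- names(colorings[[1]])
  out <- character(length(nodes))
  names(out) <- nodes
  for (n in nodes) {
    out[n] <- oracle_class(vapply(colorings, `[[`, character(1), n))
  }
  out
}

# Exhaustive MCOS: smallest exemption sets admitting a consistent coloring.
oracle_mcos <- function(graph, beta_chr = character(0)) {
  eligible <- setdiff(graph$nodes, graph$inputs)
  candidates <- oracle_all_colorings(graph$nodes, beta_chr)
  for (size in 0:length(eligible)) {
    subsets <- if (size == 0L) list(character(0)) else
      apply(utils::combn(eligible, size), 2L, identity, simplify = FALSE)
    repairs <- list()
    colorings <- list()
    for (sub in subsets) {
      ok <- Filter(function(mu) oracle_consistent(graph, mu, exempt = sub),
                   candidates)
      if (length(ok)) {
        repairs[[length(repairs) + 1L]] <- sort(sub)
        colorings <- c(colorings, ok)
      }
    }
    if (length(repairs)) {
      colorings <- colorings[!duplicated(vapply(colorings, paste,
                                                character(1),
                                                collapse = ""))]
      return(list(score = size, repairs = repairs,
                  projections = oracle_project(colorings)))
    }
  }
}

oracle_switch_cost <- function(from, to) {
  if (from == to) return(0L)
  if (from == "0" || to == "0") return(1L)
  2L
}

# Exhaustive SCENFIT: minimal-cost sign switches over observed nodes;
# `clamped` nodes are fixed and never charged.
oracle_scenfit <- function(graph, beta_chr, clamped = character(0)) {
  candidates <- Filter(function(mu) oracle_consistent(graph, mu),
                       oracle_all_colorings(graph$nodes, clamped))
  if (length(candidates) == 0L) return(list(score = Inf))
  costs <- vapply(candidates, function(mu) {
    tot <- 0L
    for (n in names(beta_chr)) {
      tot <- tot + oracle_switch_cost(beta_chr[[n]], mu[[n]])
    }
    tot
  }, integer(1))
  best <- min(costs)
  sel <- candidates[costs == best]
  repairs <- unique(lapply(sel, function(mu) {
    ch <- sort(names(beta_chr)[vapply(names(beta_chr), function(n)
      mu[[n]] != beta_chr[[n]], logical(1))])
    data.frame(node = ch,
               from = unname(beta_chr[ch]),
               to = vapply(ch, function(n) mu[[n]], character(1),
                           USE.NAMES = FALSE),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(score = best, repairs = repairs, projections = oracle_project(sel))
}

# One-sided hypergeometric tail for a 2x2 with/without table.
oracle_fisher_greater <- function(a_with, a_n, b_with, b_n) {
  total_with <- a_with + b_with
  sum(stats::dhyper(a_with:min(a_n, total_with), a_n, b_n, total_with))
}
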