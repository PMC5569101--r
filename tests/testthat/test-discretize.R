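make_expr <- function(values, classes) {
  expression_set(values, classes)
}

test_that("differential_matrix centers on the reference-class mean", {
  vals <- matrix(c(5.0, 4.9, 4.7,
                   7.1, 7.0, 7.0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("m1", "n1", "n2")))
  expr <- make_expr(vals, c(m1 = "MC", n1 = "NPC", n2 = "NPC"))
  d <- differential_matrix(expr)
  expect_equal(d$values["g1", "m1"], 5.0 - 4.8)
  # reference profiles get differential values too
  expect_equal(d$values["g1", "n1"], 4.9 - 4.8)

  flat <- make_expr(matrix(3, 2, 3, dimnames = dimnames(vals)),
                    c(m1 = "MC", n1 = "NPC", n2 = "NPC"))
  expect_true(all(differential_matrix(flat)$values == 0))

  noref <- make_expr(vals, c(m1 = "MC", n1 = "MC", n2 = "MC"))
  expect_error(differential_matrix(noref), "reference")
})

test_that("differential values match an independent recomputation", {
  set.seed(42)
  vals <- matrix(rnorm(12, 7, 1), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("p", 1:4)))
  classes <- c(p1 = "MC", p2 = "MC", p3 = "NPC", p4 = "NPC")
  d <- differential_matrix(make_expr(vals, classes))$values
  for (g in rownames(vals)) {
    ref_mean <- (vals[g, "p3"] + vals[g, "p4"]) / 2
    for (p in colnames(vals)) {
      expect_equal(d[g, p], vals[g, p] - ref_mean)
    }
  }
})

test_that("discretize_profile applies the two-threshold three-sign rules", {
  vals <- matrix(c(0.25, 0.01, 0.10, -0.25, -0.01, -0.15, 0.03, 0.2),
                 ncol = 1,
                 dimnames = list(paste0("g", 1:8), "p"))
  diff <- structure(list(values = vals, classes = c(p = "MC")),
                    class = "expression_set")
  b <- discretize_profile(diff, "p", k1 = 0.03, k2 = 0.2)
  s <- stats::setNames(rep(NA_character_, 8), paste0("g", 1:8))
  s[names(b$signs)] <- c("+", "-", "0")[match(b$signs, c(1, -1, 0))]
  expect_identical(unname(s[c("g1", "g2", "g4", "g5")]),
                   c("+", "0", "-", "0"))
  # the gaps [k1, k2] and [-k2, -k1] yield no observation (incl. bounds)
  expect_true(all(is.na(s[c("g3", "g6", "g7", "g8")])))
})

test_that("discretization is monotone and partitions the line", {
  k1 <- 0.05; k2 <- 0.4
  p <- seq(-1, 1, by = 0.01)
  vals <- matrix(p, ncol = 1,
                 dimnames = list(sprintf("g%03d", seq_along(p)), "p"))
  dm <- structure(list(values = vals, classes = c(p = "MC")),
                  class = "expression_set")
  b <- discretize_profile(dm, "p", k1, k2)
  lvl <- stats::setNames(rep(NA_integer_, length(p)), rownames(vals))
  lvl[names(b$signs)] <- b$signs
  # monotone in p: the called signs are nondecreasing along the line
  seq_signs <- lvl[order(p)]
  seq_signs <- seq_signs[!is.na(seq_signs)]
  expect_true(all(diff(match(seq_signs, c(-1L, 0L, 1L))) >= 0))
  # the three sign regions and the two gaps partition the line
  expect_true(all(ifelse(p > k2, !is.na(lvl) & lvl == 1L,
                  ifelse(p < -k2, !is.na(lvl) & lvl == -1L,
                  ifelse(abs(p) < k1, !is.na(lvl) & lvl == 0L,
                         is.na(lvl))))))
})

test_that("sign_proportion_filter discards pooled variant excess strictly", {
  lab <- function(n_var, n_inv) {
    labeling(stats::setNames(c(rep("+", n_var), rep("0", n_inv)),
                             paste0("g", seq_len(n_var + n_inv))))
  }
  expect_false(sign_proportion_filter(list(lab(60, 40))))
  expect_true(sign_proportion_filter(list(lab(0, 40))))
  expect_true(sign_proportion_filter(list(lab(50, 50))))  # exactly 50%: kept
  expect_error(sign_proportion_filter(list()), "nonempty")
})

test_that("threshold_search ranks surviving pairs and is deterministic", {
  g <- star_graph(6)
  spec <- synthetic_spec(n_nodes = 7, n_variant_genes = 2, shift = 0.5,
                         noise_sd = 0.02, seed = 11)
  sim <- generate_expression(g, spec)
  grid <- data.frame(k1 = c(0.03, 0.05), k2 = c(0.2, 0.3))
  r1 <- threshold_search(sim$expr, g, grid, reps = 4, holdout_frac = 0.5,
                         seed = 9)
  r2 <- threshold_search(sim$expr, g, grid, reps = 4, holdout_frac = 0.5,
                         seed = 9)
  expect_identical(r1, r2)
  expect_true(all(c("k1", "k2", "kept", "mean_precision", "ci95") %in%
                  names(r1)))
  expect_true(any(r1$kept))

  # a graph without observable genes is rejected
  bare <- signed_graph(data.frame(source = "A", sign = "+", target = "B"))
  expect_error(threshold_search(sim$expr, bare, grid, reps = 1,
                                holdout_frac = 0.5, seed = 1),
               "observable gene")
})

test_that("threshold_search warns when every pair is discarded", {
  # huge k1 band calls everything variant-free... use tiny k2 so all calls
  # are variant: pooled proportion 100% -> discarded
  g <- star_graph(4)
  spec <- synthetic_spec(n_nodes = 5, n_variant_genes = 4, shift = 1,
                         noise_sd = 0.01, seed = 3,
                         n_profiles_per_class = c(MC = 3, NPC = 2))
  sim <- generate_expression(g, spec)
  grid <- data.frame(k1 = 0.0, k2 = 0.001)
  expect_warning(out <- threshold_search(sim$expr, g, grid, reps = 2,
                                         holdout_frac = 0.5, seed = 1),
                 "discarded")
  expect_false(any(out$kept))
})

test_that("default grid keeps k1 <= k2 and contains the reference pair", {
  grid <- default_threshold_grid()
  expect_true(all(grid$k1 <= grid$k2))
  expect_true(any(abs(grid$k1 - 0.03) < 1e-9 & abs(grid$k2 - 0.2) < 1e-9))
})
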