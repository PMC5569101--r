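# Build a prediction_matrix directly from given boolean rows (bypassing
# the solver) for arithmetic-level checks.
manual_M <- function(plus, minus, classes) {
  structure(list(plus = plus, minus = minus, classes = classes),
            class = "prediction_matrix")
}

test_that("build_prediction_matrix decomposes projections per sign", {
  profs <- c("p1", "p2")
  projections <- list(
    p1 = c(U = "change", V = "0", W = "Not-", obs1 = "+"),
    p2 = c(U = "+", V = "?", W = "-", obs1 = "+"))
  labelings <- list(p1 = labeling(c(obs1 = "+"), "p1"),
                    p2 = labeling(c(obs1 = "+"), "p2"))
  classes <- c(p1 = "MC", p2 = "NPC")
  M <- build_prediction_matrix(projections, labelings, classes)
  # "change" sets both signs, "0" neither, "Not-" = {+, 0} sets + only
  expect_true(M$plus["U", "p1"] && M$minus["U", "p1"])
  expect_false(M$plus["V", "p1"] || M$minus["V", "p1"])
  expect_true(M$plus["W", "p1"])
  expect_false(M$minus["W", "p1"])
  expect_true(M$plus["V", "p2"] && M$minus["V", "p2"]) # "?"
  # observed nodes are excluded entirely
  expect_false("obs1" %in% rownames(M$plus))
  # missing class map entry is rejected
  expect_error(build_prediction_matrix(projections, labelings,
                                       c(p1 = "MC")), "class map")
})

test_that("per-profile sign membership sums to at most two", {
  g <- random_graph(7, p_edge = 0.3, p_gene = 0.5, seed = 77)
  pl <- plant_consistent_labeling(g, seed = 78)
  r <- solve_consistency(g, pl$labeling, "mcos")
  M <- build_prediction_matrix(list(p1 = r$projections),
                               list(p1 = pl$labeling), c(p1 = "MC"))
  expect_true(all(M$plus + M$minus <= 2))
})

test_that("frequency_score averages boolean predictions per class", {
  plus <- matrix(c(1, 1, 0, 1,
                   0, 0, 0, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("U", "V"), paste0("p", 1:4))) == 1
  minus <- matrix(1, 2, 4, dimnames = dimnames(plus)) == 1
  M <- manual_M(plus, minus,
                stats::setNames(rep("MC", 4), paste0("p", 1:4)))
  expect_equal(frequency_score(M, "U", "+", "MC"), 0.75)
  expect_equal(frequency_score(M, "V", "+", "MC"), 0)
  expect_equal(frequency_score(M, "U", "-", "MC"), 1)
  expect_error(frequency_score(M, "U", "+", "NPC"), "empty class")
  expect_error(frequency_score(M, "U", "0", "MC"), "variant")
})

test_that("rank_assignments matches the hypergeometric tail oracle", {
  # counts shaped like a strongly class-specific assignment:
  # 570/602 in one class vs 4/9 in the other
  n_mc <- 602; n_npc <- 9
  profs <- c(sprintf("m%03d", 1:n_mc), sprintf("n%01d", 1:n_npc))
  plus <- matrix(FALSE, 1, n_mc + n_npc, dimnames = list("U", profs))
  plus["U", 1:570] <- TRUE
  plus["U", n_mc + 1:4] <- TRUE
  minus <- matrix(FALSE, 1, n_mc + n_npc, dimnames = list("U", profs))
  M <- manual_M(plus, minus,
                stats::setNames(rep(c("MC", "NPC"), c(n_mc, n_npc)), profs))
  out <- rank_assignments(M)
  expect_equal(nrow(out), 1L)
  expect_equal(out$p, oracle_fisher_greater(570, n_mc, 4, n_npc),
               tolerance = 1e-12)
})

test_that("rank_assignments filters by direction and sorts by p", {
  profs <- paste0("p", 1:8)
  classes <- stats::setNames(rep(c("MC", "NPC"), each = 4), profs)
  plus <- matrix(c(rep(TRUE, 4), rep(FALSE, 4),   # MC-specific
                   rep(TRUE, 8),                  # identical proportions
                   rep(FALSE, 4), rep(TRUE, 4)),  # NPC-specific
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), profs))
  minus <- matrix(FALSE, 3, 8, dimnames = dimnames(plus))
  M <- manual_M(plus, minus, classes)
  out <- rank_assignments(M)
  # identical proportions and NPC-specific rows are excluded
  expect_identical(out$node, "A")
  expect_true(all(out$p >= 0 & out$p <= 1))

  # identical proportions give p = 1 when not filtered out: check via a
  # tie where FS_MC is barely higher
  plus2 <- matrix(c(rep(TRUE, 4), TRUE, rep(FALSE, 3)), nrow = 1,
                  byrow = TRUE, dimnames = list("D", profs))
  M2 <- manual_M(plus2, matrix(FALSE, 1, 8, dimnames = list("D", profs)),
                 classes)
  out2 <- rank_assignments(M2)
  expect_true(!is.unsorted(out2$p))
})

test_that("connectivity annotation joins the ranked table", {
  g <- signed_graph(data.frame(source = c("U", "U"), sign = "+",
                               target = c("g1", "g2")),
                    roles = c(g1 = "gene", g2 = "gene"))
  profs <- c("p1", "p2")
  plus <- matrix(c(TRUE, FALSE), 1, 2, dimnames = list("U", profs))
  minus <- matrix(FALSE, 1, 2, dimnames = list("U", profs))
  M <- manual_M(plus, minus, c(p1 = "MC", p2 = "NPC"))
  out <- rank_assignments(M, graph = g)
  expect_identical(out$connectivity, "2/2")
})

test_that("prediction matrices export with a class header", {
  profs <- c("p1", "p2")
  plus <- matrix(c(TRUE, FALSE), 1, 2, dimnames = list("U", profs))
  minus <- matrix(FALSE, 1, 2, dimnames = list("U", profs))
  M <- manual_M(plus, minus, c(p1 = "MC", p2 = "NPC"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_prediction_matrix(M, f)
  lines <- readLines(f)
  expect_match(lines[1], "^class\t\tMC\tNPC$")
  expect_equal(length(lines), 4L) # header, colnames, two sign rows
})
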