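test_that("is_consistent_coloring applies the three local rules", {
  g <- fork_graph()
  expect_true(is_consistent_coloring(g, c(A = "+", B = "+", C = "-")))
  expect_false(is_consistent_coloring(g, c(A = "+", B = "+", C = "+")))
  expect_true(is_consistent_coloring(g, c(A = "0", B = "0", C = "0")))
  expect_error(is_consistent_coloring(g, c(A = "+", B = "+")),
               "every graph node")

  # an isolated input is consistent under any sign
  iso <- signed_graph(data.frame(source = character(0),
                                 sign = character(0),
                                 target = character(0)), nodes = "X")
  for (s in c("+", "-", "0")) {
    expect_true(is_consistent_coloring(iso, stats::setNames(s, "X")))
  }
})

test_that("invariant rule accepts opposite variant influences", {
  g <- signed_graph(data.frame(source = c("A", "B"), sign = c("+", "+"),
                               target = c("C", "C")))
  expect_true(is_consistent_coloring(g, c(A = "+", B = "-", C = "0")))
  expect_false(is_consistent_coloring(g, c(A = "+", B = "+", C = "0")))
})

test_that("enumerate_colorings is exhaustive and respects the labeling", {
  iso <- signed_graph(data.frame(source = character(0),
                                 sign = character(0),
                                 target = character(0)), nodes = "X")
  expect_equal(ncol(enumerate_colorings(iso)), 3L)

  g <- fork_graph()
  one <- enumerate_colorings(g, labeling(c(B = "+", C = "-")))
  expect_equal(ncol(one), 1L)
  expect_identical(unname(one["A", 1]), "+")
  none <- enumerate_colorings(g, labeling(c(B = "+", C = "+")))
  expect_equal(ncol(none), 0L)

  expect_error(enumerate_colorings(random_graph(14, seed = 3)),
               "refused")
})

test_that("the seven projection classes map sign sets bijectively", {
  expect_identical(projection_class("+"), "+")
  expect_identical(projection_class(c("+", "-")), "change")
  expect_identical(projection_class(c("+", "-", "0")), "?")
  expect_identical(projection_class(c("-", "0")), "Not+")
  expect_identical(projection_class(c("+", "0")), "Not-")
  expect_error(projection_class(character(0)), "undefined")
  expect_error(project_signs(matrix(character(0), nrow = 2,
                                    dimnames = list(c("a", "b"), NULL))),
               "undefined")
})

test_that("MCOS repairs the fork instance with all minimal sets", {
  g <- fork_graph()
  r <- solve_consistency(g, labeling(c(B = "+", C = "+")), "mcos")
  expect_identical(r$score, 1L)
  expect_setequal(lapply(r$repairs, identity), list("B", "C"))
  expect_identical(unname(r$projections["A"]), "change")
  # observed nodes keep their observed strong class
  expect_identical(unname(r$projections["B"]), "+")
  expect_identical(unname(r$projections["C"]), "+")
})

test_that("SCENFIT repairs the fork instance at cost 2", {
  g <- fork_graph()
  r <- solve_consistency(g, labeling(c(B = "+", C = "+")), "scenfit")
  expect_identical(r$score, 2L)
  expect_true(any(vapply(r$repairs, function(d)
    identical(d$node, "B"), logical(1))))
  expect_true(any(vapply(r$repairs, function(d)
    identical(d$node, "C"), logical(1))))
  # oracle agreement on the full repair set
  o <- oracle_scenfit(g, c(B = "+", C = "+"))
  expect_identical(r$score, o$score)
  expect_setequal(r$repairs, o$repairs)
})

test_that("consistent labelings solve at score 0 in both modes", {
  g <- fork_graph()
  b <- labeling(c(B = "+", C = "-"))
  for (mode in c("mcos", "scenfit")) {
    r <- solve_consistency(g, b, mode)
    expect_identical(r$score, 0L)
    expect_identical(r$repairs,
                     if (mode == "mcos") list(character(0)) else
                       list(data.frame(node = character(0),
                                       from = character(0),
                                       to = character(0))))
    expect_identical(unname(r$projections["A"]), "+")
  }
})

test_that("solver matches the brute-force oracle on random instances", {
  n_cases <- 40
  for (i in seq_len(n_cases)) {
    g <- random_graph(n_nodes = 4 + (i %% 3), p_edge = 0.35, seed = 100 + i)
    b <- random_labeling(g, p_obs = 0.7, seed = 200 + i)
    bc <- as.character(c("+", "-", "0")[match(b$signs, c(1L, -1L, 0L))])
    names(bc) <- names(b$signs)

    m <- solve_consistency(g, b, "mcos")
    om <- oracle_mcos(g, bc)
    expect_identical(m$score, as.integer(om$score))
    expect_setequal(m$repairs, om$repairs)
    expect_identical(m$projections[sort(names(m$projections))],
                     om$projections[sort(names(om$projections))])

    s <- solve_consistency(g, b, "scenfit")
    os <- oracle_scenfit(g, bc)
    expect_identical(s$score, as.integer(os$score))
    expect_setequal(s$repairs, os$repairs)
    expect_identical(s$projections[sort(names(s$projections))],
                     os$projections[sort(names(os$projections))])
  }
})

test_that("adding observations never decreases the SCENFIT score", {
  for (i in 1:15) {
    g <- random_graph(5, p_edge = 0.35, seed = 300 + i)
    b <- random_labeling(g, p_obs = 0.9, seed = 400 + i)
    if (length(b$signs) < 2) next
    sub <- labeling(b$signs[-1], b$profile_id)
    expect_lte(solve_consistency(g, sub, "scenfit")$score,
               solve_consistency(g, b, "scenfit")$score)
  }
})

test_that("repair results serialise to JSON and TSV", {
  skip_if_not_installed("jsonlite")
  g <- fork_graph()
  r <- solve_consistency(g, labeling(c(B = "+", C = "+")), "mcos")
  dir <- withr::local_tempdir()
  jf <- file.path(dir, "r.json"); tf <- file.path(dir, "r.tsv")
  write_repair_result(r, jf, tf)
  j <- jsonlite::read_json(jf)
  expect_equal(j$score, 1)
  expect_equal(j$n_repair_sets, 2)
  tab <- read.delim(tf)
  expect_setequal(tab$node, g$nodes)
})
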