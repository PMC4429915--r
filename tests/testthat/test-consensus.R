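# two-tip tree with one ancestor: convenient for hand-built pools
cons_fixture <- function() {
  tips <- list(t1 = c(1L, 2L, 3L, 4L), t2 = c(2L, 3L, 4L, 1L))
  toy_dataset(tips, "(t1,t2)root;")
}

sol_with_root <- function(root_seq) {
  m <- matrix(root_seq, nrow = 1, dimnames = list("root", NULL))
  toy_solution(m)
}

test_that("per-solution heterochronies follow move-set majority voting", {
  ds <- cons_fixture()
  # root identical to t1: branch to t2 has the unique cover {event 4, A}
  h <- solution_heterochronies(sol_with_root(c(1L, 2L, 3L, 4L)), ds)
  expect_equal(h[["root -> t1"]]$event, integer(0))
  expect_equal(h[["root -> t2"]]$event, 4L)
  expect_equal(h[["root -> t2"]]$direction, "A")
  # swap of two events yields two disjoint singleton covers: no majority
  ds2 <- toy_dataset(list(t1 = c(1L, 2L), t2 = c(2L, 1L)), "(t1,t2)root;")
  h2 <- solution_heterochronies(sol_with_root(c(1L, 2L)), ds2)
  expect_equal(nrow(h2[["root -> t2"]]), 0)
})

test_that("pseudoconsensus applies the strict 50% majority rule", {
  ds <- cons_fixture()
  s_yes <- sol_with_root(c(1L, 2L, 3L, 4L))  # records (t2, ev4, A)
  s_no <- sol_with_root(c(2L, 3L, 4L, 1L))   # records (t1, ev4, D)
  # 2 of 3 solutions: included at 66.7
  pool <- toy_pool(list(s_yes, s_yes, s_no), ds$tree, best_cost = 1)
  cons <- pseudoconsensus(pool, ds)
  r <- cons$records[cons$records$child == "t2", ]
  expect_equal(r$event, 4L)
  expect_equal(r$support, 100 * 2 / 3, tolerance = 1e-12)
  # 1 of 3: excluded
  expect_false(any(cons$records$child == "t1" & cons$records$event == 4 &
                     cons$records$support > 50 &
                     cons$records$direction == "D" &
                     cons$records$support < 50))
  expect_equal(nrow(cons$records[cons$records$child == "t1", ]), 0)
  # 3 of 3: support 100
  pool2 <- toy_pool(list(s_yes, s_yes, s_yes), ds$tree, best_cost = 1)
  cons2 <- pseudoconsensus(pool2, ds)
  expect_equal(cons2$records$support, 100)
  expect_true(all(cons2$records$support > 50 & cons2$records$support <= 100))
})

test_that("superconsensus pools solutions and averages run lengths", {
  ds <- cons_fixture()
  s <- sol_with_root(c(1L, 2L, 3L, 4L))
  p1 <- toy_pool(list(s), ds$tree, best_cost = 101)
  p2 <- toy_pool(list(s), ds$tree, best_cost = 100)
  p3 <- toy_pool(list(s), ds$tree, best_cost = 98)
  sup <- superconsensus(list(p1, p2, p3), ds)
  expect_equal(sup$run_tree_lengths, c(101, 100, 98))
  expect_equal(round(sup$mean_tree_length, 2), 99.67)
  expect_equal(sup$records$support, 100)
  # a single pool reduces to its pseudoconsensus
  expect_equal(superconsensus(list(p1), ds)$records,
               pseudoconsensus(p1, ds)$records)
  # superconsensus of k copies of one pool equals its pseudoconsensus
  expect_equal(superconsensus(list(p1, p1, p1), ds)$records,
               pseudoconsensus(p1, ds)$records)
})

test_that("supports are invariant under permutation of the solutions", {
  ds <- cons_fixture()
  s_yes <- sol_with_root(c(1L, 2L, 3L, 4L))
  s_no <- sol_with_root(c(2L, 3L, 4L, 1L))
  a <- pseudoconsensus(toy_pool(list(s_yes, s_yes, s_no), ds$tree, 1), ds)
  b <- pseudoconsensus(toy_pool(list(s_no, s_yes, s_yes), ds$tree, 1), ds)
  expect_equal(a$records, b$records)
})

test_that("mean-rank ancestors average ranks and keep exact-tie structure", {
  m1 <- matrix(c(2L, 4L, 1L), nrow = 1, dimnames = list("n", NULL))
  m2 <- matrix(c(4L, 2L, 1L), nrow = 1, dimnames = list("n", NULL))
  # single solution: identity
  expect_equal(mean_rank_ancestors(list(toy_solution(m1)))$n,
               canonicalize(c(2L, 4L, 1L)))
  # means 3, 3, 1 -> tie at exact equality
  anc <- mean_rank_ancestors(list(toy_solution(m1), toy_solution(m2)))
  expect_equal(unname(anc$n), c(2L, 2L, 1L))
  # order invariance
  anc2 <- mean_rank_ancestors(list(toy_solution(m2), toy_solution(m1)))
  expect_equal(anc, anc2)
  # absent anywhere stays absent
  m3 <- m1; m3[1, 2] <- NA_integer_
  anc3 <- mean_rank_ancestors(list(toy_solution(m1), toy_solution(m3)))
  expect_true(is.na(anc3$n[2]))
})

test_that("consensus outputs are written as TSV and JSON", {
  ds <- cons_fixture()
  pool <- toy_pool(list(sol_with_root(c(1L, 2L, 3L, 4L))), ds$tree, 1)
  cons <- pseudoconsensus(pool, ds)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_consensus(cons, tsv, js)
  recs <- read.delim(tsv)
  expect_equal(recs$event, 4L)
  anc <- jsonlite::read_json(js)
  expect_equal(unlist(anc$root), c(1, 2, 3, 4))
})
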