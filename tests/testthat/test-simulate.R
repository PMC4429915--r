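test_that("sim params validate their ranges", {
  expect_error(sim_params(n_events = 5, n_rank_levels = 6))
  expect_error(sim_params(tie_probability = 1))
  expect_error(sim_params(loss_probability = -0.1))
})

test_that("random sequences are canonical with the requested shape", {
  set.seed(20)
  p <- sim_params(n_events = 33, n_rank_levels = 10)
  for (i in 1:20) {
    s <- random_sequence(p)
    expect_false(anyNA(s))
    expect_lte(max(s), 10)
    expect_identical(canonicalize(s), s)
  }
  # zero tie probability with as many levels as events: strict permutation
  p0 <- sim_params(n_events = 8, n_rank_levels = 8, tie_probability = 0)
  s <- random_sequence(p0)
  expect_setequal(as.integer(s), 1:8)
  # determinism
  set.seed(5); a <- random_sequence(p)
  set.seed(5); b <- random_sequence(p)
  expect_identical(a, b)
})

test_that("tie frequency tracks the tie probability", {
  set.seed(30)
  p <- sim_params(n_events = 30, n_rank_levels = 30, tie_probability = 0.4)
  # fraction of adjacent placements that join the current level ~ 0.4
  ties <- replicate(300, {
    s <- random_sequence(p)
    1 - (max(s) - 1) / (length(s) - 1)
  })
  expect_equal(mean(ties), 0.4, tolerance = 0.05)
})

test_that("zero-shift simulations keep every tip at the root sequence", {
  tree <- ape::read.tree(text = "((a,b)n1,(c,d)n2)root;")
  tr <- simulate_sequences(tree, sim_params(n_events = 10, n_rank_levels = 5,
                                            shifts_per_branch = 0, seed = 1))
  expect_equal(nrow(tr$shifts), 0)
  for (t in rownames(tr$matrix)) {
    expect_identical(unname(tr$matrix[t, ]), unname(tr$root_sequence))
  }
})

test_that("simulations are reproducible and record replayable shifts", {
  tree <- ape::read.tree(text = "((a,b)n1,(c,d)n2)root;")
  p <- sim_params(n_events = 12, n_rank_levels = 6, shifts_per_branch = 2,
                  seed = 9)
  t1 <- simulate_sequences(tree, p)
  t2 <- simulate_sequences(tree, p)
  expect_identical(t1$matrix, t2$matrix)
  expect_identical(t1$shifts, t2$shifts)
  # k recorded shifts on a branch bound the branch's edit cost
  idx <- tree_branches(tree)
  seqs <- rbind(t1$matrix,
                root = t1$root_sequence)
  # reconstruct internal sequences by walking shifts? instead check the
  # recorded branch shift counts bound the cost on tip branches from the root
  # for the star-ish case we only check the invariant on branches where both
  # endpoint sequences are known (root -> internal unavailable); use a
  # two-tip tree for the exact bound
  tree2 <- ape::read.tree(text = "(a,b)root;")
  tr2 <- simulate_sequences(tree2, p)
  for (t in c("a", "b")) {
    k <- sum(tr2$shifts$child == t)
    expect_lte(parsimov_cost(tr2$root_sequence, tr2$matrix[t, ]), max(k, 0))
  }
})

test_that("per-branch shift counts follow the Poisson mean", {
  # 1000 root-to-tip branches on a star tree
  tree <- ape::read.tree(text = paste0("(",
    paste0("t", 1:1000, collapse = ","), ")root;"))
  tr <- simulate_sequences(tree, sim_params(n_events = 10, n_rank_levels = 5,
                                            shifts_per_branch = 1, seed = 4))
  counts <- table(factor(tr$shifts$child, levels = paste0("t", 1:1000)))
  m <- mean(counts)
  se <- sqrt(1 / 1000)  # Poisson variance = mean = 1
  expect_gt(m, 1 - 3 * se)
  expect_lt(m, 1 + 3 * se)
})

test_that("losses are inherited and reported as absences", {
  tree <- ape::read.tree(text = "((a,b)n1,c)root;")
  set.seed(2)
  tr <- simulate_sequences(tree, sim_params(n_events = 10, n_rank_levels = 5,
                                            shifts_per_branch = 0,
                                            loss_probability = 0.3, seed = 3))
  expect_true(anyNA(tr$matrix))
  ds <- sim_dataset(tr)
  expect_s3_class(ds, "het_dataset")
})

test_that("recovery score counts planted observable shifts", {
  tree <- ape::read.tree(text = "(a,b)root;")
  truth <- structure(list(
    shifts = data.frame(parent = c("root", "root"), child = c("a", "b"),
                        event = c(1L, 2L), old_pos = c(0, 0),
                        new_pos = c(1, 0), net = c(1, 0)),
    tree = tree), class = "sim_truth")
  cons_hit <- structure(list(
    records = data.frame(parent = "root", child = "a", event = 1L),
    tree = tree), class = "het_consensus")
  # the event-2 shift cancelled (net 0): excluded from the denominator
  sc <- recovery_score(truth, cons_hit)
  expect_equal(unname(sc), c(1, 1))
  cons_empty <- structure(list(
    records = data.frame(parent = character(0), child = character(0),
                         event = integer(0)),
    tree = tree), class = "het_consensus")
  expect_equal(unname(recovery_score(truth, cons_empty)), c(0, 1))
  truth0 <- truth; truth0$shifts <- truth0$shifts[0, ]
  expect_equal(unname(recovery_score(truth0, cons_empty)), c(1, 1))
})

test_that("simulated datasets round-trip through the NEXUS dialect", {
  tree <- ape::read.tree(text = "((a,b)n1,(c,d)n2)root;")
  tr <- simulate_sequences(tree, sim_params(n_events = 15, n_rank_levels = 8,
                                            shifts_per_branch = 1, seed = 6))
  nex <- withr::local_tempfile(fileext = ".nex")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_simulation(tr, nex, tsv)
  ds <- read_nexus(nex)
  expect_identical(ds$matrix, sim_dataset(tr)$matrix)
  shifts <- read.delim(tsv)
  expect_equal(nrow(shifts), nrow(tr$shifts))
})
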