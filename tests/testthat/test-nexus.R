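test_that("letters decode to high ranks and z to absent", {
  tmp <- withr::local_tempfile(fileext = ".nex")
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    "  DIMENSIONS NTAX=2 NCHAR=4;",
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"123456789abc\" MISSING=z;",
    "  MATRIX",
    "    t1 1abc",
    "    t2 12z3",
    "  ;",
    "END;",
    "BEGIN TREES;",
    "  TREE tree1 = [&R] (t1,t2)root;",
    "END;"), tmp)
  ds <- read_nexus(tmp)
  # a/b/c are ranks 10/11/12 before canonicalization; with the gaps closed
  # the order must be preserved
  expect_equal(unname(ds$matrix["t1", ]), c(1L, 2L, 3L, 4L))
  expect_true(is.na(ds$matrix["t2", 3]))
  expect_equal(unname(ds$matrix["t2", c(1, 2, 4)]), c(1L, 2L, 3L))
})

test_that("symbols outside the dialect are rejected with position info", {
  tmp <- withr::local_tempfile(fileext = ".nex")
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    "  MATRIX",
    "    t1 1x2",
    "    t2 123",
    "  ;",
    "END;",
    "BEGIN TREES;",
    "  TREE tree1 = [&R] (t1,t2)root;",
    "END;"), tmp)
  expect_error(read_nexus(tmp), "symbol 'x'.*line 4")
})

test_that("tip/matrix mismatches are reported", {
  tmp <- withr::local_tempfile(fileext = ".nex")
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    "  MATRIX",
    "    t1 12",
    "    tX 21",
    "  ;",
    "END;",
    "BEGIN TREES;",
    "  TREE tree1 = [&R] (t1,t2)root;",
    "END;"), tmp)
  expect_error(read_nexus(tmp), "t2.*tX")
})

test_that("write/read round-trips arbitrary in-dialect datasets", {
  set.seed(11)
  for (trial in 1:10) {
    n_tips <- sample(3:6, 1)
    n_ev <- sample(4:12, 1)
    tree <- ape::rtree(n_tips, rooted = TRUE,
                       tip.label = paste0("t", seq_len(n_tips)))
    tree$edge.length <- NULL
    m <- t(replicate(n_tips, random_canonical(n_ev, p_absent = 0.2,
                                              max_level = 12)))
    rownames(m) <- tree$tip.label
    ds <- het_dataset(m, tree)
    tmp <- withr::local_tempfile(fileext = ".nex")
    write_nexus(ds, tmp)
    ds2 <- read_nexus(tmp)
    expect_identical(ds2$matrix, ds$matrix)
    expect_equal(ape::write.tree(ds2$tree), ape::write.tree(ds$tree))
  }
})

test_that("ranks beyond 12 are unrepresentable and named in the error", {
  m <- rbind(t1 = c(1L, 13L), t2 = c(1L, 2L))
  m <- canonicalize_matrix(m)  # still canonical: 13 -> 2
  m[1, 2] <- 13L               # force an out-of-dialect rank
  ds <- structure(list(matrix = m,
                       tree = ape::read.tree(text = "(t1,t2)r;"),
                       events = NULL, outgroup = "t1"),
                  class = "het_dataset")
  tmp <- withr::local_tempfile(fileext = ".nex")
  expect_error(write_nexus(ds, tmp), "rank 13.*t1.*event 2")
})

test_that("the built-in rank table matches the published fixture", {
  ds7 <- load_eumalacostraca_dataset(duplicate_outgroup = FALSE)
  expect_equal(dim(ds7$matrix), c(7, 33))
  expect_equal(nrow(ds7$matrix), 7)
  # per-species maximum rank, directly assertable against the table
  expect_equal(apply(ds7$matrix, 1, max, na.rm = TRUE),
               c(Af = 9, Gf = 10, Si = 11, Nh = 9, Pf = 9, Ni = 9, Ph = 11))
  # spot checks: G.f. scores the antennal bud event first; the outgroup
  # lacks the sixth-pleopod bud
  expect_equal(unname(ds7$matrix["Gf", 1]), 1L)
  expect_true(is.na(ds7$matrix["Af", 6]))
  ds8 <- load_eumalacostraca_dataset(duplicate_outgroup = TRUE)
  expect_equal(length(ds8$tree$tip.label), 8)
  expect_identical(unname(ds8$matrix["Af_dup", ]), unname(ds8$matrix["Af", ]))
  # labelled ancestors present
  expect_setequal(
    setdiff(tree_branches(ds8$tree)$parent, tree_branches(ds8$tree)$child),
    "Branchiopod_Malacostracan_LCA")
  expect_true(all(c("Eumalacostraca_LCA", "Caridoida_LCA", "Decapoda_LCA",
                    "Pleocyemata_LCA", "Peracarida_LCA") %in%
                    tree_branches(ds8$tree)$parent))
  # the TSV mirror keeps the printed '-' / 'n.a.' distinction
  tsv <- read.delim(eumalacostraca_rank_table_path(), check.names = FALSE)
  expect_equal(nrow(tsv), 33)
  expect_equal(tsv[["A.f."]][6], "n.a.")
  expect_equal(tsv[["P.f."]][31], "-")
})
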