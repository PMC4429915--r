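# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's optimized code paths.

# all unordered pairs whose relation (before/simultaneous/after) is defined
# in both sequences and differs -- direct definition, no conflict graph
oracle_changed_pairs <- function(a, b) {
  n <- length(a)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (any(is.na(c(a[i], a[j], b[i], b[j])))) next
      ra <- sign(a[i] - a[j])
      rb <- sign(b[i] - b[j])
      if (ra != rb) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# minimum number of moving events by exhaustive subset search: a subset S
# explains the change iff every changed pair has an endpoint in S
oracle_cost <- function(a, b) {
  cp <- oracle_changed_pairs(a, b)
  if (!nrow(cp)) return(0L)
  verts <- sort(unique(c(cp)))
  for (k in 0:length(verts)) {
    if (k == 0) next
    subsets <- utils::combn(verts, k, simplify = FALSE)
    for (s in subsets) {
      covered <- apply(cp, 1, function(p) any(p %in% s))
      if (all(covered)) return(k)
    }
  }
  length(verts)
}

# all minimum covers by exhaustive subset search
oracle_min_covers <- function(a, b) {
  cp <- oracle_changed_pairs(a, b)
  if (!nrow(cp)) return(list(integer(0)))
  k <- oracle_cost(a, b)
  verts <- sort(unique(c(cp)))
  keep <- list()
  for (s in utils::combn(verts, k, simplify = FALSE)) {
    if (all(apply(cp, 1, function(p) any(p %in% s)))) {
      keep[[length(keep) + 1]] <- as.integer(s)
    }
  }
  keep
}

# a random canonical sequence over n events (possibly with ties/absences)
random_canonical <- function(n, p_absent = 0.1, max_level = n) {
  x <- sample.int(max_level, n, replace = TRUE)
  x[runif(n) < p_absent] <- NA_integer_
  if (all(is.na(x))) x[1] <- 1L
  canonicalize(x)
}

# tiny dataset builder: tips given as a named list of rank vectors
toy_dataset <- function(tips, newick) {
  m <- do.call(rbind, tips)
  het_dataset(m, ape::read.tree(text = newick))
}

# hand-built solution object for consensus tests
toy_solution <- function(node_sequences, cost = 0L) {
  list(node_sequences = node_sequences, total_cost = cost)
}

toy_pool <- function(solutions, tree, best_cost = NULL) {
  if (is.null(best_cost)) best_cost <- solutions[[1]]$total_cost
  structure(list(best_cost = as.integer(best_cost), solutions = solutions,
                 sweep_costs = best_cost, tree = tree,
                 params = search_params()),
            class = "het_pool")
}
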