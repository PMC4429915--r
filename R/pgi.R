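# PGi-style search: the whole developmental sequence is treated as a single
# complex character, and a genetic algorithm looks for assignments of ranked
# sequences to the internal nodes of a rooted tree that minimize the summed
# Parsimov edit cost over branches. Per-node co-optimal sequences are
# retained, and whole-tree solutions of equal minimal cost are collected by
# exact dynamic programming over the retained sets ("semi-exhaustive", capped).

#' Search parameters for the genetic algorithm
#'
#' Defaults are the study's published settings: 100 cycles of selection
#' per node, 200 sequences per cycle, at most 100 retained ancestral
#' sequences per node, and a cap of 3,000 collected equal-score solutions.
#'
#' @param cycles_per_node GA cycles per node visit
#' @param population candidate sequences evaluated per cycle
#' @param retain_per_node maximum co-optimal sequences retained per node
#' @param solution_cap maximum number of equal-score whole-tree solutions
#' @param max_sweeps maximum alternating post-/pre-order sweeps
#' @param move_set_cap cap on enumerated minimal move sets per branch
#' @param seed integer seed for the run's RNG (optional)
#' @return a list of class `het_params`
#' @export
search_params <- function(cycles_per_node = 100L, population = 200L,
                          retain_per_node = 100L, solution_cap = 3000L,
                          max_sweeps = 10L, move_set_cap = 64L, seed = NULL) {
  p <- list(cycles_per_node = as.integer(cycles_per_node),
            population = as.integer(population),
            retain_per_node = as.integer(retain_per_node),
            solution_cap = as.integer(solution_cap),
            max_sweeps = as.integer(max_sweeps),
            move_set_cap = as.integer(move_set_cap),
            seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(p$cycles_per_node >= 1, p$population >= 1,
            p$retain_per_node >= 1, p$solution_cap >= 1, p$max_sweeps >= 1)
  if (p$retain_per_node > p$population)
    stop("retain_per_node must not exceed population")
  class(p) <- "het_params"
  p
}

#' Reduced-effort parameter profile
#'
#' A cheaper profile (20 cycles, 50 candidates, 20 retained, 200-solution
#' cap) for continuous testing and quick exploration; results are noisier
#' than with [search_params()] defaults.
#' @param seed optional seed
#' @return a `het_params` list
#' @export
fast_params <- function(seed = NULL) {
  search_params(cycles_per_node = 20L, population = 50L,
                retain_per_node = 20L, solution_cap = 200L, seed = seed)
}

#' Local objective of the per-node search
#'
#' Sum of Parsimov costs between a candidate ancestral sequence and the
#' node's current neighbours (parent and children; the root uses its
#' children only).
#'
#' @param candidate ranked sequence
#' @param neighbors list of ranked sequences, or a matrix with one
#'   neighbour per row
#' @return non-negative integer
#' @export
node_fitness <- function(candidate, neighbors) {
  if (is.list(neighbors)) neighbors <- do.call(rbind, neighbors)
  if (is.null(neighbors) || nrow(neighbors) == 0)
    stop("neighbor list must not be empty")
  storage.mode(neighbors) <- "integer"
  cpp_fitness(matrix(as.integer(candidate), nrow = 1), neighbors)[1]
}

# mutation: with equal probability shift one present event by one rank level
# (joining the adjacent level or stepping out of a tie into a new level) or
# relocate one present event to a uniformly chosen existing rank level
mutate_seq <- function(seq, present_idx, depth = 0) {
  e <- present_idx[sample.int(length(present_idx), 1)]
  x <- as.numeric(seq)
  k <- max(x, na.rm = TRUE)
  if (stats::runif(1) < 0.5) {
    s <- if (stats::runif(1) < 0.5) 1 else -1
    # join the adjacent level or settle between levels (leaving a tie)
    step <- if (stats::runif(1) < 0.5) s else 0.5 * s
    x[e] <- max(0.25, x[e] + step)
  } else {
    x[e] <- sample.int(k, 1)
  }
  out <- canonicalize(x)
  # occasional compound mutation helps escape single-move plateaus
  if (depth < 2 && stats::runif(1) < 0.25) {
    out <- mutate_seq(out, present_idx, depth + 1)
  }
  out
}

# crossover: per-event uniform choice of rank from the two parents
cross_seq <- function(p1, p2) {
  pick <- stats::runif(length(p1)) < 0.5
  x <- ifelse(pick, as.numeric(p1), as.numeric(p2))
  canonicalize(x)
}

#' One genetic-algorithm pass at a single node
#'
#' Runs `cycles_per_node` cycles of selection on a population of candidate
#' ancestral sequences, scored against the node's current neighbours, and
#' returns every co-optimal sequence found (up to `retain_per_node`). The
#' result is never worse than the incumbent, which seeds the population.
#'
#' @param neighbors matrix of neighbour sequences (one per row)
#' @param incumbent current assignment of the node (integer vector)
#' @param params a [search_params()] object
#' @return list with `retained` (matrix of co-optimal sequences, incumbent
#'   first if co-optimal), `fitness` (their common local cost), and `top`
#'   (the best `retain_per_node` distinct candidates seen, by local cost —
#'   the whole-tree recombination step searches over these, since a
#'   globally optimal assignment may pass through locally suboptimal
#'   sequences)
#' @export
optimize_node <- function(neighbors, incumbent, params = search_params()) {
  if (is.list(neighbors)) neighbors <- do.call(rbind, neighbors)
  if (is.null(neighbors) || nrow(neighbors) == 0)
    stop("neighbor list must not be empty")
  storage.mode(neighbors) <- "integer"
  incumbent <- as.integer(incumbent)
  present_idx <- which(!is.na(incumbent))
  m <- length(present_idx)
  # ordered-set-partition counts: number of canonical sequences over m events
  fubini <- c(1, 3, 13, 75, 541, 4683, 47293)
  if (m >= 1 && m <= length(fubini) &&
      fubini[m] <= params$cycles_per_node * params$population) {
    # the whole candidate space is smaller than the evaluations one GA pass
    # would spend on it: enumerate it exactly instead of sampling
    cands <- matrix(NA_integer_, nrow = fubini[m], ncol = length(incumbent))
    cands[, present_idx] <- all_canonical_sequences(m)
    fit <- cpp_fitness(cands, neighbors)
    best_fit <- min(fit)
    o <- order(fit)
    retained <- cands[fit == best_fit, , drop = FALSE]
    # keep the incumbent first when co-optimal, so sweeps stay stable
    inc_row <- which(apply(retained, 1, identical, incumbent))
    if (length(inc_row))
      retained <- retained[c(inc_row[1], setdiff(seq_len(nrow(retained)),
                                                 inc_row[1])), , drop = FALSE]
    if (nrow(retained) > params$retain_per_node)
      retained <- retained[seq_len(params$retain_per_node), , drop = FALSE]
    top <- cands[o[seq_len(min(length(o), params$retain_per_node))], ,
                 drop = FALSE]
    return(list(retained = retained, fitness = best_fit, top = top))
  }
  # seed the population with the incumbent and with each neighbour projected
  # onto the node's presence pattern (events the neighbour lacks keep the
  # incumbent's rank) -- lets a node adopt a neighbour's ordering wholesale
  seeds <- matrix(incumbent, nrow = 1)
  for (q in seq_len(nrow(neighbors))) {
    x <- as.numeric(incumbent)
    nb <- neighbors[q, ]
    take <- !is.na(nb) & !is.na(incumbent)
    if (!any(take)) next
    x[take] <- nb[take] + 0.001 * x[take]  # incumbent rank breaks ties
    seeds <- rbind(seeds, canonicalize(x))
  }
  seeds <- seeds[!duplicated(seeds), , drop = FALSE]
  fit0 <- cpp_fitness(seeds, neighbors)
  best_fit <- min(fit0)
  retained <- seeds[fit0 == best_fit, , drop = FALSE]
  # archive of the best distinct candidates seen, ranked by local cost
  arch_seq <- seeds
  arch_fit <- fit0
  prune_archive <- function() {
    o <- order(arch_fit)
    arch_seq <<- arch_seq[o, , drop = FALSE]
    arch_fit <<- arch_fit[o]
    if (nrow(arch_seq) > params$retain_per_node) {
      keep <- seq_len(params$retain_per_node)
      arch_seq <<- arch_seq[keep, , drop = FALSE]
      arch_fit <<- arch_fit[keep]
    }
  }
  prune_archive()
  if (best_fit == 0L || length(present_idx) == 0) {
    return(list(retained = retained, fitness = best_fit, top = arch_seq))
  }
  for (cycle in seq_len(params$cycles_per_node)) {
    n_off <- params$population - nrow(retained)
    if (n_off <= 0) n_off <- 1L
    off <- matrix(NA_integer_, nrow = n_off, ncol = length(incumbent))
    nr <- nrow(retained)
    for (o in seq_len(n_off)) {
      if (nr > 1 && stats::runif(1) < 0.5) {
        ij <- sample.int(nr, 2, replace = TRUE)
        child <- cross_seq(retained[ij[1], ], retained[ij[2], ])
      } else {
        child <- mutate_seq(retained[sample.int(nr, 1), ], present_idx)
      }
      off[o, ] <- child
    }
    off_fit <- cpp_fitness(off, neighbors)
    pool_seq <- rbind(retained, off)
    pool_fit <- c(rep(best_fit, nrow(retained)), off_fit)
    minf <- min(pool_fit)
    keep <- pool_seq[pool_fit == minf, , drop = FALSE]
    keep <- keep[!duplicated(keep), , drop = FALSE]
    if (nrow(keep) > params$retain_per_node)
      keep <- keep[seq_len(params$retain_per_node), , drop = FALSE]
    retained <- keep
    best_fit <- minf
    new_rows <- !duplicated(rbind(arch_seq, off))[nrow(arch_seq) + seq_len(nrow(off))]
    if (any(new_rows)) {
      arch_seq <- rbind(arch_seq, off[new_rows, , drop = FALSE])
      arch_fit <- c(arch_fit, off_fit[new_rows])
      prune_archive()
    }
  }
  list(retained = retained, fitness = best_fit, top = arch_seq)
}

# presence rule for ancestors: an event is present at every internal node
# iff it is present in at least one tip; absent-in-all events stay absent
ancestral_presence <- function(tip_matrix) {
  apply(!is.na(tip_matrix), 2, any)
}

# post-order initialization: rank-wise median of the children's sequences
init_assignments <- function(idx, tip_matrix, present) {
  n_events <- ncol(tip_matrix)
  nn <- length(idx$labels)
  asg <- matrix(NA_integer_, nrow = nn, ncol = n_events)
  rownames(asg) <- idx$labels
  asg[seq_len(idx$ntip), ] <- tip_matrix[idx$labels[seq_len(idx$ntip)], ]
  for (v in idx$postorder) {
    kids <- asg[idx$children[[v]], , drop = FALSE]
    med <- apply(kids, 2, function(col) {
      if (all(is.na(col))) NA_real_ else stats::median(col, na.rm = TRUE)
    })
    med[!present] <- NA_real_
    # events present at ancestors but unseen in any child: append at the end
    med[present & is.na(med)] <- max(med, 1, na.rm = TRUE) + 1
    asg[v, ] <- canonicalize(med)
  }
  asg
}

total_tree_cost <- function(idx, asg) {
  tot <- 0L
  for (r in seq_len(nrow(idx$edges))) {
    tot <- tot + cpp_pars_cost(asg[idx$edges[r, 1], ], asg[idx$edges[r, 2], ])
  }
  tot
}

#' Most-parsimonious ancestral sequence search on a tree
#'
#' Initializes every internal node from the rank-wise median of its
#' children (post-order), then performs alternating post-/pre-order sweeps
#' of [optimize_node()] until a full sweep no longer improves the total
#' cost (or `max_sweeps` is reached). Whole-tree solutions are then formed
#' from the per-node retained co-optimal sequences by exact dynamic
#' programming over the tree, and all assignments attaining the minimal
#' total cost are collected, up to `solution_cap`.
#'
#' @param ds a [het_dataset()]
#' @param params a [search_params()] object; `params$seed`, if set, seeds
#'   the run
#' @return an object of class `het_pool`: list with `best_cost`,
#'   `solutions` (each a list with `node_sequences` matrix and
#'   `total_cost`), `sweep_costs`, `tree`, `params`
#' @export
#' @examples
#' \donttest{
#' ds <- load_eumalacostraca_dataset()
#' pool <- optimize_tree(ds, fast_params(seed = 1))
#' pool$best_cost
#' }
optimize_tree <- function(ds, params = search_params()) {
  stopifnot(inherits(ds, "het_dataset"))
  if (!is.null(params$seed)) set.seed(params$seed)
  idx <- index_tree(ds$tree)
  tipm <- ds$matrix
  present <- ancestral_presence(tipm)
  asg <- init_assignments(idx, tipm, present)
  internal <- idx$postorder
  sweep_costs <- total_tree_cost(idx, asg)
  pool <- NULL
  # cumulative per-node candidate archive across sweeps and outer rounds;
  # earlier sweeps explore different basins, and the recombination step can
  # route a globally optimal assignment through any of them
  run_archive <- vector("list", length(idx$labels))
  add_to_archive <- function(v, rows) {
    merged <- rbind(rows, run_archive[[v]])
    merged <- merged[!duplicated(merged), , drop = FALSE]
    cap <- 2L * params$retain_per_node
    if (nrow(merged) > cap) merged <- merged[seq_len(cap), , drop = FALSE]
    run_archive[[v]] <<- merged
  }
  # outer loop: GA sweeps to a local optimum, then exact recombination of
  # the retained per-node co-optimal sets; when the recombined solution is
  # cheaper than the swept one, adopt it and sweep again
  repeat {
    for (s in seq_len(params$max_sweeps)) {
      order_s <- if (s %% 2 == 1) internal else rev(internal)
      for (v in order_s) {
        nb_idx <- c(idx$parent[v], idx$children[[v]])
        nb_idx <- nb_idx[!is.na(nb_idx)]
        res <- optimize_node(asg[nb_idx, , drop = FALSE], asg[v, ], params)
        asg[v, ] <- res$retained[1, ]
        add_to_archive(v, res$top)
      }
      cost_s <- total_tree_cost(idx, asg)
      sweep_costs <- c(sweep_costs, cost_s)
      if (cost_s >= sweep_costs[length(sweep_costs) - 1]) break
    }
    # collection pass against the final assignments (no reassignment);
    # the recombination searches over each node's best distinct candidates,
    # not only the locally co-optimal ones: a globally optimal assignment
    # may route through locally suboptimal node sequences
    retained <- vector("list", length(idx$labels))
    for (v in internal) {
      nb_idx <- c(idx$parent[v], idx$children[[v]])
      nb_idx <- nb_idx[!is.na(nb_idx)]
      res <- optimize_node(asg[nb_idx, , drop = FALSE], asg[v, ], params)
      add_to_archive(v, res$top)
      retained[[v]] <- rbind(asg[v, ], res$top, run_archive[[v]])
      retained[[v]] <- retained[[v]][!duplicated(retained[[v]]), , drop = FALSE]
    }
    pool <- combine_solutions(idx, asg, retained, params)
    if (pool$best_cost < sweep_costs[length(sweep_costs)]) {
      asg[rownames(pool$solutions[[1]]$node_sequences), ] <-
        pool$solutions[[1]]$node_sequences
      sweep_costs <- c(sweep_costs, pool$best_cost)
    } else break
  }
  pool$sweep_costs <- sweep_costs
  pool$tree <- ds$tree
  pool$params <- params
  class(pool) <- "het_pool"
  pool
}

# exact DP over the tree restricted to the per-node candidate sets;
# enumerates all minimum-cost combinations up to the solution cap
combine_solutions <- function(idx, asg, retained, params) {
  cand <- vector("list", length(idx$labels))
  for (v in seq_along(cand)) {
    cand[[v]] <- if (v <= idx$ntip) asg[v, , drop = FALSE] else retained[[v]]
  }
  subtree_cost <- vector("list", length(cand))   # per candidate of v
  choice <- vector("list", length(cand))         # per child: cost matrix + child scores
  for (v in idx$postorder) {
    nc <- nrow(cand[[v]])
    sc <- numeric(nc)
    ch_info <- list()
    for (ch in idx$children[[v]]) {
      m <- cpp_cost_matrix(cand[[v]], cand[[ch]])
      ch_sc <- if (ch > idx$ntip) subtree_cost[[ch]] else 0
      tot <- sweep(m, 2, ch_sc, "+")
      sc <- sc + apply(tot, 1, min)
      ch_info[[as.character(ch)]] <- tot
    }
    subtree_cost[[v]] <- sc
    choice[[v]] <- ch_info
  }
  best <- min(subtree_cost[[idx$root]])
  solutions <- list()
  # enumerate all optimal assignments of the subtree rooted at v given v = i,
  # returned as a list of assignment-index lists (bounded by solution_cap)
  enum_list <- function(v, i, acc) {
    acc[[as.character(v)]] <- i
    kids <- idx$children[[v]][idx$children[[v]] > idx$ntip]
    out <- list(acc)
    for (ch in kids) {
      tot <- choice[[v]][[as.character(ch)]]
      opts <- which(tot[i, ] == min(tot[i, ]))
      nxt <- list()
      for (a in out) {
        for (j in opts) {
          subs <- enum_list(ch, j, a)
          nxt <- c(nxt, subs)
          if (length(nxt) > params$solution_cap) break
        }
        if (length(nxt) > params$solution_cap) break
      }
      out <- nxt
    }
    out
  }
  roots <- which(subtree_cost[[idx$root]] == best)
  assignments <- list()
  for (i in roots) {
    subs <- enum_list(idx$root, i, list())
    assignments <- c(assignments, subs)
    if (length(assignments) >= params$solution_cap) break
  }
  if (length(assignments) > params$solution_cap)
    assignments <- assignments[seq_len(params$solution_cap)]
  # materialize and deduplicate
  keys <- character(0)
  for (a in assignments) {
    mat <- do.call(rbind, lapply(idx$postorder, function(v) {
      cand[[v]][a[[as.character(v)]], ]
    }))
    rownames(mat) <- idx$labels[idx$postorder]
    key <- paste(mat, collapse = ",")
    if (key %in% keys) next
    keys <- c(keys, key)
    solutions[[length(solutions) + 1]] <- list(node_sequences = mat,
                                               total_cost = best)
  }
  list(best_cost = as.integer(best), solutions = solutions)
}

#' @export
print.het_pool <- function(x, ...) {
  cat("Solution pool: best cost", x$best_cost, "with", length(x$solutions),
      "equal-score solutions\n")
  cat("Sweep costs:", paste(x$sweep_costs, collapse = " -> "), "\n")
  invisible(x)
}

# all canonical (dense) rank vectors over m present events
all_canonical_sequences <- function(m) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(m)), m)))
  keep <- apply(grid, 1, function(r) all(seq_len(max(r)) %in% r))
  grid[keep, , drop = FALSE]
}

#' Exhaustive search oracle for tiny instances
#'
#' Enumerates every canonical ranked sequence at every internal node and
#' returns the global optimum. Refuses instances with more than
#' `max_events` present events (at most 5) or more than 4 internal nodes;
#' intended as an independent check on [optimize_tree()].
#'
#' @param ds a [het_dataset()]
#' @param max_events largest admissible event universe (capped at 5)
#' @param solution_cap cap on collected solutions
#' @return a `het_pool` with the global optimum
#' @export
exhaustive_tree_search <- function(ds, max_events = 5L, solution_cap = 1000L) {
  stopifnot(inherits(ds, "het_dataset"))
  max_events <- min(as.integer(max_events), 5L)
  idx <- index_tree(ds$tree)
  tipm <- ds$matrix
  present <- ancestral_presence(tipm)
  m <- sum(present)
  if (m > max_events)
    stop("instance too large for exhaustive search: ", m, " events (limit ",
         max_events, ")")
  if (length(idx$postorder) > 4)
    stop("instance too large for exhaustive search: ",
         length(idx$postorder), " internal nodes (limit 4)")
  cands <- all_canonical_sequences(m)
  full <- matrix(NA_integer_, nrow = nrow(cands), ncol = ncol(tipm))
  full[, present] <- cands
  retained <- vector("list", length(idx$labels))
  for (v in idx$postorder) retained[[v]] <- full
  asg <- init_assignments(idx, tipm, present)
  pool <- combine_solutions(idx, asg, retained,
                            search_params(solution_cap = solution_cap))
  pool$sweep_costs <- pool$best_cost
  pool$tree <- ds$tree
  pool$params <- NULL
  class(pool) <- "het_pool"
  pool
}
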