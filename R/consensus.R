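# Majority-rule consensus over pools of equally parsimonious solutions.
# Per solution and branch, the heterochronies are the events appearing in a
# strict majority of that branch's minimal move sets ("one solution, one
# vote"); across solutions, a (branch, event, direction) record enters the
# consensus if it occurs in more than half of the solutions, and its
# occurrence percentage is reported as support. Ancestral sequences are the
# mean-rank summaries of the pooled solutions.

branch_key <- function(parent, child) paste(parent, child, sep = " -> ")

#' Per-branch heterochronies of a single tree solution
#'
#' For each branch, enumerates the minimal move sets between the parent
#' and child sequences and keeps the (event, direction) pairs present in
#' a strict majority of those sets; the direction is the majority
#' direction among the event's occurrences (`AMBIGUOUS` on a tie).
#'
#' @param sol a solution from a `het_pool` (list with `node_sequences`)
#' @param ds the [het_dataset()] supplying tips and tree
#' @param cap cap on enumerated move sets per branch
#' @param cache optional environment memoizing move-set enumerations
#' @return named list (one element per branch, `"parent -> child"`) of
#'   data frames with columns `event` and `direction`
#' @export
solution_heterochronies <- function(sol, ds, cap = 64L, cache = NULL) {
  idx <- index_tree(ds$tree)
  asg <- rbind(ds$matrix[idx$labels[seq_len(idx$ntip)], , drop = FALSE],
               sol$node_sequences[idx$labels[idx$postorder], , drop = FALSE])
  rownames(asg) <- c(idx$labels[seq_len(idx$ntip)], idx$labels[idx$postorder])
  out <- list()
  for (r in seq_len(nrow(idx$edges))) {
    p <- idx$labels[idx$edges[r, 1]]
    ch <- idx$labels[idx$edges[r, 2]]
    a <- asg[p, ]; b <- asg[ch, ]
    key <- paste(paste(a, collapse = ","), paste(b, collapse = ","), sep = "|")
    if (!is.null(cache) && !is.null(cache[[key]])) {
      sets <- cache[[key]]
    } else {
      sets <- minimum_move_sets(a, b, cap = cap)
      if (!is.null(cache)) cache[[key]] <- sets
    }
    out[[branch_key(p, ch)]] <- majority_moves(sets)
  }
  out
}

# strict majority vote over a branch's move sets
majority_moves <- function(sets) {
  nsets <- length(sets)
  if (nsets == 0)
    return(data.frame(event = integer(0), direction = character(0),
                      stringsAsFactors = FALSE))
  all_moves <- do.call(rbind, sets)
  if (is.null(all_moves) || nrow(all_moves) == 0)
    return(data.frame(event = integer(0), direction = character(0),
                      stringsAsFactors = FALSE))
  counts <- table(all_moves$event)
  keep <- as.integer(names(counts)[counts > nsets / 2])
  dir <- vapply(keep, function(e) {
    d <- all_moves$direction[all_moves$event == e]
    ta <- sum(d == "A"); td <- sum(d == "D")
    if (ta > td) "A" else if (td > ta) "D" else "AMBIGUOUS"
  }, character(1))
  data.frame(event = keep, direction = dir, stringsAsFactors = FALSE)
}

consensus_from_solutions <- function(solutions, ds, run_lengths,
                                     cap = 64L) {
  if (!length(solutions)) stop("empty solution pool")
  cache <- new.env(parent = emptyenv())
  per_sol <- lapply(solutions, solution_heterochronies, ds = ds, cap = cap,
                    cache = cache)
  nsol <- length(solutions)
  branches <- unique(unlist(lapply(per_sol, names)))
  recs <- list()
  for (br in branches) {
    votes <- list()
    for (s in per_sol) {
      h <- s[[br]]
      if (is.null(h) || !nrow(h)) next
      for (r in seq_len(nrow(h))) {
        k <- paste(h$event[r], h$direction[r])
        votes[[k]] <- (if (is.null(votes[[k]])) 0 else votes[[k]]) + 1
      }
    }
    for (k in names(votes)) {
      supp <- 100 * votes[[k]] / nsol
      if (supp > 50) {
        parts <- strsplit(k, " ", fixed = TRUE)[[1]]
        pc <- strsplit(br, " -> ", fixed = TRUE)[[1]]
        recs[[length(recs) + 1]] <- data.frame(
          parent = pc[1], child = pc[2],
          event = as.integer(parts[1]),
          abbrev = ds$events$abbrev[as.integer(parts[1])],
          direction = parts[2], support = supp,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(parent = character(0), child = character(0),
               event = integer(0), abbrev = character(0),
               direction = character(0), support = numeric(0),
               stringsAsFactors = FALSE)
  records <- records[order(records$parent, records$child, records$event), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(list(tree = ds$tree,
                 records = records,
                 ancestral_sequences = mean_rank_ancestors(solutions),
                 run_tree_lengths = run_lengths,
                 mean_tree_length = mean(run_lengths),
                 n_solutions = nsol),
            class = "het_consensus")
}

#' Pseudoconsensus tree of one run's solution pool
#'
#' Applies the 50% majority rule across the pool's equally parsimonious
#' solutions: a (branch, event, direction) heterochrony is kept iff it
#' occurs in more than half of the solutions, with its occurrence
#' percentage reported as support. Ancestral sequences are mean-rank
#' summaries over the pool.
#'
#' @param pool a `het_pool` from [optimize_tree()]
#' @param ds the [het_dataset()] analysed
#' @param cap cap on enumerated move sets per branch
#' @return an object of class `het_consensus` with elements `records`
#'   (data frame: parent, child, event, abbrev, direction, support),
#'   `ancestral_sequences`, `run_tree_lengths`, `mean_tree_length`
#' @export
pseudoconsensus <- function(pool, ds, cap = 64L) {
  stopifnot(inherits(pool, "het_pool"))
  if (!length(pool$solutions)) stop("empty solution pool")
  consensus_from_solutions(pool$solutions, ds, run_lengths = pool$best_cost,
                           cap = cap)
}

#' Superconsensus tree across independent runs
#'
#' Pools all equally parsimonious solutions of several runs into one
#' collection and applies the same majority rule, so support stays
#' interpretable as a fraction of solutions. `run_tree_lengths` lists each
#' run's best cost; `mean_tree_length` is their mean.
#'
#' @param pools list of `het_pool` objects over the same tree
#' @param ds the [het_dataset()] analysed
#' @param cap cap on enumerated move sets per branch
#' @return a `het_consensus`
#' @export
superconsensus <- function(pools, ds, cap = 64L) {
  if (!length(pools)) stop("need at least one pool")
  nwk <- vapply(pools, function(p) ape::write.tree(p$tree), character(1))
  if (length(unique(nwk)) != 1) stop("pools are over different trees")
  sols <- do.call(c, lapply(pools, `[[`, "solutions"))
  consensus_from_solutions(sols, ds,
                           run_lengths = vapply(pools, `[[`, integer(1),
                                                "best_cost"),
                           cap = cap)
}

#' Mean-rank ancestral sequences over equally parsimonious solutions
#'
#' Per node and event, averages the rank across solutions (an event absent
#' in any solution's node sequence stays absent) and converts the means to
#' a canonical ranked sequence; ties arise only at exact mean equality.
#'
#' @param solutions list of solutions (each with a `node_sequences` matrix
#'   over the same nodes)
#' @return named list of canonical ranked sequences, one per node
#' @export
mean_rank_ancestors <- function(solutions) {
  stopifnot(length(solutions) > 0)
  nodes <- rownames(solutions[[1]]$node_sequences)
  out <- list()
  for (nd in nodes) {
    rows <- vapply(solutions, function(s) s$node_sequences[nd, ],
                   numeric(ncol(solutions[[1]]$node_sequences)))
    rows <- matrix(rows, ncol = length(solutions))
    means <- rowMeans(rows)           # NA if absent anywhere
    out[[nd]] <- canonicalize(means)
  }
  out
}

#' @export
print.het_consensus <- function(x, ...) {
  cat("Consensus over", x$n_solutions, "solutions;",
      nrow(x$records), "majority-rule heterochronies\n")
  cat("Run tree lengths:", paste(x$run_tree_lengths, collapse = ", "),
      "(mean", round(x$mean_tree_length, 2), ")\n")
  invisible(x)
}

#' Write consensus outputs (records TSV + ancestral sequences JSON)
#'
#' @param consensus a `het_consensus`
#' @param records_path TSV output for the heterochrony records (support to
#'   one decimal)
#' @param ancestors_path JSON output for ancestral sequences keyed by node
#' @return invisibly, the two paths
#' @export
write_consensus <- function(consensus, records_path, ancestors_path) {
  recs <- consensus$records
  recs$support <- round(recs$support, 1)
  utils::write.table(recs, records_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  anc <- lapply(consensus$ancestral_sequences, function(s) {
    v <- as.integer(s)
    names(v) <- NULL
    v
  })
  jsonlite::write_json(anc, ancestors_path, auto_unbox = FALSE, null = "null",
                       na = "null")
  invisible(c(records_path, ancestors_path))
}
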