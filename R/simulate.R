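# Synthetic ranked-sequence evolution with known ground truth. Sequences
# evolve on a rooted tree by discrete event shifts: along each branch a
# Poisson number of uniformly chosen events relocate to uniformly chosen
# rank levels, and events may be lost (loss is inherited). The generator
# mirrors the shape of the empirical table: ~33 events on ~10 dense rank
# levels with frequent ties and occasional absences.

#' Simulation parameters
#'
#' Defaults mirror the fixture's shape: 33 events, 10 rank levels,
#' tie probability 0.35.
#'
#' @param n_events number of events
#' @param n_rank_levels number of dense rank levels (at most `n_events`)
#' @param tie_probability probability that consecutive events share a rank
#' @param shifts_per_branch Poisson mean number of event shifts per branch
#' @param loss_probability per-branch, per-event loss probability
#' @param seed optional seed
#' @return list of class `sim_params`
#' @export
sim_params <- function(n_events = 33L, n_rank_levels = 10L,
                       tie_probability = 0.35, shifts_per_branch = 1,
                       loss_probability = 0, seed = NULL) {
  p <- list(n_events = as.integer(n_events),
            n_rank_levels = as.integer(n_rank_levels),
            tie_probability = tie_probability,
            shifts_per_branch = shifts_per_branch,
            loss_probability = loss_probability,
            seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(p$n_events >= 1, p$n_rank_levels >= 1,
            p$n_rank_levels <= p$n_events,
            p$tie_probability >= 0, p$tie_probability < 1,
            p$shifts_per_branch >= 0,
            p$loss_probability >= 0, p$loss_probability < 1)
  class(p) <- "sim_params"
  p
}

#' Draw a random canonical ranked sequence
#'
#' Events are placed in random order; each subsequent event joins the
#' current rank level with probability `tie_probability` and opens a new
#' level otherwise. If more than `n_rank_levels` levels result, uniformly
#' chosen adjacent levels are merged until the limit holds, so ranks are
#' always dense within `1..n_rank_levels`.
#'
#' @param params a [sim_params()] object
#' @return canonical integer rank vector of length `n_events`
#' @export
random_sequence <- function(params) {
  n <- params$n_events
  ord <- sample.int(n)
  lev <- integer(n)
  cur <- 1L
  lev[ord[1]] <- 1L
  for (i in seq_len(n - 1)) {
    if (stats::runif(1) >= params$tie_probability) cur <- cur + 1L
    lev[ord[i + 1]] <- cur
  }
  k <- max(lev)
  while (k > params$n_rank_levels) {
    cut <- sample.int(k - 1, 1)  # merge levels cut and cut+1
    lev[lev > cut] <- lev[lev > cut] - 1L
    k <- k - 1L
  }
  canonicalize(lev)
}

#' Simulate ranked-sequence evolution on a tree
#'
#' Draws a root sequence with [random_sequence()], then walks the tree in
#' preorder applying, on every branch, `Poisson(shifts_per_branch)`
#' relocations of uniformly chosen present events to uniformly chosen rank
#' levels (followed by canonicalization) and independent event losses with
#' probability `loss_probability` (losses are inherited). Every shift is
#' recorded, along with its net normalized displacement over the branch.
#'
#' @param tree rooted `phylo` tree
#' @param params a [sim_params()] object; `params$seed`, if set, seeds the
#'   simulation
#' @return list of class `sim_truth` with `root_sequence`, `shifts` (data
#'   frame: parent, child, event, old_pos, new_pos, net — normalized
#'   positions in the parent and child sequences), `matrix` (tip rank
#'   matrix), `tree`, `params`
#' @export
simulate_sequences <- function(tree, params = sim_params()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  idx <- index_tree(tree)
  nn <- length(idx$labels)
  seqs <- vector("list", nn)
  root_seq <- random_sequence(params)
  seqs[[idx$root]] <- root_seq
  shifts <- list()
  visit <- function(v) {
    for (ch in idx$children[[v]]) {
      parent_seq <- seqs[[v]]
      x <- parent_seq
      nshift <- stats::rpois(1, params$shifts_per_branch)
      moved <- integer(0)
      old_pos <- new_pos <- numeric(0)
      for (s in seq_len(nshift)) {
        present <- which(!is.na(x))
        if (!length(present)) break
        e <- present[sample.int(length(present), 1)]
        k <- max(x, na.rm = TRUE)
        before <- normalized_positions(x)[e]
        x[e] <- sample.int(k, 1)
        x <- canonicalize(x)
        moved <- c(moved, e)
        old_pos <- c(old_pos, before)
        new_pos <- c(new_pos, normalized_positions(x)[e])
      }
      if (params$loss_probability > 0) {
        present <- which(!is.na(x))
        lose <- present[stats::runif(length(present)) < params$loss_probability]
        x[lose] <- NA_integer_
        x <- canonicalize(x)
      }
      if (length(moved)) {
        # net displacement over the whole branch (parent vs final child);
        # repeated shifts of one event share its net value
        pa <- normalized_positions(parent_seq)
        pb <- normalized_positions(x)
        net <- pb[moved] - pa[moved]
        shifts[[length(shifts) + 1]] <<- data.frame(
          parent = idx$labels[v], child = idx$labels[ch],
          event = moved,
          old_pos = unname(old_pos), new_pos = unname(new_pos),
          net = unname(net),
          stringsAsFactors = FALSE)
      }
      seqs[[ch]] <<- x
      if (ch > idx$ntip) visit(ch)
    }
  }
  visit(idx$root)
  tipm <- do.call(rbind, seqs[seq_len(idx$ntip)])
  rownames(tipm) <- idx$labels[seq_len(idx$ntip)]
  shifts <- if (length(shifts)) do.call(rbind, shifts) else
    data.frame(parent = character(0), child = character(0),
               event = integer(0), old_pos = numeric(0),
               new_pos = numeric(0), net = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(root_sequence = root_seq, shifts = shifts, matrix = tipm,
                 tree = tree, params = params),
            class = "sim_truth")
}

#' Dataset view of a simulation
#'
#' @param truth a `sim_truth` from [simulate_sequences()]
#' @return a [het_dataset()] over the simulated tips
#' @export
sim_dataset <- function(truth) {
  het_dataset(truth$matrix, truth$tree)
}

#' Recovery of planted shifts by a consensus tree
#'
#' Recall is the fraction of planted (branch, event) shifts with nonzero
#' net normalized displacement that appear as consensus records on the
#' same branch; precision is the fraction of records matching such a
#' planted shift. Cancelling shifts (zero net displacement) are
#' unobservable in principle and excluded from the denominator. With no
#' observable shifts and no records, both are 1 by convention.
#'
#' @param truth a `sim_truth`
#' @param consensus a `het_consensus` over the same tree
#' @return named numeric vector `c(recall, precision)`
#' @export
recovery_score <- function(truth, consensus) {
  if (ape::write.tree(truth$tree) != ape::write.tree(consensus$tree))
    stop("truth and consensus are over different trees")
  planted <- truth$shifts
  # cancelled shifts (zero net) and shifts of events subsequently lost on the
  # branch (net NA) are unobservable in principle
  planted <- planted[!is.na(planted$net) & abs(planted$net) > 1e-12, ,
                     drop = FALSE]
  pkey <- unique(paste(planted$parent, planted$child, planted$event))
  recs <- consensus$records
  rkey <- unique(paste(recs$parent, recs$child, recs$event))
  recall <- if (length(pkey)) mean(pkey %in% rkey) else 1
  precision <- if (length(rkey)) mean(rkey %in% pkey) else 1
  c(recall = recall, precision = precision)
}

#' Write a simulated dataset (NEXUS) and its ground truth (TSV)
#'
#' @param truth a `sim_truth`
#' @param nexus_path output NEXUS path
#' @param truth_path output TSV path for the planted shifts
#' @return invisibly, the two paths
#' @export
write_simulation <- function(truth, nexus_path, truth_path) {
  write_nexus(sim_dataset(truth), nexus_path)
  utils::write.table(truth$shifts, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nexus_path, truth_path))
}
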