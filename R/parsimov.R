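# Event-pair edit cost between two ranked sequences. The relative timing of
# every pair of events (before / simultaneous / after) is the unit of
# comparison; the edit cost of a branch is the smallest number of events
# whose movement explains all pair relations that changed — the minimum
# vertex cover of the conflict graph whose edges are the changed pairs.
# Pairs involving an absent event are undefined and contribute nothing:
# absence is missing data, not heterochrony.

#' Relation of an event pair within a sequence
#'
#' @param seq canonical ranked sequence (integer vector, `NA` = absent)
#' @param i,j event indices (1-based positions in the universe), `i != j`
#' @return one of `"BEFORE"`, `"SIMULTANEOUS"`, `"AFTER"`, `"UNDEFINED"`
#' @export
#' @examples
#' pair_relation(c(1L, 2L), 1, 2)       # "BEFORE"
#' pair_relation(c(1L, NA), 1, 2)       # "UNDEFINED"
pair_relation <- function(seq, i, j) {
  n <- length(seq)
  if (i < 1 || i > n || j < 1 || j > n) stop("unknown event id")
  if (i == j) stop("pair must consist of two distinct events")
  ri <- seq[i]; rj <- seq[j]
  if (is.na(ri) || is.na(rj)) return("UNDEFINED")
  if (ri < rj) "BEFORE" else if (ri > rj) "AFTER" else "SIMULTANEOUS"
}

#' Event pairs whose relation differs between two sequences
#'
#' Pairs undefined (one event absent) in either sequence are never
#' reported.
#'
#' @param a,b canonical ranked sequences over the same event universe
#' @return two-column integer matrix of event indices, one changed pair
#'   per row (`i < j`)
#' @export
changed_pairs <- function(a, b) {
  validate_same_universe(a, b)
  cpp_changed_pairs(as.integer(a), as.integer(b))
}

#' Parsimov edit cost between two ranked sequences
#'
#' The minimum number of events whose movement explains every changed
#' event-pair relation, computed exactly as the minimum vertex cover of
#' the changed-pair conflict graph (branch and bound; conflict graphs here
#' have at most as many vertices as events). Symmetric, zero iff no pair
#' relation changed.
#'
#' @param a,b canonical ranked sequences over the same event universe
#' @return non-negative integer cost
#' @export
#' @examples
#' parsimov_cost(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 1L))  # one event moved
parsimov_cost <- function(a, b) {
  validate_same_universe(a, b)
  cpp_pars_cost(as.integer(a), as.integer(b))
}

#' Minimal move sets between two sequences, with directions
#'
#' Enumerates every minimum vertex cover of the changed-pair conflict
#' graph (capped), i.e. every smallest set of events whose movement
#' explains the differences between `a` and `b`. Each moved event is
#' labelled `A` (accelerated) if its normalized sequence position
#' `(rank-1)/(k-1)` is smaller in `b` than in `a`, `D` (delayed) if
#' larger, and `AMBIGUOUS` if unchanged (e.g. a pure tie change).
#'
#' @param a,b canonical ranked sequences over the same event universe;
#'   `a` is read as the ancestral (parent) state and `b` as the derived
#'   (child) state
#' @param cap maximum number of move sets to enumerate (default 64)
#' @return list of data frames with columns `event` (index) and
#'   `direction`; a single empty data frame when the sequences agree
#' @export
minimum_move_sets <- function(a, b, cap = 64L) {
  validate_same_universe(a, b)
  if (!is.numeric(cap) || cap < 1) stop("cap must be a positive integer")
  covers <- cpp_min_covers(as.integer(a), as.integer(b), as.integer(cap))
  pa <- normalized_positions(a)
  pb <- normalized_positions(b)
  lapply(covers, function(ev) {
    ev <- as.integer(ev)
    dir <- vapply(ev, function(e) {
      if (is.na(pa[e]) || is.na(pb[e])) return("AMBIGUOUS")
      if (pb[e] < pa[e]) "A" else if (pb[e] > pa[e]) "D" else "AMBIGUOUS"
    }, character(1))
    data.frame(event = ev, direction = dir, stringsAsFactors = FALSE)
  })
}

#' Presence/absence differences between two sequences
#'
#' Evolutionary gain or loss of events along a branch is reported
#' separately from heterochrony: pairs involving absent events carry no
#' edit cost, so losses (e.g. of the nauplius eye anlage within
#' Peracarida) never masquerade as timing shifts.
#'
#' @param a,b ranked sequences over the same event universe (`a` parent,
#'   `b` child)
#' @return data frame with columns `event` and `change`
#'   (`"lost"`/`"gained"`)
#' @export
presence_diff <- function(a, b) {
  validate_same_universe(a, b)
  lost <- which(!is.na(a) & is.na(b))
  gained <- which(is.na(a) & !is.na(b))
  data.frame(event = c(lost, gained),
             change = rep(c("lost", "gained"), c(length(lost), length(gained))),
             stringsAsFactors = FALSE)
}
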