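#' Developmental event table for eumalacostracan ontogeny
#'
#' Returns the catalogue of the 33 developmental events scored across the
#' seven study species: appearance of appendage buds (epidermal events),
#' onset of segmentation, first appearance of muscle precursor groups
#' (myogenic events), ganglion anlagen and other neurogenic features, and
#' hatching. Each event carries its tissue type, germ layer, and the body
#' segment(s) it is affiliated with; composite events (e.g. the joint
#' first/second antenna bud) list several segments.
#'
#' Tissue membership partitions the table: events 1-6 are epidermal,
#' 8-25 myogenic, 26-32 neurogenic; events 7 (segmentation offset) and
#' 33 (hatching) belong to no tissue. Events with problematic segment
#' affiliation (FS, st, NEA, HAT) carry an empty segment set and are
#' excluded from segment-level rate aggregation.
#'
#' @return A data frame with one row per event and columns `id`, `abbrev`,
#'   `category`, `tissue`, `germ_layer` and `segments` (comma-separated,
#'   possibly empty).
#' @seealso [segment_rates()], [tissue_rates()]
#' @export
#' @examples
#' ev <- default_event_table()
#' table(ev$tissue)
default_event_table <- function() {
  ev <- data.frame(
    id = 1:33,
    abbrev = c("[A1/A2]", "[Md]", "[Mx1]", "[Mx2]", "[T1]", "[P6]",
               "[FS]", "[st]",
               "[a1-m]", "[a1-l]", "[a2-m]", "[a2-l]", "[md-m]", "[md-l]",
               "[mx1-m]", "[mx1-l]", "[lmp-mx1]",
               "[mx2-m]", "[mx2-l]", "[lmp-mx2]",
               "[t1-m]", "[t1-l]", "[lmp-t1]",
               "[lmp-p6]", "[lmp-post]",
               "[NGA]", "[mx1-g]", "[mx2-g]", "[t1-g]", "[p6-g]",
               "[NEA]", "[PPN]", "[HAT]"),
    category = c(rep("epidermal-appendage", 6), "segmentation",
                 rep("myogenesis", 18), rep("neurogenesis", 7), "hatching"),
    tissue = c(rep("epidermis", 6), "none",
               rep("muscle", 18), rep("neural", 7), "none"),
    germ_layer = c(rep("ectoderm", 6), "none",
                   rep("mesoderm", 18), rep("ectoderm", 7), "none"),
    segments = c("A1,A2", "Md", "Mx1", "Mx2", "T1", "P6",
                 "", "",
                 "A1", "A1", "A2", "A2", "Md", "Md",
                 "Mx1", "Mx1", "Mx1",
                 "Mx2", "Mx2", "Mx2",
                 "T1", "T1", "T1",
                 "P6", "telson",
                 "A1,A2,Md", "Mx1", "Mx2", "T1", "P6",
                 "", "telson", ""),
    stringsAsFactors = FALSE
  )
  ev
}

#' Segment affiliations of an event as a character vector
#'
#' @param events event table as returned by [default_event_table()]
#' @param id event id
#' @return character vector of segment names (possibly empty)
#' @keywords internal
event_segments <- function(events, id) {
  s <- events$segments[match(id, events$id)]
  if (is.na(s) || !nzchar(s)) return(character(0))
  strsplit(s, ",", fixed = TRUE)[[1]]
}

#' Canonicalize a ranked developmental sequence
#'
#' Re-ranks a sequence so that the occupied rank levels are exactly
#' `1..k` (dense ranking), preserving the order and ties among present
#' events. Absent events (`NA`) are left untouched. All module boundaries
#' in this package assume canonical sequences, so that rank arithmetic is
#' comparable across species.
#'
#' @param seq integer (or numeric) vector of ranks, `NA` for absent events;
#'   names, if any, are preserved.
#' @return integer vector of dense ranks with the same names and `NA`
#'   pattern as the input.
#' @export
#' @examples
#' canonicalize(c(A = 2, B = 5, C = 5))   # -> 1, 2, 2
#' canonicalize(c(A = 4, B = NA, C = 1))  # -> 2, NA, 1
canonicalize <- function(seq) {
  x <- seq
  if (!is.numeric(x)) stop("ranks must be numeric")
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad)) {
    nm <- if (!is.null(names(x))) names(x)[bad[1]] else as.character(bad[1])
    stop("non-positive rank for event ", nm)
  }
  present <- !is.na(x)
  lev <- sort(unique(x[present]))
  out <- rep(NA_integer_, length(x))
  out[present] <- match(x[present], lev)
  names(out) <- names(x)
  out
}

#' Canonicalize every row of a rank matrix
#'
#' @param m integer matrix, taxa in rows, events in columns, `NA` = absent
#' @return matrix of the same shape with dense ranks per row
#' @export
canonicalize_matrix <- function(m) {
  stopifnot(is.matrix(m))
  storage.mode(m) <- "integer"
  out <- cpp_canon_rows(m)
  dimnames(out) <- dimnames(m)
  out
}

#' Normalized positions of events within a sequence
#'
#' Maps each present event's rank to `(rank - 1) / (k - 1)` where `k` is
#' the sequence's maximum rank, so sequences with different numbers of
#' rank levels are comparable; a single-level sequence maps to 0.
#'
#' @param seq canonical ranked sequence (integer vector, `NA` = absent)
#' @return numeric vector in `[0, 1]`, `NA` where absent
#' @export
normalized_positions <- function(seq) {
  k <- suppressWarnings(max(seq, na.rm = TRUE))
  if (!is.finite(k) || k <= 1) {
    out <- ifelse(is.na(seq), NA_real_, 0)
  } else {
    out <- (as.numeric(seq) - 1) / (k - 1)
  }
  names(out) <- names(seq)
  out
}

validate_same_universe <- function(a, b) {
  if (length(a) != length(b))
    stop("sequences are over different event universes")
  invisible(TRUE)
}
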