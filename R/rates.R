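# reported tables round half away from zero (1.115 -> 1.12, as printed
# tables conventionally do), unlike base round()'s half-to-even
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Heterochrony-rate statistics. The rate of an event is the number of
# heterochronic changes it shows across branches of the superconsensus tree
# multiplied by the mean support of those changes taken as a fraction
# (86% -> 0.86). Direction does not matter: accelerations, delays and
# ambiguous shifts all count as changes.

#' Heterochrony rate of a single event
#'
#' @param consensus a `het_consensus`
#' @param event_id event id
#' @return non-negative real; 0 when the event appears in no record
#' @export
#' @examples
#' # two recovered changes with supports 60% and 72% give 2 * 0.66 = 1.32
event_rate <- function(consensus, event_id) {
  ev <- consensus$records$event
  if (!is.numeric(event_id) || length(event_id) != 1)
    stop("event_id must be a single event id")
  hit <- ev == event_id
  if (!any(hit)) return(0)
  sum(hit) * mean(consensus$records$support[hit]) / 100
}

#' Per-event heterochrony rates
#'
#' @param consensus a `het_consensus`
#' @param events event table (defaults to [default_event_table()])
#' @return named numeric vector indexed by event id
#' @export
event_rates <- function(consensus, events = default_event_table()) {
  r <- vapply(events$id, function(e) event_rate(consensus, e), numeric(1))
  names(r) <- events$id
  r
}

#' Tissue-specific mean heterochrony rates
#'
#' Unweighted mean of the per-event rates over each tissue's events
#' (epidermis: appendage buds, ids 1-6; muscle: myogenic events, ids 8-25;
#' neural: ids 26-32). Events outside the three tissues (segmentation
#' offset, hatching) do not contribute.
#'
#' @param per_event named per-event rate vector from [event_rates()]
#' @param events event table
#' @return named numeric vector (`epidermis`, `neural`, `muscle`)
#' @export
tissue_rates <- function(per_event, events = default_event_table()) {
  out <- vapply(c("epidermis", "neural", "muscle"), function(t) {
    ids <- events$id[events$tissue == t]
    mean(per_event[as.character(ids)])
  }, numeric(1))
  out
}

#' Germ-layer mean heterochrony rates
#'
#' Ectoderm is the unweighted mean of the epidermis and neural tissue
#' rates; mesoderm equals the muscle tissue rate.
#'
#' @param tissue named vector from [tissue_rates()]
#' @return named numeric vector (`ectoderm`, `mesoderm`)
#' @export
#' @examples
#' germ_layer_rates(c(epidermis = 1.32, neural = 0.91, muscle = 1.72))
#' # ectoderm 1.115 (prints as 1.12), mesoderm 1.72
germ_layer_rates <- function(tissue) {
  c(ectoderm = unname((tissue["epidermis"] + tissue["neural"]) / 2),
    mesoderm = unname(tissue["muscle"]))
}

SEGMENTS <- c("A1", "A2", "Md", "Mx1", "Mx2", "T1", "P6", "telson")
SEGMENT_EXCLUDED_EVENTS <- c(7L, 8L, 31L, 33L)  # FS, st, NEA, HAT

#' Segment-by-tissue heterochrony rates
#'
#' For each body segment (A1, A2, Md, Mx1, Mx2, T1, P6, telson) and tissue
#' column: the appendage-bud cell carries the rate of the segment's bud
#' event (the composite first/second-antenna event applies to both A1 and
#' A2); the ganglion cell the segment's ganglion event (the composite
#' naupliar-ganglia event applies to A1, A2 and Md); the muscle cell the
#' mean rate of the segment's myogenic events. Events with problematic
#' segment affiliation (segmentation offset, stomodeal muscle group,
#' nauplius eye, hatching) are excluded throughout; cells with no
#' affiliated event are `NA`.
#'
#' @param per_event named per-event rate vector from [event_rates()]
#' @param events event table
#' @return numeric matrix, segments in rows, tissues
#'   (`epidermis`, `neural`, `muscle`) in columns
#' @export
segment_rates <- function(per_event, events = default_event_table()) {
  keep <- events[!events$id %in% SEGMENT_EXCLUDED_EVENTS, , drop = FALSE]
  out <- matrix(NA_real_, nrow = length(SEGMENTS), ncol = 3,
                dimnames = list(SEGMENTS, c("epidermis", "neural", "muscle")))
  for (seg in SEGMENTS) {
    for (tis in colnames(out)) {
      ids <- keep$id[keep$tissue == tis &
                       vapply(keep$id, function(i)
                         seg %in% event_segments(keep, i), logical(1))]
      if (length(ids)) out[seg, tis] <- mean(per_event[as.character(ids)])
    }
  }
  out
}

#' Full rate table for a consensus tree
#'
#' @param consensus a `het_consensus`
#' @param events event table
#' @return list with `per_event`, `per_tissue`, `per_germ_layer`,
#'   `per_segment`
#' @export
rate_table <- function(consensus, events = default_event_table()) {
  pe <- event_rates(consensus, events)
  tr <- tissue_rates(pe, events)
  list(per_event = pe,
       per_tissue = tr,
       per_germ_layer = germ_layer_rates(tr),
       per_segment = segment_rates(pe, events))
}

#' Write rate tables (germ-layer/tissue TSV, segment grid TSV, JSON)
#'
#' Reported rates are rounded to two decimals; internal arithmetic is
#' unrounded.
#'
#' @param rates result of [rate_table()]
#' @param dir output directory
#' @param events event table
#' @return invisibly, the written paths
#' @export
write_rate_tables <- function(rates, dir, events = default_event_table()) {
  tissue_tab <- data.frame(
    germ_layer = c("Ectoderm", "Ectoderm", "Mesoderm"),
    tissue = c("Epidermis", "Neural tissue", "Muscle tissue"),
    events = c(sum(events$tissue == "epidermis"),
               sum(events$tissue == "neural"),
               sum(events$tissue == "muscle")),
    mean_rate = round_half_up(rates$per_tissue[c("epidermis", "neural",
                                                 "muscle")]),
    germ_layer_rate = round_half_up(rates$per_germ_layer[
      c("ectoderm", "ectoderm", "mesoderm")]))
  p1 <- file.path(dir, "tissue_rates.tsv")
  utils::write.table(tissue_tab, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  seg <- round_half_up(rates$per_segment)
  p2 <- file.path(dir, "segment_rates.tsv")
  utils::write.table(cbind(segment = rownames(seg), as.data.frame(seg)), p2,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(dir, "event_rates.json")
  jsonlite::write_json(as.list(round(rates$per_event, 4)), p3,
                       auto_unbox = TRUE)
  invisible(c(p1, p2, p3))
}
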