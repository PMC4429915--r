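# NEXUS dialect of the study's data file: a DATA block of single-character
# states over SYMBOLS "123456789abc" (letters a/b/c stand for ranks 10/11/12),
# MISSING=z for absent events, plus a TREES block holding one rooted newick
# tree with named internal nodes. This is deliberately not a general NEXUS
# parser: interleaved matrices, polymorphic states and multiple trees are out
# of scope.

NEXUS_SYMBOLS <- c(as.character(1:9), "a", "b", "c")

decode_state <- function(ch) {
  i <- match(ch, NEXUS_SYMBOLS)
  if (!is.na(i)) return(i)
  if (ch == "z") return(NA_integer_)
  NULL
}

encode_state <- function(rank) {
  if (is.na(rank)) return("z")
  if (rank < 1 || rank > 12) return(NULL)
  NEXUS_SYMBOLS[rank]
}

generic_event_table <- function(n) {
  data.frame(id = seq_len(n), abbrev = paste0("E", seq_len(n)),
             category = "unknown", tissue = "none", germ_layer = "none",
             segments = "", stringsAsFactors = FALSE)
}

#' Assemble a heterochrony dataset
#'
#' Bundles a taxa-by-events rank matrix, a rooted tree and an event table
#' into the container consumed by [optimize_tree()] and friends, after
#' validating that tree tips and matrix rows agree and canonicalizing
#' every row.
#'
#' @param matrix integer matrix of dense ranks (`NA` = absent); row names
#'   are taxa, columns are events in id order
#' @param tree rooted `phylo` tree whose tip labels match the row names
#' @param events event table (defaults to [default_event_table()] for 33
#'   columns, a generic table otherwise)
#' @param outgroup outgroup taxon name (default: first matrix row)
#' @return an object of class `het_dataset`
#' @export
het_dataset <- function(matrix, tree, events = NULL, outgroup = NULL) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  if (is.null(events)) {
    events <- if (ncol(matrix) == 33) default_event_table()
              else generic_event_table(ncol(matrix))
  }
  tips <- tree$tip.label
  missing_rows <- setdiff(tips, rownames(matrix))
  extra_rows <- setdiff(rownames(matrix), tips)
  if (length(missing_rows) || length(extra_rows)) {
    stop("tree tips and matrix rows disagree; missing rows: ",
         paste(missing_rows, collapse = ", "), "; unmatched rows: ",
         paste(extra_rows, collapse = ", "))
  }
  if (is.null(outgroup)) outgroup <- rownames(matrix)[1]
  if (!outgroup %in% tips) stop("outgroup is not a tip of the tree")
  structure(list(matrix = canonicalize_matrix(matrix), tree = tree,
                 events = events, outgroup = outgroup),
            class = "het_dataset")
}

#' @export
print.het_dataset <- function(x, ...) {
  cat("Heterochrony dataset:", nrow(x$matrix), "taxa x", ncol(x$matrix),
      "events\n")
  cat("Taxa:", paste(rownames(x$matrix), collapse = ", "), "\n")
  cat("Outgroup:", x$outgroup, "\n")
  invisible(x)
}

#' Read a rank-matrix NEXUS file
#'
#' Parses the dialect described above: ranks 1-9 as digits, 10/11/12 as
#' letters a/b/c, absent events as 'z', and one rooted newick tree in a
#' TREES block. Rows are canonicalized on input; taxon order is preserved.
#'
#' @param path path to the NEXUS file
#' @param outgroup outgroup taxon (default: first taxon in the matrix)
#' @return a [het_dataset()]
#' @export
read_nexus <- function(path, outgroup = NULL) {
  lines <- readLines(path, warn = FALSE)
  # locate MATRIX .. ;
  mstart <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)
  if (length(mstart) != 1) stop("expected exactly one MATRIX block in ", path)
  taxa <- character(0)
  rows <- list()
  i <- mstart + 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == ";") break
    if (nzchar(ln)) {
      parts <- strsplit(ln, "\\s+")[[1]]
      if (length(parts) != 2)
        stop("cannot parse matrix row at line ", i, ": ", ln)
      taxon <- parts[1]
      states <- strsplit(parts[2], "")[[1]]
      ranks <- integer(length(states))
      for (k in seq_along(states)) {
        v <- decode_state(states[k])
        if (is.null(v)) {
          col <- regexpr(parts[2], lines[i], fixed = TRUE) + k - 1
          stop("symbol '", states[k], "' outside the dialect at line ", i,
               ", column ", col)
        }
        ranks[k] <- v
      }
      taxa <- c(taxa, taxon)
      rows[[taxon]] <- ranks
    }
    i <- i + 1
  }
  if (!length(taxa)) stop("empty matrix in ", path)
  nchar_ <- unique(lengths(rows))
  if (length(nchar_) != 1)
    stop("matrix rows have differing numbers of characters")
  m <- do.call(rbind, rows[taxa])
  rownames(m) <- taxa
  colnames(m) <- NULL
  # tree
  tline <- grep("^\\s*TREE\\s+", lines, ignore.case = TRUE, value = TRUE)
  if (length(tline) != 1) stop("expected exactly one TREE statement in ", path)
  nwk <- sub("^[^=]*=\\s*(\\[&R\\]\\s*)?", "", tline)
  tree <- ape::read.tree(text = nwk)
  if (is.null(tree)) stop("cannot parse newick tree in ", path)
  het_dataset(m, tree, outgroup = outgroup)
}

#' Write a dataset in the rank-matrix NEXUS dialect
#'
#' Inverse of [read_nexus()]: ranks 10/11/12 are encoded as a/b/c, absent
#' events as 'z'. Ranks above 12 are not representable in the dialect and
#' raise an error. The tree is written as newick with internal node labels
#' and no branch lengths.
#'
#' @param ds a [het_dataset()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_nexus <- function(ds, path) {
  m <- ds$matrix
  rows <- character(nrow(m))
  for (r in seq_len(nrow(m))) {
    chars <- character(ncol(m))
    for (c in seq_len(ncol(m))) {
      s <- encode_state(m[r, c])
      if (is.null(s))
        stop("rank ", m[r, c], " for taxon ", rownames(m)[r], ", event ", c,
             " exceeds the dialect limit of 12")
      chars[c] <- s
    }
    rows[r] <- paste0("    ", format(rownames(m)[r], width = 12), " ",
                      paste(chars, collapse = ""))
  }
  nwk <- ape::write.tree(ds$tree)
  out <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"123456789abc\" MISSING=z;",
    "  MATRIX",
    rows,
    "  ;",
    "END;",
    "BEGIN TREES;",
    paste0("  TREE tree1 = [&R] ", nwk),
    "END;")
  writeLines(out, path)
  invisible(path)
}

eumalacostraca_newick <- function() {
  paste0("(Af,(Gf,((Si,(Nh,Pf)Pleocyemata_LCA)Decapoda_LCA,",
         "(Ni,Ph)Peracarida_LCA)Caridoida_LCA)Eumalacostraca_LCA)",
         "Branchiopod_Malacostracan_LCA;")
}

#' Load the eumalacostracan rank-table dataset
#'
#' Returns the built-in seven-species, 33-event rank matrix (tips
#' `Af`, `Gf`, `Si`, `Nh`, `Pf`, `Ni`, `Ph` for *A. franciscana*,
#' *G. falcatus*, *S. ingentis*, *N. heteropoda*, *P. fallax*,
#' *N. integer*, *P. hawaiensis*) on the rooted topology with labelled
#' ancestors (Branchiopod/Malacostracan LCA at the root, then
#' Eumalacostraca, Caridoida, Decapoda, Pleocyemata and Peracarida LCAs).
#' Both "feature absent/lost" and "not applicable" codings collapse to
#' `NA`: absences are missing data for the event-pair cost, never
#' heterochronies.
#'
#' With `duplicate_outgroup = TRUE` (the default, matching the study
#' design) the *A. franciscana* row is added a second time under the tip
#' name `Af_dup`, attached at the root, so that the naupliar condition of
#' the outgroup anchors the root sequence during optimization.
#'
#' @param duplicate_outgroup add the outgroup row twice (default `TRUE`)
#' @return a [het_dataset()]
#' @export
#' @examples
#' ds <- load_eumalacostraca_dataset()
#' nrow(ds$matrix)  # 8 tips with the duplicated outgroup
load_eumalacostraca_dataset <- function(duplicate_outgroup = TRUE) {
  nex <- system.file("extdata", "eumalacostraca_ranks.nex",
                     package = "heterochron", mustWork = TRUE)
  ds <- read_nexus(nex, outgroup = "Af")
  if (duplicate_outgroup) {
    m <- rbind(ds$matrix, Af_dup = ds$matrix["Af", ])
    nwk <- ape::write.tree(ds$tree)
    nwk <- sub("^\\(", "(Af_dup,", nwk)  # attach duplicate at the root
    tree <- ape::read.tree(text = nwk)
    ds <- het_dataset(m, tree, events = ds$events, outgroup = "Af")
  }
  ds
}

#' Path to the TSV mirror of the printed rank table
#'
#' The distributed fixture keeps the published table verbatim, including
#' its distinction between '-' (feature absent or lost) and 'n.a.' (not
#' applicable to the outgroup); both are treated as absent in analysis.
#'
#' @return file path of the TSV
#' @export
eumalacostraca_rank_table_path <- function() {
  system.file("extdata", "eumalacostraca_ranks.tsv",
              package = "heterochron", mustWork = TRUE)
}
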