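# Helpers over ape "phylo" trees. The analysis is topology-only: trees are
# rooted, tips carry taxon names and internal nodes carry ancestor labels
# (e.g. "Eumalacostraca_LCA"); branch lengths are ignored.

#' Indexed view of a rooted phylogeny
#'
#' Precomputes node labels, parent pointers, children lists and a postorder
#' of the internal nodes for a rooted `phylo` tree. Unlabelled internal
#' nodes are given stable `NodeN` labels.
#'
#' @param tree an object of class `phylo` (rooted)
#' @return a list with elements `tree`, `labels` (tips then internals),
#'   `ntip`, `root`, `parent` (index vector, `NA` at the root), `children`
#'   (list of index vectors), `postorder` (internal node indices, children
#'   before parents) and `edges` (two-column matrix of parent/child indices).
#' @keywords internal
index_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  # the node without a parent is the root; a basal multifurcation (e.g. the
  # duplicated-outgroup topology) is a legitimate rooted tree here, even
  # though ape::is.rooted() would call it unrooted
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nlab <- tree$node.label
  if (is.null(nlab) || length(nlab) != nnode) nlab <- rep("", nnode)
  blank <- !nzchar(nlab) | is.na(nlab)
  nlab[blank] <- paste0("Node", which(blank) + ntip)
  labels <- c(tree$tip.label, nlab)
  nn <- ntip + nnode
  parent <- rep(NA_integer_, nn)
  children <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    parent[ch] <- p
    children[[p]] <- c(children[[p]], ch)
  }
  root <- which(is.na(parent) & seq_len(nn) > ntip)
  if (length(root) != 1) stop("tree must have exactly one root")
  # postorder over internal nodes
  post <- integer(0)
  visit <- function(v) {
    for (ch in children[[v]]) if (ch > ntip) visit(ch)
    post <<- c(post, v)
  }
  visit(root)
  list(tree = tree, labels = labels, ntip = ntip, root = root,
       parent = parent, children = children, postorder = post,
       edges = cbind(parent = parent[!is.na(parent)],
                     child = which(!is.na(parent))))
}

#' Branches of a rooted tree as parent/child label pairs
#'
#' @param tree a `phylo` tree
#' @return data frame with columns `parent` and `child` (node labels)
#' @export
tree_branches <- function(tree) {
  idx <- index_tree(tree)
  data.frame(parent = idx$labels[idx$edges[, "parent"]],
             child = idx$labels[idx$edges[, "child"]],
             stringsAsFactors = FALSE)
}
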