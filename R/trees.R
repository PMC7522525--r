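#' Read a rooted tree with a declared branch-length unit
#'
#' Thin wrapper around [ape::read.tree()] that enforces the conventions the
#' pipeline relies on: trees must be rooted (a basal trifurcation is
#' rejected unless an outgroup is supplied for explicit rooting, because
#' silent re-rooting changes ancestral-state results), branch lengths must
#' be present and non-negative, and the unit of the branch lengths is
#' recorded on the object (`"subs_per_site"`, `"My"` or `"unitless"`).
#'
#' @param path newick file path.
#' @param unit branch length unit tag.
#' @param outgroup optional tip label (or vector) used to root an unrooted
#'   input.
#' @param metadata optional metadata data.frame; when given every leaf label
#'   must have a metadata row.
#' @return an [ape::phylo] tree with attribute `unit` and node labels
#'   (`n1`, `n2`, ... assigned when absent).
#' @export
read_tree <- function(path, unit = c("subs_per_site", "My", "unitless"),
                      outgroup = NULL, metadata = NULL) {
  unit <- match.arg(unit)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  as_evo_tree(tree, unit, outgroup = outgroup, metadata = metadata)
}

#' Declare an ape tree as a unit-tagged pipeline tree
#'
#' @param tree an [ape::phylo] object.
#' @inheritParams read_tree
#' @return the tree, rooted, node-labelled and unit-tagged.
#' @export
as_evo_tree <- function(tree, unit = c("subs_per_site", "My", "unitless"),
                        outgroup = NULL, metadata = NULL) {
  unit <- match.arg(unit)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup))
      stop("unrooted tree (basal multifurcation); supply an outgroup to root it")
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)))
    tree$node.label <- paste0("n", seq_len(tree$Nnode))
  if (!is.null(metadata)) {
    missing <- setdiff(tree$tip.label, metadata$strain)
    if (length(missing))
      stop("tree leaves absent from metadata: ", paste(missing, collapse = ", "))
  }
  attr(tree, "unit") <- unit
  tree
}

#' Write a tree to newick
#'
#' @param tree an [ape::phylo] tree.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Branch length unit of a tree
#' @param tree a tree read with [read_tree()] or tagged by [as_evo_tree()].
#' @return the unit tag, or `"unitless"` when untagged.
#' @export
tree_unit <- function(tree) {
  u <- attr(tree, "unit")
  if (is.null(u)) "unitless" else u
}

# Internal: per-node label vector indexed by ape node number (tips then
# internal nodes).
node_labels <- function(tree) {
  c(tree$tip.label,
    if (is.null(tree$node.label)) paste0("n", seq_len(tree$Nnode)) else tree$node.label)
}

# Internal: resolve node identifiers (labels or numbers) to ape node numbers.
resolve_nodes <- function(tree, nodes) {
  if (is.numeric(nodes)) return(as.integer(nodes))
  labels <- node_labels(tree)
  idx <- match(nodes, labels)
  if (anyNA(idx)) stop("unknown node id: ", paste(nodes[is.na(idx)], collapse = ", "))
  idx
}

#' Branch table of a tree
#'
#' One row per edge, with the child-node label as the stable branch id (a
#' branch is named after the node it leads to).
#'
#' @param tree an [ape::phylo] tree.
#' @return data.frame with columns `parent`, `child` (ape node numbers),
#'   `child_label`, `length`, `terminal`.
#' @export
tree_branches <- function(tree) {
  labels <- node_labels(tree)
  ntip <- length(tree$tip.label)
  data.frame(
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    child_label = labels[tree$edge[, 2]],
    length = tree$edge.length,
    terminal = tree$edge[, 2] <= ntip,
    stringsAsFactors = FALSE
  )
}

# Internal: tip numbers below each node, as a list indexed by node number.
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  out <- vector("list", nnode)
  for (i in seq_len(ntip)) out[[i]] <- i
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

#' Node ages of an ultrametric tree
#'
#' @param tree an ultrametric tree (branch lengths in time units).
#' @return numeric vector of ages (time before present), indexed by ape node
#'   number; tips have age ~0.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Patristic distance between two leaves
#'
#' @param tree an [ape::phylo] tree.
#' @param a,b tip labels.
#' @return sum of branch lengths on the path between `a` and `b`.
#' @export
patristic_distance <- function(tree, a, b) {
  d <- ape::cophenetic.phylo(tree)
  for (x in c(a, b)) if (!x %in% rownames(d)) stop("strain missing from tree: ", x)
  d[a, b]
}
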