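# Phylogenetic-tree plumbing: Newick I/O, neighbor joining, midpoint
# rooting, clade extraction.  Trees are `ape` "phylo" objects;
# multifurcations are permitted throughout, and an uploaded tree is treated
# as rooted as given.

#' Parse a Newick tree
#'
#' Accepts bifurcating and multifurcating trees (a trifurcating root is
#' treated as a rooted multifurcation).  Missing branch lengths default to
#' 1.0; zero-length branches are permitted.
#'
#' @param text Newick text or a file path.
#' @param msa optional [msa()]; when given, every leaf label must match an
#'   alignment row (error naming the missing leaves otherwise).
#' @return an `ape` `phylo` object with finite branch lengths.
#' @export
parse_newick <- function(text, msa = NULL) {
  lines <- as_lines(text)
  tree <- tryCatch(ape::read.tree(text = paste(lines, collapse = "")),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || is.null(tree$tip.label) || is.null(tree$edge)) {
    stop("could not parse Newick text")
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  tree$edge.length[is.na(tree$edge.length)] <- 1
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  if (!is.null(msa)) {
    missing <- setdiff(tree$tip.label, msa$ids)
    if (length(missing) > 0L) {
      stop("tree leaves absent from the alignment: ",
           paste(missing, collapse = ","))
    }
    extra <- setdiff(msa$ids, tree$tip.label)
    if (length(extra) > 0L) {
      stop("alignment rows absent from the tree: ",
           paste(extra, collapse = ","))
    }
  }
  tree
}

#' Write a tree as Newick text
#'
#' @param tree a `phylo` object.
#' @param path optional output file.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical NJ; exact on additive distance matrices.  Negative branch
#' lengths (which NJ can produce on non-additive input) are clamped to 0.
#'
#' @param D symmetric distance matrix with at least 3 taxa, labeled
#'   dimnames.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix is not symmetric")
  }
  tree <- ape::nj(D)
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path,
#' preserving all pairwise leaf path lengths.  A tree whose branch lengths
#' are all zero is returned unchanged with a warning.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return a rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (all(tree$edge.length == 0)) {
    warning("all branch lengths are zero; keeping the current root",
            call. = FALSE)
    return(tree)
  }
  phangorn::midpoint(tree)
}

#' Extract the subtree under an internal node
#'
#' @param tree a rooted `phylo` object.
#' @param node internal node number (ape numbering: leaves are
#'   `1..Ntip`, internal nodes follow), or an internal node label.
#' @return list with `tree` (the subtree, branch lengths preserved) and
#'   `leaves` (leaf labels in subtree order).
#' @export
extract_clade <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (is.character(node)) {
    idx <- match(node, tree$node.label)
    if (is.na(idx)) stop("no internal node labeled '", node, "'")
    node <- ntip + idx
  }
  node <- as.integer(node)
  if (node <= ntip) stop("node ", node, " is a leaf, not an internal node")
  root <- ntip + 1L
  sub <- if (node == root) tree else ape::extract.clade(tree, node)
  list(tree = sub, leaves = leaf_order(sub))
}

# Leaves in plotted (preorder traversal) order.  For a phylo object the
# edge matrix in cladewise order visits leaves in display order.
leaf_order <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  tips <- tree$edge[, 2][tree$edge[, 2] <= length(tree$tip.label)]
  tree$tip.label[tips]
}

# children of each node from the edge matrix (cladewise order).
tree_children <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  split(tree$edge[, 2], tree$edge[, 1])
}
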