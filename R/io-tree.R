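#' Construct a dated species tree
#'
#' Wraps an `ape` phylo object with node ages in million years (MY): leaves at
#' age 0, every internal node strictly older than its children.
#'
#' @param tree An `ape::phylo` object with branch lengths in MY.
#' @param tol Ultrametricity tolerance in MY (default 1e-6).
#' @return Object of class `dated_tree`: `list(tree, ages)` with `ages`
#'   indexed by ape node number.
#' @export
dated_tree <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths (MY)")
  depth <- ape::node.depth.edgelength(tree)
  leaf_depth <- depth[seq_len(ntip)]
  root_age <- max(leaf_depth)
  off <- which(abs(leaf_depth - root_age) > tol)
  if (length(off))
    stop(sprintf("tree is not ultrametric: leaf '%s' at depth %.6g vs %.6g",
                 tree$tip.label[off[1L]], leaf_depth[off[1L]], root_age))
  ages <- root_age - depth
  ages[seq_len(ntip)] <- 0
  structure(list(tree = tree, ages = ages), class = "dated_tree")
}

#' Read a dated ultrametric Newick tree
#'
#' Branch lengths are interpreted as MY; node ages are computed by
#' subtraction from the root and checked for ultrametricity within `tol`.
#'
#' @param path Newick file.
#' @param tol Ultrametricity tolerance in MY.
#' @return A [dated_tree()].
#' @export
read_newick_dated <- function(path, tol = 1e-6) {
  txt <- paste(readLines(path), collapse = "")
  ## a bare single-leaf tree ("x;" or "x:0;") has no internal node for ape
  if (!grepl("(", txt, fixed = TRUE)) {
    lab <- sub("[:;].*$", "", trimws(txt))
    tree <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                           tip.label = lab, Nnode = 1L,
                           edge.length = 0),
                      class = "phylo", order = "cladewise")
    return(structure(list(tree = tree, ages = c(0, 0)), class = "dated_tree"))
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  dated_tree(tree, tol = tol)
}

#' Age of a node in a dated tree
#' @param dtree A [dated_tree()].
#' @param node Ape node number, or a tip label, or a character vector of tip
#'   labels (in which case the MRCA's age is returned).
#' @return Age in MY.
#' @export
node_age <- function(dtree, node) {
  if (is.character(node)) {
    node <- if (length(node) == 1L) match(node, dtree$tree$tip.label)
            else ape::getMRCA(dtree$tree, node)
  }
  dtree$ages[node]
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("<dated_tree> %d tips, root age %.4g MY\n",
              length(x$tree$tip.label), max(x$ages)))
  invisible(x)
}

#' Write a dated tree as Newick
#' @param dtree A [dated_tree()].
#' @param path Output path.
#' @export
write_newick_dated <- function(dtree, path) {
  ape::write.tree(dtree$tree, file = path)
  invisible(NULL)
}
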