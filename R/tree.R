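# Differentiation trees --------------------------------------------------
#
# A differentiation tree is the minimal input of the simulator: a rooted
# tree whose nodes are cell types/states and whose branch lengths measure
# developmental distance. Internally we keep a flat parent-pointer table
# (ids, parent, branch length, depth) which is convenient for Brownian
# walks and pseudotime; ape does the Newick parsing.

new_diff_tree <- function(nodes, parent, blen, root) {
  stopifnot(length(nodes) >= 1L, root %in% nodes)
  # parent/blen keep their given (edge/traversal) order: it defines the
  # child ordering used by serialization and tree walks
  children <- names(parent)
  stopifnot(setequal(children, setdiff(nodes, root)),
            all(parent %in% nodes), all(blen[children] >= 0))
  depth <- setNames(numeric(length(nodes)), nodes)
  # depths by repeated relaxation (trees are small)
  computed <- root
  remaining <- children
  while (length(remaining)) {
    done <- remaining[parent[remaining] %in% computed]
    if (!length(done)) stop("cycle or disconnected node in tree")
    depth[done] <- depth[parent[done]] + blen[done]
    computed <- c(computed, done)
    remaining <- setdiff(remaining, done)
  }
  leaves <- setdiff(nodes, unique(unname(parent[children])))
  structure(
    list(nodes = nodes, parent = parent[children], blen = blen[children],
         root = root, leaves = leaves, depth = depth),
    class = "diff_tree")
}

#' Parse a Newick differentiation tree
#'
#' Missing branch lengths default to 1. Leaves are enumerated in input
#' order. A bare label such as `"A;"` yields a degenerate tree whose single
#' node is both root and leaf.
#'
#' @param newick_text a Newick string.
#' @return a `diff_tree` object.
#' @export
parse_tree <- function(newick_text) {
  stopifnot(is.character(newick_text), length(newick_text) == 1L)
  txt <- trimws(newick_text)
  if (!nzchar(txt)) stop("empty Newick string at position 1")
  if (!grepl(";$", txt)) txt <- paste0(txt, ";")
  if (!grepl("[(),]", txt)) {
    # degenerate single-node tree, e.g. "A;"
    lab <- sub(";$", "", txt)
    lab <- sub(":.*$", "", lab)
    if (!nzchar(lab)) lab <- "root"
    return(new_diff_tree(lab, setNames(character(0), character(0)),
                         setNames(numeric(0), character(0)), lab))
  }
  depth_chk <- cumsum((strsplit(txt, "")[[1]] == "(") -
                        (strsplit(txt, "")[[1]] == ")"))
  if (any(depth_chk < 0) || tail(depth_chk, 1) != 0)
    stop("malformed Newick: unbalanced parentheses near position ",
         which(depth_chk < 0)[1] %||% nchar(txt))
  phy <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(phy) || is.null(phy$tip.label) || anyNA(phy$tip.label))
    stop("malformed Newick at position 1: ", newick_text)
  as_diff_tree(phy)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' Convert an ape `phylo` object to a differentiation tree
#'
#' @param phy a `phylo` object.
#' @return a `diff_tree`.
#' @export
as_diff_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  node_lab <- phy$node.label
  if (is.null(node_lab) || !length(node_lab))
    node_lab <- paste0("node", seq_len(nnode))
  node_lab[!nzchar(node_lab)] <- paste0("node", which(!nzchar(node_lab)))
  labs <- c(phy$tip.label, node_lab)
  if (anyDuplicated(labs)) labs <- make.unique(labs, sep = "_")
  el <- phy$edge.length
  if (is.null(el)) el <- rep(1, nrow(phy$edge))
  el[is.na(el)] <- 1
  parent <- setNames(character(0), character(0))
  blen <- setNames(numeric(0), character(0))
  for (i in seq_len(nrow(phy$edge))) {
    ch <- labs[phy$edge[i, 2]]
    parent[ch] <- labs[phy$edge[i, 1]]
    blen[ch] <- el[i]
  }
  root <- labs[ntip + 1L]
  new_diff_tree(labs, parent, blen, root)
}

#' Built-in differentiation trees
#'
#' Three stock topologies with 1, 3 and 5 leaves. `Phyla1` is a single
#' root-to-leaf path (a linear trajectory); `Phyla3` and `Phyla5` are
#' balanced trees with unit branch lengths, shipped as stand-ins for the
#' unpublished stock topologies.
#'
#' @param name one of `"Phyla1"`, `"Phyla3"`, `"Phyla5"`.
#' @return a `diff_tree`.
#' @export
builtin_tree <- function(name) {
  txt <- switch(name,
    Phyla1 = "(A:1);",
    Phyla3 = "((A:1,B:1)M1:1,C:1)root;",
    Phyla5 = "(((A:1,B:1)M1:1,C:1)M2:1,(D:1,E:1)M3:1)root;",
    stop("unknown tree '", name, "'; valid names: Phyla1, Phyla3, Phyla5"))
  parse_tree(txt)
}

#' @export
print.diff_tree <- function(x, ...) {
  cat("<diff_tree> ", length(x$nodes), " nodes, ", length(x$leaves),
      " leaves, root '", x$root, "', depth ", max(x$depth), "\n", sep = "")
  invisible(x)
}

#' Serialize a differentiation tree to Newick
#'
#' @param tree a `diff_tree`.
#' @return a Newick string.
#' @export
serialize_tree <- function(tree) {
  stopifnot(inherits(tree, "diff_tree"))
  rec <- function(node) {
    kids <- names(tree$parent)[tree$parent == node]
    lab <- node
    if (!length(kids)) return(lab)
    paste0("(", paste(vapply(kids, function(k)
      paste0(rec(k), ":", format(tree$blen[k])), ""), collapse = ","),
      ")", lab)
  }
  paste0(rec(tree$root), ";")
}

tree_children <- function(tree, node)
  names(tree$parent)[tree$parent == node]

# Root-to-leaf lineages: list of node-id vectors (root first).
tree_lineages <- function(tree) {
  lapply(tree$leaves, function(lf) {
    path <- lf
    while (path[1] != tree$root) path <- c(tree$parent[[path[1]]], path)
    path
  })
}

# Pairwise path length between two nodes (through their common ancestor).
tree_path_length <- function(tree, a, b) {
  anc <- function(n) {
    p <- n
    while (p[1] != tree$root) p <- c(tree$parent[[p[1]]], p)
    p
  }
  pa <- anc(a); pb <- anc(b)
  common <- max(which(pa %in% pb & seq_along(pa) <= length(pb)))
  mrca <- pa[max(which(pa %in% pb))]
  tree$depth[a] + tree$depth[b] - 2 * tree$depth[mrca]
}
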