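#' Read a rooted tree from a Newick string
#'
#' Parses a Newick string (internal node labels and branch lengths optional)
#' into a `rooted_tree` object. Internal nodes without labels are auto-named
#' by post-order index (`"n0001"`, `"n0002"`, ...) so that every node is
#' addressable, e.g. when reporting Dollo gain/loss events.
#'
#' @param text a single Newick string, terminated by `;`.
#' @return a `rooted_tree`: a list with components `ids` (all node ids,
#'   leaves first), `leaves`, `root`, `parent` (named character vector,
#'   `parent[child]`), `children` (named list), `lengths` (named numeric
#'   vector of branch lengths keyed by child node, or `NULL`), and `phy`
#'   (the underlying [ape::read.tree()] `phylo` object).
#' @examples
#' tr <- read_newick("((A:1,B:1)N1:0.5,C:2)R;")
#' tree_leaves(tr)
#' tr$parent[["A"]]
#' @seealso [write_newick()], [tree_mrca()]
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) {
    stop("failed to parse Newick string", call. = FALSE)
  }
  as_rooted_tree(phy)
}

#' Read a rooted tree from a Newick file
#' @param path path to a file containing a single Newick tree.
#' @return a `rooted_tree`; see [read_newick()].
#' @export
read_newick_file <- function(path) {
  read_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

# Cheap structural validation so malformed input fails with a position,
# before ape's parser (which reports no location) sees it.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unmatched ')' at position ", i, call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at end of input",
         call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("Newick parse error: missing terminating ';' at position ",
         nchar(text), call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert an ape phylo object to a rooted_tree
#'
#' @param phy a rooted `phylo` object.
#' @return a `rooted_tree`; see [read_newick()].
#' @export
as_rooted_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) {
    stop("tree must be rooted", call. = FALSE)
  }
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  node_lab <- phy$node.label
  if (is.null(node_lab)) node_lab <- rep("", nnode)
  # auto-name unlabeled internal nodes by post-order index
  po <- rev(postorder_ape(phy))      # ape node numbers, post-order
  po_internal <- po[po > ntip]
  blank <- !nzchar(node_lab)
  if (any(blank)) {
    counter <- 0L
    for (nd in rev(po_internal)) {   # post-order traversal order
      idx <- nd - ntip
      if (blank[idx]) {
        counter <- counter + 1L
        node_lab[idx] <- sprintf("n%04d", counter)
      }
    }
  }
  labs <- node_lab[nzchar(node_lab)]
  if (anyDuplicated(labs)) {
    stop("duplicate internal node label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  if (any(node_lab %in% phy$tip.label)) {
    stop("internal node label(s) collide with leaf labels: ",
         paste(intersect(node_lab, phy$tip.label), collapse = ", "),
         call. = FALSE)
  }
  phy$node.label <- node_lab
  ids <- c(phy$tip.label, node_lab)          # indexed by ape node number
  parent <- rep(NA_character_, ntip + nnode)
  for (e in seq_len(nrow(phy$edge))) {
    parent[phy$edge[e, 2L]] <- ids[phy$edge[e, 1L]]
  }
  names(parent) <- ids
  children <- split(ids[phy$edge[, 2L]], factor(ids[phy$edge[, 1L]], levels = ids))
  children <- children[vapply(children, length, 1L) > 0L]
  lengths <- NULL
  if (!is.null(phy$edge.length)) {
    lengths <- stats::setNames(phy$edge.length, ids[phy$edge[, 2L]])
  }
  root <- ids[ntip + 1L]
  structure(
    list(ids = ids, leaves = phy$tip.label, root = root,
         parent = parent, children = children, lengths = lengths, phy = phy,
         cache = new.env(parent = emptyenv())),
    class = "rooted_tree"
  )
}

# post-order sequence of ape node numbers (children before parents)
postorder_ape <- function(phy) {
  ntip <- length(phy$tip.label)
  res <- integer(0)
  walk <- function(nd) {
    kids <- phy$edge[phy$edge[, 1L] == nd, 2L]
    for (k in kids) walk(k)
    res[[length(res) + 1L]] <<- nd
  }
  walk(ntip + 1L)
  unlist(res)
}

#' Write a rooted_tree as a Newick string
#' @param tree a `rooted_tree`.
#' @param path optional file path; if `NULL` the string is returned.
#' @return the Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "rooted_tree"))
  txt <- ape::write.tree(tree$phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat("rooted_tree:", length(x$leaves), "leaves,",
      length(x$ids) - length(x$leaves), "internal nodes, root =", x$root, "\n")
  cat("leaves:", paste(utils::head(x$leaves, 10), collapse = ", "),
      if (length(x$leaves) > 10) "..." else "", "\n")
  invisible(x)
}

#' Tree accessors
#'
#' `tree_leaves` returns leaf ids, `tree_nodes` all node ids (leaves first),
#' `tree_children` the child ids of a node (empty for a leaf), and
#' `tree_parent` the parent id (`NA` for the root).
#' @param tree a `rooted_tree`.
#' @param node a node id.
#' @name tree-accessors
#' @export
tree_leaves <- function(tree) tree$leaves

#' @rdname tree-accessors
#' @export
tree_nodes <- function(tree) tree$ids

#' @rdname tree-accessors
#' @export
tree_children <- function(tree, node) {
  check_node(tree, node)
  kids <- tree$children[[node]]
  if (is.null(kids)) character(0) else kids
}

#' @rdname tree-accessors
#' @export
tree_parent <- function(tree, node) {
  check_node(tree, node)
  unname(tree$parent[[node]])
}

check_node <- function(tree, node) {
  if (!node %in% tree$ids) {
    stop("unknown node id: ", node, call. = FALSE)
  }
  invisible(TRUE)
}

#' Descendant leaves of a node
#' @param tree a `rooted_tree`.
#' @param node a node id (a leaf is its own descendant leaf).
#' @return character vector of leaf ids in the subtree rooted at `node`.
#' @export
tree_descendant_leaves <- function(tree, node) {
  check_node(tree, node)
  inc <- tree_leaf_incidence(tree)
  tree$leaves[inc[node, ]]
}

#' Most recent common ancestor of a set of leaves
#' @param tree a `rooted_tree`.
#' @param leaves character vector of leaf ids (length >= 1).
#' @return the node id of the MRCA (a leaf id if `leaves` is one leaf).
#' @export
tree_mrca <- function(tree, leaves) {
  stopifnot(length(leaves) >= 1L)
  missing <- setdiff(leaves, tree$leaves)
  if (length(missing)) {
    stop("not leaves of the tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(leaves)) == 1L) return(leaves[[1L]])
  inc <- tree_leaf_incidence(tree)
  want <- tree$leaves %in% leaves
  cover <- inc[, want, drop = FALSE]
  cand <- rownames(inc)[rowSums(cover) == sum(want)]
  depth <- tree_depths(tree)
  cand[which.max(depth[cand])]
}

#' Is node `a` an ancestor of (or equal to) node `b`?
#' @param tree a `rooted_tree`.
#' @param a,b node ids.
#' @export
is_ancestor <- function(tree, a, b) {
  check_node(tree, a); check_node(tree, b)
  nd <- b
  repeat {
    if (identical(nd, a)) return(TRUE)
    nd <- tree$parent[[nd]]
    if (is.na(nd)) return(FALSE)
  }
}

# node x leaf incidence matrix (TRUE iff leaf below-or-equal node), cached
# in the tree's environment (reference semantics survive copies)
tree_leaf_incidence <- function(tree) {
  cached <- tree$cache$leaf_incidence
  if (!is.null(cached)) return(cached)
  ids <- tree$ids
  nl <- length(tree$leaves)
  inc <- matrix(FALSE, nrow = length(ids), ncol = nl,
                dimnames = list(ids, tree$leaves))
  po <- tree_postorder(tree)
  for (nd in po) {
    kids <- tree$children[[nd]]
    if (is.null(kids)) {
      inc[nd, nd] <- TRUE
    } else {
      inc[nd, ] <- colSums(inc[kids, , drop = FALSE]) > 0L
    }
  }
  tree$cache$leaf_incidence <- inc
  inc
}

# node ids in post-order (children before parents)
tree_postorder <- function(tree) {
  cached <- tree$cache$postorder
  if (!is.null(cached)) return(cached)
  po <- tree$ids[postorder_ape(tree$phy)]
  tree$cache$postorder <- po
  po
}

# depth (edges from root) per node, named vector
tree_depths <- function(tree) {
  cached <- tree$cache$depths
  if (!is.null(cached)) return(cached)
  depth <- stats::setNames(rep(NA_integer_, length(tree$ids)), tree$ids)
  depth[tree$root] <- 0L
  for (nd in rev(tree_postorder(tree))) {    # pre-order
    if (nd == tree$root) next
    depth[nd] <- depth[tree$parent[[nd]]] + 1L
  }
  tree$cache$depths <- depth
  depth
}
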