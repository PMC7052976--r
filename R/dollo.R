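#' Dollo-parsimony reconstruction for a single feature
#'
#' Under Dollo parsimony a feature is gained exactly once and may be lost
#' repeatedly. Given the set of leaves where the feature is present, the
#' unique minimum-loss single-gain reconstruction places the gain at the
#' MRCA of the presence leaves; the losses are the roots of the maximal
#' subtrees below the gain node that contain no presence leaf (a branch is
#' identified by its child node).
#'
#' @param tree a `rooted_tree` (see [read_newick()]).
#' @param presence character vector of leaf ids where the feature is
#'   present (may be empty).
#' @return list with `gain` (node id, or `NA` for an all-absent feature)
#'   and `losses` (sorted character vector of child-node ids of loss
#'   branches).
#' @examples
#' tr <- read_newick("((A,B)N1,(C,D)N2)R;")
#' reconstruct_dollo(tr, c("A", "C"))  # gain at R, losses on B and D
#' @export
reconstruct_dollo <- function(tree, presence) {
  stopifnot(inherits(tree, "rooted_tree"))
  presence <- unique(as.character(presence))
  bad <- setdiff(presence, tree$leaves)
  if (length(bad)) {
    stop("presence leaves not in tree: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!length(presence)) return(list(gain = NA_character_,
                                     losses = character(0)))
  inc <- tree_leaf_incidence(tree)
  depth <- tree_depths(tree)
  pres <- tree$leaves %in% presence
  cnt <- as.integer(inc %*% pres)
  names(cnt) <- tree$ids
  dollo_from_counts(tree, cnt, length(presence), inc, depth)
}

# shared core: counts of presence leaves below each node -> (gain, losses)
dollo_from_counts <- function(tree, cnt, npres, inc, depth) {
  cand <- tree$ids[cnt == npres]
  gain <- cand[which.max(depth[cand])]      # deepest covering node = MRCA
  below_gain <- inc[gain, ]                  # leaves under the gain node
  # loss roots: empty subtree whose parent subtree is non-empty, inside the
  # gain subtree (parent-count > 0 alone also matches children of ancestors
  # of the gain node, so restrict to nodes whose leaves all sit under gain)
  losses <- character(0)
  for (nd in tree$ids) {
    if (nd == tree$root || cnt[nd] != 0L) next
    par <- tree$parent[[nd]]
    if (cnt[par] == 0L) next
    nd_leaves <- inc[nd, ]
    if (all(below_gain[nd_leaves])) losses <- c(losses, nd)
  }
  list(gain = gain, losses = sort(losses))
}

#' Map Dollo gain/loss events for every feature of a matrix
#'
#' Applies the single-feature reconstruction column-wise and assembles
#' per-node gained/lost feature sets. Matrix species must coincide with the
#' tree leaves (include or drop an outgroup explicitly before calling).
#'
#' @param tree a `rooted_tree`.
#' @param pm a [presence_matrix()]; `pm$species` must equal
#'   `tree_leaves(tree)` as a set.
#' @return an `event_map`: list with `features` (data frame: `feature`,
#'   `gain`, `n_losses`, `losses` semicolon-joined), `node_gains` and
#'   `node_losses` (named lists of feature-id vectors per node), and
#'   `tree`.
#' @export
map_events <- function(tree, pm) {
  stopifnot(inherits(tree, "rooted_tree"), inherits(pm, "presence_matrix"))
  only_mat <- setdiff(pm$species, tree$leaves)
  only_tree <- setdiff(tree$leaves, pm$species)
  if (length(only_mat) || length(only_tree)) {
    stop("species/leaf mismatch; matrix-only: {",
         paste(only_mat, collapse = ", "), "}, tree-only: {",
         paste(only_tree, collapse = ", "), "}", call. = FALSE)
  }
  inc <- tree_leaf_incidence(tree)
  depth <- tree_depths(tree)
  mat <- pm$matrix[tree$leaves, , drop = FALSE]
  cnt_all <- inc %*% mat                       # nodes x features
  npres_all <- colSums(mat)
  feats <- pm$features
  gains <- character(length(feats))
  losses <- vector("list", length(feats))
  for (j in seq_along(feats)) {
    if (npres_all[j] == 0L) {
      gains[j] <- NA_character_
      losses[[j]] <- character(0)
      next
    }
    cnt <- cnt_all[, j]
    rec <- dollo_from_counts(tree, cnt, npres_all[j], inc, depth)
    gains[j] <- rec$gain
    losses[[j]] <- rec$losses
  }
  node_gains <- split(feats[!is.na(gains)], gains[!is.na(gains)])
  loss_feat <- rep(feats, lengths(losses))
  loss_node <- unlist(losses, use.names = FALSE)
  node_losses <- if (length(loss_feat)) split(loss_feat, loss_node) else list()
  structure(
    list(
      features = data.frame(
        feature = feats, gain = gains,
        n_losses = lengths(losses),
        losses = vapply(losses, paste, character(1), collapse = ";"),
        stringsAsFactors = FALSE
      ),
      node_gains = node_gains, node_losses = node_losses, tree = tree
    ),
    class = "event_map"
  )
}

#' @export
print.event_map <- function(x, ...) {
  cat("event_map:", nrow(x$features), "features;",
      sum(!is.na(x$features$gain)), "gained;",
      sum(x$features$n_losses), "loss events\n")
  invisible(x)
}

#' Rank event categories at a node
#'
#' Summarizes the features gained or lost on the branch leading to a node by
#' functional category (one count per KO per top-level category, i.e. the
#' level below "Metabolism" in a BRITE path). Ranking is by descending
#' count, ties broken alphabetically.
#'
#' @param em an `event_map` from [map_events()].
#' @param categories KO-to-category map (data frame `ko`, `path`).
#' @param node a node id of the tree.
#' @param type `"loss"` (default) or `"gain"`.
#' @return data frame with columns `category`, `count` (possibly 0 rows).
#' @export
aggregate_node_categories <- function(em, categories, node,
                                      type = c("loss", "gain")) {
  stopifnot(inherits(em, "event_map"))
  type <- match.arg(type)
  check_node(em$tree, node)
  feats <- if (type == "loss") em$node_losses[[node]] else em$node_gains[[node]]
  if (is.null(feats) || !length(feats)) {
    return(data.frame(category = character(0), count = integer(0)))
  }
  map <- feature_categories(validate_categories(categories))
  hit <- map[map$ko %in% feats, , drop = FALSE]
  if (!nrow(hit)) {
    return(data.frame(category = character(0), count = integer(0)))
  }
  tab <- table(hit$category)
  res <- data.frame(category = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$count, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Brute-force Dollo oracle
#'
#' Exhaustively searches all single-gain scenarios: every gain node whose
#' subtree covers the presence leaves, combined with every loss-branch set
#' (enumerated by increasing size) that reproduces the observed leaf
#' pattern. Returns the minimum-loss scenario. Exponential; intended as an
#' independent check of [reconstruct_dollo()] on small trees.
#'
#' @param tree a `rooted_tree` (keep it small, e.g. <= 8 leaves).
#' @param presence character vector of presence leaf ids.
#' @return list with `gain`, `losses`, `n_losses` of the global minimum
#'   (`gain = NA` for the empty pattern).
#' @export
dollo_brute_force <- function(tree, presence) {
  stopifnot(inherits(tree, "rooted_tree"))
  presence <- unique(as.character(presence))
  if (!length(presence)) {
    return(list(gain = NA_character_, losses = character(0), n_losses = 0L))
  }
  inc <- tree_leaf_incidence(tree)
  pres <- tree$leaves %in% presence
  best <- NULL
  covering <- tree$ids[as.integer(inc %*% pres) == sum(pres)]
  for (g in covering) {
    # candidate loss branches: nodes strictly inside the gain subtree
    inside <- tree$ids[vapply(tree$ids, function(nd) {
      nd != g && is_ancestor(tree, g, nd)
    }, logical(1))]
    # iterative deepening: the first feasible loss-set size is minimal for g
    for (k in 0:length(inside)) {
      if (!is.null(best) && k >= best$n_losses) break
      sets <- if (k == 0L) list(character(0)) else
        utils::combn(inside, k, simplify = FALSE)
      found <- FALSE
      for (ls in sets) {
        leaf_state <- inc[g, ]
        for (l in ls) leaf_state <- leaf_state & !inc[l, ]
        if (identical(unname(leaf_state), unname(pres))) {
          best <- list(gain = g, losses = sort(ls), n_losses = k)
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  best
}
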